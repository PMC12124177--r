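# Posterior summaries, model comparison and diagnostics for AFT fits.

#' Acceleration factors from an AFT coefficient
#'
#' `exp(-beta)` multiplies the median survival time per unit covariate
#' increase; `exp(beta)` multiplies the rate of survival decline (e.g.
#' beta = 0.41 for males means female survival times are 1.5 times longer).
#'
#' @param beta coefficient draw(s) or estimate(s).
#' @return data frame with `median_time_factor` (`exp(-beta)`) and
#'   `decline_factor` (`exp(beta)`).
#' @export
acceleration_factor <- function(beta) {
  data.frame(beta = beta, median_time_factor = exp(-beta),
             decline_factor = exp(beta))
}

#' Evidence ratio for a one-sided statement
#'
#' The posterior probability `p` that the statement holds, as the fraction
#' of draws satisfying it, and the odds `ER = p / (1 - p)`. When every draw
#' satisfies the statement the ratio is infinite (printed `Inf`).
#'
#' @param draws numeric draws (at least 100).
#' @param direction `"greater"` or `"less"`.
#' @param threshold comparison point (default 0).
#' @return list with `er` and `p`.
#' @examples
#' evidence_ratio(c(rep(1, 9992), rep(-1, 8)))  # er = 1249, p = 0.9992
#' @export
evidence_ratio <- function(draws, direction = c("greater", "less"),
                           threshold = 0) {
  direction <- match.arg(direction)
  if (length(draws) < 100L) fail("at least 100 draws are needed")
  p <- if (direction == "greater") mean(draws > threshold)
  else mean(draws < threshold)
  list(er = if (p == 1) Inf else p / (1 - p), p = p)
}

#' Deviance information criterion
#'
#' `DIC = mean(D) + pD` with `D = -2 loglik` per draw and
#' `pD = mean(D) - D(posterior mean)`.
#'
#' @param x an `aft_fit`, or a list with `deviance_draws` and
#'   `deviance_at_mean`.
#' @param ... unused.
#' @return DIC value with attributes `pD` and `Dbar`.
#' @export
dic <- function(x, ...) UseMethod("dic")

#' @export
dic.default <- function(x, ...) {
  Dbar <- mean(x$deviance_draws)
  pD <- Dbar - x$deviance_at_mean
  structure(Dbar + pD, pD = pD, Dbar = Dbar)
}

#' @export
dic.aft_fit <- function(x, ...) {
  Dbar <- mean(-2 * x$draws$loglik)
  p <- ncol(x$prep$X)
  beta <- coef(x)
  base <- fitted_baseline(x)
  w <- if (is.null(x$w_draws)) NULL else colMeans(x$w_draws)
  Dhat <- -2 * aft_loglik(x$prep, beta, base, w)$total
  structure(Dbar + (Dbar - Dhat), pD = Dbar - Dhat, Dbar = Dbar)
}

#' Log pseudo-marginal likelihood
#'
#' `CPO_i` is the harmonic mean over draws of unit `i`'s likelihood;
#' `LPML = sum(log CPO_i)`. Computed stably on the log scale; a unit whose
#' harmonic mean underflows is floored and flagged.
#'
#' @param x an `aft_fit`, or a list with `loglik_matrix` (draws x units).
#' @param ... unused.
#' @return LPML value with attribute `n_floored`.
#' @export
lpml <- function(x, ...) UseMethod("lpml")

#' @export
lpml.default <- function(x, ...) {
  ll <- x$loglik_matrix
  S <- nrow(ll)
  # log CPO_i = -(logmeanexp of -ll_i)
  neg <- -ll
  m <- apply(neg, 2, max)
  logcpo <- -(m + log(colMeans(exp(sweep(neg, 2, m)))))
  floored <- !is.finite(logcpo)
  logcpo[floored] <- min(logcpo[is.finite(logcpo)], -745)
  structure(sum(logcpo), n_floored = sum(floored))
}

#' @export
lpml.aft_fit <- function(x, ...) {
  lpml.default(list(loglik_matrix = x$ll_unit))
}

#' Select parsimonious models by DIC and LPML
#'
#' The selected set is the union of candidates within 2 DIC of the minimum
#' and within 2 LPML of the maximum.
#'
#' @param scores data frame with columns `model`, `dic`, `lpml`.
#' @param delta selection threshold (default 2).
#' @return the scores with `delta_dic`, `delta_lpml` and logical `selected`
#'   columns, ordered by DIC.
#' @export
select_models <- function(scores, delta = 2) {
  stopifnot(all(c("model", "dic", "lpml") %in% names(scores)),
            nrow(scores) >= 1)
  scores$delta_dic <- scores$dic - min(scores$dic)
  scores$delta_lpml <- max(scores$lpml) - scores$lpml
  scores$selected <- scores$delta_dic < delta | scores$delta_lpml < delta
  scores[order(scores$dic), ]
}

#' Cox-Snell residual diagnostics
#'
#' Conditional Cox-Snell residuals at the posterior means:
#' `r = -log S(exit | x, w) + log S(entry | x, w)`. Under a correct model
#' the residuals behave like a unit-exponential censored sample, so the
#' Kaplan-Meier survival of `r` is compared against `exp(-r)`; the summary
#' reports the largest absolute difference at the residual event times
#' (a Kolmogorov-Smirnov-style distance).
#'
#' @param fit an `aft_fit`.
#' @return list with `residuals` (data frame `unit`, `r`, `event`), `ks`
#'   and `low_information` (no events).
#' @export
cox_snell <- function(fit) {
  stopifnot(inherits(fit, "aft_fit"))
  prep <- fit$prep
  beta <- coef(fit)
  base <- fitted_baseline(fit)
  w <- if (is.null(fit$w_draws)) rep(0, length(prep$groups)) else
    colMeans(fit$w_draws)
  eta <- (if (ncol(prep$X)) as.numeric(prep$X %*% beta) else 0) +
    (if (length(w)) w[prep$gidx] else 0)
  rate <- exp(eta)
  contrib <- rate * (prep$exit - prep$entry)
  tau_exit <- rowsum(contrib, prep$uidx, reorder = TRUE)[, 1L]
  tau_entry <- prep$entry[prep$first] * rate[prep$first]
  r <- -baseline_logS(tau_exit + tau_entry, base) +
    baseline_logS(tau_entry, base)
  res <- data.frame(unit = prep$unit_ids, r = r, event = prep$ev_unit)
  if (!any(res$event == 1)) {
    return(list(residuals = res, ks = NA_real_, low_information = TRUE))
  }
  km <- km_survival(data.frame(entry = 0, exit = res$r, event = res$event))
  ev <- km$n_event > 0
  ks <- max(abs(km$surv[ev] - exp(-km$time[ev])))
  list(residuals = res, ks = ks, low_information = FALSE)
}

#' @export
residuals.aft_fit <- function(object, ...) cox_snell(object)$residuals

#' Enumerate the candidate model grid
#'
#' The factorial of covariate sets (base; habitat suitability; one model
#' per retained principal component plus one with the first two components)
#' with each frailty type, survival time scale and spatial scale. With five
#' retained components per spatial scale this gives
#' (1 + 1 + 6) x 2 x 2 x 2 = 64 specifications.
#'
#' @param n_pc named vector: retained components per spatial scale.
#' @param time_scales,spatial_scales,frailties factor levels of the grid.
#' @param include_pair include the first-two-components model (default TRUE).
#' @return data frame of model specifications (one row each).
#' @export
build_model_grid <- function(n_pc = c(landscape = 5, home_range = 5),
                             time_scales = c("age", "annual"),
                             spatial_scales = c("landscape", "home_range"),
                             frailties = c("IID", "GRF"),
                             include_pair = TRUE) {
  rows <- list()
  for (ts in time_scales) for (ss in spatial_scales) for (fr in frailties) {
    sets <- c("base", "HSI",
              if (n_pc[[ss]] >= 1) paste0("PC", seq_len(n_pc[[ss]])),
              if (include_pair && n_pc[[ss]] >= 2) "PC1+2")
    for (cs in sets) {
      rows[[length(rows) + 1L]] <- data.frame(
        time_scale = ts, spatial_scale = ss, frailty = fr,
        covariates = cs, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  key <- do.call(paste, c(out, sep = "|"))
  if (anyDuplicated(key)) fail("duplicate model specification(s): %s",
                               paste(unique(key[duplicated(key)]),
                                     collapse = "; "))
  out$model <- paste(out$covariates, out$frailty, out$time_scale,
                     out$spatial_scale, sep = ".")
  out
}
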