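# Additive-versus-compensatory mortality analysis: uncertainty in annual
# rate estimates is propagated by sampling each rate from a beta
# distribution (moments matched to the estimate and its standard error),
# a logit-link beta regression is fitted to every sampled data set, and the
# slopes are summarised by their mean and 90% highest-posterior-density
# interval. Slopes of the survival regressions (H1, H2) are classified
# against the fitted no-hunting survival S0: positive trends are consistent
# with (over)compensation, trends steeper than -S0 with (super)additivity,
# and anything between with partial compensation.

#' Beta parameters from moments
#'
#' Method of moments: `nu = mean (1 - mean) / se^2 - 1`, `alpha = mean nu`,
#' `beta = (1 - mean) nu`. The variance must be feasible for a beta law
#' (`se^2 < mean (1 - mean)`).
#'
#' @param mean estimate in (0, 1).
#' @param se standard error (> 0).
#' @param label optional name used in error messages.
#' @return list with `alpha` and `beta`.
#' @examples
#' beta_moments_to_params(0.5, 0.1)   # alpha = beta = 12
#' beta_moments_to_params(0.8, 0.05)  # alpha = 50.4, beta = 12.6
#' @export
beta_moments_to_params <- function(mean, se, label = NULL) {
  if (any(mean <= 0 | mean >= 1)) fail("rate estimate%s outside (0, 1)",
                                       if (is.null(label)) "" else paste0(" ", label))
  if (any(se <= 0)) fail("standard error must be positive")
  if (any(se^2 >= mean * (1 - mean))) {
    fail("infeasible variance for %s: se^2 = %.4g >= mean(1-mean) = %.4g",
         label %||% "rate", max(se^2), min(mean * (1 - mean)))
  }
  nu <- mean * (1 - mean) / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Sample rate draws from moment-matched beta distributions
#'
#' Independent beta draws for every (area, quantity) rate in the table;
#' the same draw array is shared by all hypotheses downstream to reduce
#' Monte Carlo noise between them.
#'
#' @param rates data frame with columns `area`, `quantity`, `estimate`, `se`.
#' @param n_draws number of draws per rate (default 10,000).
#' @param seed integer seed.
#' @return 3-d array `[draw, area, quantity]`.
#' @export
sample_rates <- function(rates, n_draws = 10000, seed = 1) {
  areas <- unique(rates$area)
  quantities <- unique(rates$quantity)
  arr <- array(NA_real_, c(n_draws, length(areas), length(quantities)),
               dimnames = list(NULL, areas, quantities))
  with_seed(seed, {
    for (r in seq_len(nrow(rates))) {
      p <- beta_moments_to_params(rates$estimate[r], rates$se[r],
                                  label = sprintf("%s/%s", rates$area[r],
                                                  rates$quantity[r]))
      arr[, rates$area[r], rates$quantity[r]] <-
        stats::rbeta(n_draws, p$alpha, p$beta)
    }
  })
  arr
}

# Vectorised maximum-likelihood beta regression (logit mean link, common
# precision) across many response vectors. Alternating Fisher scoring for
# the regression coefficients and Newton steps for the precision. Y is
# draws x points; x is either one shared predictor vector or a draws x
# points matrix (one predictor per draw). Returns per-draw coefficients,
# precision, standard errors, log-likelihood and convergence flags.
beta_mle_matrix <- function(Y, x, tol = 1e-8, maxit = 80) {
  if (any(Y <= 0 | Y >= 1)) fail("responses must lie strictly inside (0, 1)")
  m <- nrow(Y)
  n <- ncol(Y)
  if (n < 3L) fail("at least 3 points are needed")
  X <- if (is.matrix(x)) x else matrix(x, m, n, byrow = TRUE)
  stopifnot(identical(dim(X), dim(Y)))
  ystar <- log(Y / (1 - Y))
  logy <- log(Y)
  log1y <- log(1 - Y)
  Xc <- X - rowMeans(X)
  vx <- rowSums(Xc^2)
  # least-squares start on the logit scale
  b1 <- rowSums(ystar * Xc) / vx
  b0 <- rowMeans(ystar) - b1 * rowMeans(X)
  mu <- invlogit(b0 + b1 * X)
  resid_var <- pmax(rowMeans((Y - mu)^2), 1e-8)
  phi <- pmax(rowMeans(mu * (1 - mu)) / resid_var - 1, 1)
  conv <- rep(FALSE, m)
  for (it in seq_len(maxit)) {
    mu <- invlogit(b0 + b1 * X)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    a <- mu * phi
    b <- (1 - mu) * phi
    mustar <- digamma(a) - digamma(b)
    w <- mu * (1 - mu)
    v <- trigamma(a) + trigamma(b)
    r <- ystar - mustar
    U0 <- phi * rowSums(r * w)
    U1 <- phi * rowSums(r * w * X)
    ww <- v * w^2
    I00 <- phi^2 * rowSums(ww)
    I01 <- phi^2 * rowSums(ww * X)
    I11 <- phi^2 * rowSums(ww * X^2)
    det <- pmax(I00 * I11 - I01^2, 1e-300)
    d0 <- (I11 * U0 - I01 * U1) / det
    d1 <- (I00 * U1 - I01 * U0) / det
    # damp exploding steps from poor starts
    step <- pmax(abs(d0), abs(d1))
    damp <- ifelse(step > 5, 5 / step, 1)
    b0 <- b0 + damp * d0
    b1 <- b1 + damp * d1
    # Newton update for the precision
    mu <- invlogit(b0 + b1 * X)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sphi <- rowSums(digamma(phi) - mu * digamma(mu * phi) -
                      (1 - mu) * digamma((1 - mu) * phi) +
                      mu * logy + (1 - mu) * log1y)
    hphi <- rowSums(trigamma(phi) - mu^2 * trigamma(mu * phi) -
                      (1 - mu)^2 * trigamma((1 - mu) * phi))
    dphi <- ifelse(hphi < 0, -sphi / hphi, sign(sphi) * 0.5 * phi)
    dphi <- pmin(pmax(dphi, -0.5 * phi), 2 * phi)
    phi <- pmin(pmax(phi + dphi, 1e-3), 1e8)
    newly <- pmax(abs(d0), abs(d1)) < tol & abs(dphi) / phi < tol
    conv <- conv | newly
    if (all(conv) && it > 2L) break
  }
  # rows the alternating scheme failed on are polished one by one with a
  # quasi-Newton optimiser (analytic gradient); keeps the convergence flag
  # honest on extreme, near-boundary rate draws
  if (any(!conv)) {
    for (row in which(!conv)) {
      yi <- Y[row, ]
      xi <- X[row, ]
      nll <- function(p) {
        mui <- pmin(pmax(invlogit(p[1] + p[2] * xi), 1e-12), 1 - 1e-12)
        ph <- exp(p[3])
        -sum(stats::dbeta(yi, mui * ph, (1 - mui) * ph, log = TRUE))
      }
      gr <- function(p) {
        mui <- pmin(pmax(invlogit(p[1] + p[2] * xi), 1e-12), 1 - 1e-12)
        ph <- exp(p[3])
        ystari <- log(yi / (1 - yi))
        mustari <- digamma(mui * ph) - digamma((1 - mui) * ph)
        wi <- mui * (1 - mui)
        g0 <- -ph * sum((ystari - mustari) * wi)
        g1 <- -ph * sum((ystari - mustari) * wi * xi)
        sp <- sum(digamma(ph) - mui * digamma(mui * ph) -
                    (1 - mui) * digamma((1 - mui) * ph) +
                    mui * log(yi) + (1 - mui) * log(1 - yi))
        c(g0, g1, -ph * sp)
      }
      start <- c(b0[row], b1[row], log(max(phi[row], 1e-2)))
      start[!is.finite(start)] <- 0
      o <- try(stats::optim(start, nll, gr, method = "BFGS",
                            control = list(maxit = 300, reltol = 1e-12)),
               silent = TRUE)
      if (!inherits(o, "try-error") && is.finite(o$value)) {
        b0[row] <- o$par[1]
        b1[row] <- o$par[2]
        phi[row] <- exp(o$par[3])
        conv[row] <- o$convergence == 0 &&
          sum(abs(gr(o$par))) < 1e-4 * (1 + abs(o$value))
      }
    }
  }
  mu <- invlogit(b0 + b1 * X)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  a <- mu * phi
  b <- (1 - mu) * phi
  ll <- rowSums(lgamma(phi) - lgamma(a) - lgamma(b) +
                  (a - 1) * logy + (b - 1) * log1y)
  w <- mu * (1 - mu)
  v <- trigamma(a) + trigamma(b)
  ww <- v * w^2
  I00 <- phi^2 * rowSums(ww)
  I01 <- phi^2 * rowSums(ww * X)
  I11 <- phi^2 * rowSums(ww * X^2)
  # beta-phi cross information and the phi block, so Wald errors come from
  # the full expected information, not the beta block alone
  cterm <- w * (mu * trigamma(a) - (1 - mu) * trigamma(b))
  c0 <- phi * rowSums(cterm)
  c1 <- phi * rowSums(cterm * X)
  Iphi <- rowSums(mu^2 * trigamma(a) + (1 - mu)^2 * trigamma(b) -
                    trigamma(phi))
  Iphi <- pmax(Iphi, 1e-12)
  A00 <- I00 - c0^2 / Iphi
  A01 <- I01 - c0 * c1 / Iphi
  A11 <- I11 - c1^2 / Iphi
  det <- pmax(A00 * A11 - A01^2, 1e-300)
  list(b0 = b0, b1 = b1, phi = phi,
       se_b0 = sqrt(A11 / det), se_b1 = sqrt(A00 / det),
       loglik = ll, converged = conv & is.finite(ll))
}

# Shared regime rule for a response-scale trend m and baseline survival S0.
classify_m <- function(m, S0) {
  ifelse(m >= 0, "compensatory_or_over",
         ifelse(m <= -S0, "additive_or_super", "partial"))
}

#' Fit a logit-link beta regression
#'
#' Maximum-likelihood fit of a beta law with mean `mu = invlogit(b0 + b1 x)`
#' and a common precision `psi`, by Fisher scoring. The convergence flag is
#' honest: a fit that has not met the tolerance is reported as such.
#'
#' @param y responses strictly inside (0, 1).
#' @param x predictor.
#' @return an object of class `beta_regression`: list with `b0`, `b1`,
#'   `psi`, Wald standard errors, `loglik`, `converged` and the observed
#'   predictor range `x_range`.
#' @export
fit_beta_regression <- function(y, x) {
  stopifnot(length(y) == length(x))
  fit <- beta_mle_matrix(matrix(y, nrow = 1), x)
  structure(list(b0 = fit$b0, b1 = fit$b1, psi = fit$phi,
                 se_b0 = fit$se_b0, se_b1 = fit$se_b1,
                 loglik = fit$loglik, converged = fit$converged,
                 x_range = range(x)),
            class = "beta_regression")
}

#' @export
print.beta_regression <- function(x, ...) {
  cat(sprintf("Beta regression (logit link): b0 = %.4g (SE %.3g), b1 = %.4g (SE %.3g), psi = %.4g%s\n",
              x$b0, x$se_b0, x$b1, x$se_b1, x$psi,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Highest-posterior-density interval from draws
#'
#' Shortest interval containing a fraction `level` of the empirical draws
#' (shortest-window method on the sorted sample).
#'
#' @param draws numeric vector (at least 100 values).
#' @param level coverage level (default 0.90).
#' @return numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(draws, level = 0.90) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100L) fail("at least 100 draws are needed for an HPD")
  s <- sort(draws)
  n <- length(s)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(s[1L], s[n]))
  widths <- s[(k + 1L):n] - s[1:(n - k)]
  i <- which.min(widths)
  c(s[i], s[i + k])
}

#' Classify a survival-regression slope against the mortality regimes
#'
#' The fitted no-hunting survival is `S0 = invlogit(b0)`. The trend of the
#' regression line on the response (rate) scale is either the secant of the
#' fitted mean curve over the observed predictor range (default; this is
#' the slope of the line as drawn in rate space) or the derivative of the
#' mean curve at predictor 0. Positive trends are compensatory or
#' overcompensatory, trends at or below `-S0` additive or superadditive,
#' anything between partially compensatory.
#'
#' @param fit a `beta_regression` (or any list with `b0`, `b1`, `x_range`).
#' @param slope `"secant"` or `"derivative"`.
#' @return list with `regime`, `m` (response-scale trend) and `S0`.
#' @export
classify_slope <- function(fit, slope = c("secant", "derivative")) {
  slope <- match.arg(slope)
  S0 <- invlogit(fit$b0)
  m <- if (slope == "derivative") {
    fit$b1 * S0 * (1 - S0)
  } else {
    xr <- fit$x_range
    if (diff(xr) <= 0) fail("degenerate predictor range for a secant slope")
    (invlogit(fit$b0 + fit$b1 * xr[2]) -
       invlogit(fit$b0 + fit$b1 * xr[1])) / diff(xr)
  }
  list(regime = classify_m(m, S0), m = m, S0 = S0)
}

COMPENSATION_HYPOTHESES <- data.frame(
  hypothesis = paste0("H", 1:6),
  response = c("survival", "survival", "natural", "natural", "nonhunting",
               "illegal"),
  predictor = c("anthropogenic", "hunting", "anthropogenic", "hunting",
                "hunting", "hunting"),
  classify = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Run the additive-versus-compensatory hypothesis tests
#'
#' For each hypothesis H1--H6 (survival or a mortality component regressed
#' on an anthropogenic or hunting mortality rate), rates are resampled
#' `n_draws` times from their moment-matched beta distributions, a beta
#' regression is fitted to every sampled data set, and the slopes are
#' summarised by their mean and highest-density interval. For H1 and H2
#' every draw's regression line is additionally classified against the
#' mortality regimes; for H3--H6 the conclusion is flagged inconclusive
#' when the HPD overlaps zero. Non-converging draws are dropped and counted.
#'
#' @param rates data frame `area`, `quantity`, `estimate`, `se` covering the
#'   quantities the hypotheses use.
#' @param n_draws resampling draws (the study-scale default is 10,000).
#' @param seed integer seed (one shared stream for all hypotheses).
#' @param level HPD level (default 0.90).
#' @param slope slope definition for regime classification, see
#'   [classify_slope()].
#' @param hypotheses which hypotheses to run (default all of H1--H6).
#' @return an object of class `compensation_result`: a list of per-hypothesis
#'   results with elements `mean_beta`, `hpd`, `regime_fractions`,
#'   `modal_regime`, `S0`, `n_effective`, `conclusive`.
#' @export
run_hypothesis_tests <- function(rates, n_draws = 10000, seed = 1,
                                 level = 0.90,
                                 slope = c("secant", "derivative"),
                                 hypotheses = paste0("H", 1:6)) {
  slope <- match.arg(slope)
  hyp <- COMPENSATION_HYPOTHESES[COMPENSATION_HYPOTHESES$hypothesis %in%
                                   hypotheses, ]
  if (nrow(hyp) == 0L) fail("no valid hypotheses requested")
  need <- unique(c(hyp$response, hyp$predictor))
  miss <- setdiff(need, unique(rates$quantity))
  if (length(miss)) fail("rate table lacks quantities: %s",
                         paste(miss, collapse = ", "))
  arr <- sample_rates(rates, n_draws = n_draws, seed = seed)
  out <- list()
  for (i in seq_len(nrow(hyp))) {
    h <- hyp[i, ]
    Y <- arr[, , h$response]
    X <- arr[, , h$predictor]
    f <- beta_mle_matrix(Y, X)
    keep <- f$converged & is.finite(f$b1)
    b0 <- f$b0[keep]
    b1 <- f$b1[keep]
    S0_draws <- invlogit(b0)
    res <- list(hypothesis = h$hypothesis, response = h$response,
                predictor = h$predictor,
                mean_beta = mean(b1),
                hpd = hpd_interval(b1, level = level),
                n_effective = sum(keep), n_draws = n_draws,
                S0 = mean(S0_draws))
    if (h$classify) {
      m <- if (slope == "derivative") {
        b1 * S0_draws * (1 - S0_draws)
      } else {
        xlo <- apply(X[keep, , drop = FALSE], 1, min)
        xhi <- apply(X[keep, , drop = FALSE], 1, max)
        (invlogit(b0 + b1 * xhi) - invlogit(b0 + b1 * xlo)) / (xhi - xlo)
      }
      fr <- prop.table(table(factor(classify_m(m, S0_draws),
                                    levels = c("compensatory_or_over",
                                               "partial",
                                               "additive_or_super"))))
      res$regime_fractions <- fr
      res$modal_regime <- names(fr)[which.max(fr)]
    } else {
      res$conclusive <- res$hpd[1] > 0 || res$hpd[2] < 0
    }
    out[[h$hypothesis]] <- res
  }
  structure(out, class = "compensation_result", level = level, seed = seed)
}

#' @export
print.compensation_result <- function(x, ...) {
  cat(sprintf("Compensation tests (%d%% HPD)\n",
              round(100 * attr(x, "level"))))
  for (h in x) {
    cat(sprintf("  %s %s ~ %s: mean beta %.3f [%.3f, %.3f]",
                h$hypothesis, h$response, h$predictor, h$mean_beta,
                h$hpd[1], h$hpd[2]))
    if (!is.null(h$regime_fractions)) {
      cat(sprintf("  comp %.0f%% / partial %.0f%% / additive %.0f%%",
                  100 * h$regime_fractions[1], 100 * h$regime_fractions[2],
                  100 * h$regime_fractions[3]))
    } else {
      cat(if (h$conclusive) "  (conclusive)" else "  (inconclusive)")
    }
    cat("\n")
  }
  invisible(x)
}

#' Tidy per-hypothesis summary
#'
#' @param object a `compensation_result`.
#' @param ... unused.
#' @return data frame, one row per hypothesis.
#' @export
summary.compensation_result <- function(object, ...) {
  do.call(rbind, lapply(object, function(h) {
    data.frame(hypothesis = h$hypothesis, response = h$response,
               predictor = h$predictor, mean_beta = h$mean_beta,
               hpd_lo = h$hpd[1], hpd_hi = h$hpd[2],
               frac_compensatory = h$regime_fractions[1] %||% NA_real_,
               frac_partial = h$regime_fractions[2] %||% NA_real_,
               frac_additive = h$regime_fractions[3] %||% NA_real_,
               n_effective = h$n_effective,
               stringsAsFactors = FALSE)
  }))
}
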