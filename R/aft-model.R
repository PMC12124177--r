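# Bayesian accelerated failure time (AFT) models for known-fate spells with
# time-varying covariates, left truncation and frailties.
#
# Model: each observation unit (an individual on the age scale; an
# individual-cycle on the recurrent annual scale) is a set of spells tiling
# [entry, exit) with piecewise-constant covariates. Covariates and the
# frailty rescale internal time,
#     tau(t) = integral_0^t exp(x(s)' beta + w) ds,
# so S(t | x, w) = S0(tau(t)) with a lognormal baseline S0 (optionally a
# piecewise-constant hazard on the accelerated time scale). Positive beta
# accelerates time and shortens survival. Time before first entry is
# accelerated at the first spell's covariates, which fixes the
# delayed-entry conditioning term S0(tau(entry)).
#
# Sampling: adaptive Metropolis-within-Gibbs. Scalar parameters use
# random-walk proposals whose scales adapt toward a target acceptance rate
# during burn-in and are frozen afterwards. Frailties are non-centred
# (w = tau * L(phi) z) and updated blockwise by a preconditioned
# Crank-Nicolson proposal, which leaves the standard-normal prior of z
# invariant; tau and the GRF decay phi get scalar random-walk updates.

#' MCMC control settings
#'
#' @param schedule `"desk"` (default: 500 burn-in, 1,500 retained draws,
#'   no thinning -- sized for tests and examples) or `"study"` (5,000
#'   burn-in, 10,000 retained draws thinned from 50,000, the full-scale
#'   schedule).
#' @param n_burn,n_iter,thin override the schedule explicitly; `n_iter` is
#'   the number of *retained* draws.
#' @param target_accept target acceptance rate for the adaptive random-walk
#'   proposals (aimed at the 20-40% band).
#' @param jitter ridge added to a non-positive-definite GRF correlation
#'   (logged on the fit object when used).
#' @return a list of class `aft_control`.
#' @export
aft_control <- function(schedule = c("desk", "study"), n_burn = NULL,
                        n_iter = NULL, thin = NULL, target_accept = 0.3,
                        jitter = 1e-8) {
  schedule <- match.arg(schedule)
  def <- if (schedule == "desk") list(n_burn = 500L, n_iter = 1500L,
                                      thin = 1L)
  else list(n_burn = 5000L, n_iter = 10000L, thin = 5L)
  structure(list(n_burn = as.integer(n_burn %||% def$n_burn),
                 n_iter = as.integer(n_iter %||% def$n_iter),
                 thin = as.integer(thin %||% def$thin),
                 target_accept = target_accept, jitter = jitter,
                 schedule = schedule),
            class = "aft_control")
}

#' Accelerated (effective) time along a spell path
#'
#' `tau(t) = sum_i exp(x_i' beta + w) dt_i` over the sub-spells up to `t`,
#' with time before the first entry accelerated at the first spell's
#' covariates. Invariant to refinement of the spell partition.
#'
#' @param pieces data frame with `entry`, `exit` and covariate columns
#'   named as in `beta`, tiling an interval without overlaps.
#' @param beta named coefficient vector (may be empty).
#' @param w frailty value (log acceleration offset).
#' @param t evaluation time(s), defaulting to the final exit.
#' @return numeric vector of accelerated times.
#' @export
effective_time <- function(pieces, beta, w = 0, t = max(pieces$exit)) {
  pieces <- pieces[order(pieces$entry), , drop = FALSE]
  if (nrow(pieces) > 1 &&
      any(pieces$entry[-1] < pieces$exit[-nrow(pieces)] - 1e-9)) {
    fail("overlapping spells")
  }
  X <- if (length(beta)) {
    as.matrix(pieces[, names(beta), drop = FALSE])
  } else {
    matrix(0, nrow(pieces), 0)
  }
  rate <- exp(as.numeric(X %*% beta) + w)
  vapply(t, function(ti) {
    dur <- pmax(pmin(pieces$exit, ti) - pieces$entry, 0)
    pieces$entry[1] * rate[1] + sum(rate * dur)
  }, numeric(1))
}

# Build the internal representation the likelihood consumes. `unit` is the
# likelihood unit (individual, or individual-cycle on the annual scale);
# `group` the frailty grouping.
aft_prepare <- function(formula, data, unit = NULL, group = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "counting") {
    fail("the left-hand side must be Surv(entry, exit, event)")
  }
  entry <- y[, 1L]
  exit <- y[, 2L]
  event <- y[, 3L]
  if (any(exit <= entry)) fail("exit <= entry in spells")
  X <- stats::model.matrix(stats::terms(formula), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) > 0 && nrow(X) >= ncol(X) && qr(X)$rank < ncol(X)) {
    fail("design matrix is rank deficient; model not identifiable")
  }
  # standardize continuous (non-indicator) columns
  is_dummy <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  ctr <- ifelse(is_dummy, 0, colMeans(X))
  scl <- ifelse(is_dummy, 1, apply(X, 2, stats::sd))
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  unit <- if (is.null(unit)) rep("u", nrow(X)) else as.character(unit)
  if (length(unit) != nrow(Xs)) fail("unit length mismatch")
  ord <- order(unit, entry)
  unit <- unit[ord]
  uf <- factor(unit, levels = unique(unit))
  uidx <- as.integer(uf)
  n_unit <- nlevels(uf)
  first <- match(seq_len(n_unit), uidx)
  last <- length(uidx) + 1L - match(seq_len(n_unit), rev(uidx))
  group <- if (is.null(group)) unit else as.character(group)[ord]
  gf <- factor(group, levels = unique(group))
  ev_unit <- event[ord][last]
  if (any(tapply(event[ord], uidx, sum) > 1)) {
    fail("a unit carries more than one event")
  }
  list(X = Xs[ord, , drop = FALSE], entry = entry[ord], exit = exit[ord],
       event = event[ord], uidx = uidx, n_unit = n_unit, first = first,
       last = last, ev_unit = ev_unit, gidx = as.integer(gf),
       groups = levels(gf), unit_ids = levels(uf),
       center = ctr, scale = scl, terms = stats::terms(formula))
}

# log f0 / log S0 of the baseline on the accelerated scale.
baseline_logf <- function(tau, base) {
  if (base$type == "lognormal") {
    stats::dlnorm(tau, base$mu0, base$sigma0, log = TRUE)
  } else {
    i <- findInterval(tau, base$knots, rightmost.closed = FALSE) + 1L
    log(base$lambda[i]) + baseline_logS(tau, base)
  }
}

baseline_logS <- function(tau, base) {
  if (base$type == "lognormal") {
    stats::plnorm(tau, base$mu0, base$sigma0, lower.tail = FALSE,
                  log.p = TRUE)
  } else {
    bounds <- c(0, base$knots, Inf)
    i <- findInterval(tau, base$knots) + 1L
    cum0 <- c(0, cumsum(base$lambda[-length(base$lambda)] *
                          diff(c(0, base$knots))))
    -(cum0[i] + base$lambda[i] * (tau - bounds[i]))
  }
}

#' Known-fate AFT log-likelihood
#'
#' Per unit: an event contributes `log f0(tau(exit)) + x(exit)'beta + w`,
#' a censored unit `log S0(tau(exit))`; both are conditioned on survival to
#' entry by subtracting `log S0(tau(entry))`.
#'
#' @param prep internal data representation (from the fitting routine).
#' @param beta coefficient vector (standardized scale).
#' @param base baseline parameter list (`type = "lognormal"` with `mu0`,
#'   `sigma0`, or `type = "piecewise"` with `knots`, `lambda`).
#' @param w frailty values per group (zeros when absent).
#' @return list with `total` and `by_unit`.
#' @keywords internal
aft_loglik <- function(prep, beta, base, w = NULL) {
  wv <- if (is.null(w)) rep(0, length(prep$groups)) else w
  eta <- (if (ncol(prep$X)) as.numeric(prep$X %*% beta) else 0) +
    wv[prep$gidx]
  rate <- exp(eta)
  contrib <- rate * (prep$exit - prep$entry)
  tau_exit <- rowsum(contrib, prep$uidx, reorder = TRUE)[, 1L]
  tau_entry <- prep$entry[prep$first] * rate[prep$first]
  tau_exit <- tau_exit + tau_entry
  ll <- ifelse(prep$ev_unit == 1,
               baseline_logf(tau_exit, base) + eta[prep$last],
               baseline_logS(tau_exit, base))
  cond <- ifelse(tau_entry > 0, baseline_logS(tau_entry, base), 0)
  by_unit <- ll - cond
  list(total = sum(by_unit), by_unit = by_unit)
}

#' Frailty log-prior density
#'
#' IID frailties are independent `Normal(0, tau^2)` per group; Gaussian
#' random field (GRF) frailties are jointly normal with correlation
#' `exp(-phi d_ij)` between groups at distance `d_ij` km. A
#' non-positive-definite correlation is ridged with a small jitter.
#'
#' @param w frailty values.
#' @param tau frailty standard deviation (so `tau^2` is the frailty
#'   variance).
#' @param coords two-column matrix of group coordinates in km (GRF only).
#' @param phi exponential decay rate per km (GRF only).
#' @param jitter ridge added to the correlation diagonal if needed.
#' @return the log-density of `w`.
#' @export
frailty_prior <- function(w, tau, coords = NULL, phi = NULL,
                          jitter = 1e-8) {
  if (is.null(coords)) {
    return(sum(stats::dnorm(w, 0, tau, log = TRUE)))
  }
  R <- grf_correlation(coords, phi)
  ch <- tryCatch(chol(R), error = function(e) chol(R + jitter * diag(nrow(R))))
  z <- backsolve(ch, w, transpose = TRUE)
  -0.5 * sum(z^2) / tau^2 - sum(log(diag(ch))) -
    length(w) * log(tau) - 0.5 * length(w) * log(2 * pi)
}

#' GRF correlation matrix
#'
#' `R_ij = exp(-phi d_ij)` with distances in km; the correlation between
#' two groups drops by `1 - exp(-phi d)` over a distance `d`.
#'
#' @param coords two-column matrix of coordinates (km).
#' @param phi decay rate per km (> 0).
#' @return correlation matrix.
#' @export
grf_correlation <- function(coords, phi) {
  if (phi <= 0) fail("phi must be positive")
  R <- exp(-phi * as.matrix(stats::dist(coords)))
  dimnames(R) <- NULL
  R
}

#' Fit a Bayesian AFT model by adaptive MCMC
#'
#' @param formula model formula with a counting-process response,
#'   `Surv(entry, exit, event) ~ covariates`. Continuous covariates are
#'   standardized internally; coefficients are reported per standardized
#'   unit.
#' @param data spell data frame (one row per sub-spell).
#' @param unit observation-unit identifier (one survival experience per
#'   unit): the individual id on the age scale, the individual-cycle on the
#'   annual scale. Defaults to treating all rows as one unit per
#'   `id` column if present.
#' @param frailty `"none"`, `"iid"` or `"grf"`.
#' @param group frailty grouping vector (defaults to `unit`); for `"grf"`
#'   the groups must match rows of `coords`.
#' @param coords data frame or matrix with group coordinates in km (GRF
#'   only), ordered as `sort(unique(group))` or named by group via an `id`
#'   column.
#' @param baseline `"lognormal"` (default) or `"piecewise"` (piecewise-
#'   constant hazard on the accelerated scale, knots at data quantiles).
#' @param n_knots knots for the piecewise baseline.
#' @param priors list with `beta_sd` (default 10), `mu0_sd` (10),
#'   `logsigma_sd` (10), `tau_halfnormal_sd` (1), `phi_range` (decay per km,
#'   default `c(0.001, 1)`, i.e. 1--1,000 km).
#' @param control an [aft_control()].
#' @param seed integer seed; chains are reproducible.
#' @return an object of class `aft_fit`.
#' @export
aft_fit <- function(formula, data, unit = NULL,
                    frailty = c("none", "iid", "grf"), group = NULL,
                    coords = NULL, baseline = c("lognormal", "piecewise"),
                    n_knots = 8, priors = list(), control = aft_control(),
                    seed = 1) {
  frailty <- match.arg(frailty)
  baseline <- match.arg(baseline)
  pr <- utils::modifyList(list(beta_sd = 10, mu0_sd = 10, logsigma_sd = 10,
                               tau_halfnormal_sd = 1,
                               phi_range = c(0.001, 1)), priors)
  if (is.null(unit) && !is.null(data$id)) unit <- data$id
  if (frailty != "none" && is.null(group)) group <- unit
  prep <- aft_prepare(formula, data, unit = unit,
                      group = if (frailty == "none") NULL else group)
  G <- length(prep$groups)
  p <- ncol(prep$X)

  cmat <- NULL
  if (frailty == "grf") {
    if (is.null(coords)) fail("GRF frailty needs coords")
    cm <- as.data.frame(coords)
    if (!is.null(cm$id)) {
      rows <- match(prep$groups, as.character(cm$id))
      if (anyNA(rows)) fail("coords missing for group(s): %s",
                            paste(prep$groups[is.na(rows)], collapse = ", "))
      cmat <- as.matrix(cm[rows, c("x", "y")])
    } else {
      if (nrow(cm) != G) fail("coords must have one row per group")
      cmat <- as.matrix(cm[, 1:2])
    }
  }

  # ---- phase 1: parametric centering (lognormal ML with no frailty) ----
  obj <- function(par) {
    b <- par[seq_len(p)]
    base <- list(type = "lognormal", mu0 = par[p + 1],
                 sigma0 = exp(par[p + 2]))
    ll <- aft_loglik(prep, b, base)$total
    lp <- sum(stats::dnorm(b, 0, pr$beta_sd, log = TRUE)) +
      stats::dnorm(par[p + 1], 0, pr$mu0_sd, log = TRUE) +
      stats::dnorm(par[p + 2], 0, pr$logsigma_sd, log = TRUE)
    if (!is.finite(ll)) return(1e10)
    -(ll + lp)
  }
  start <- c(rep(0, p), log(stats::median(prep$exit[prep$last])), 0)
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 300))

  base <- list(type = baseline, mu0 = opt$par[p + 1],
               sigma0 = exp(opt$par[p + 2]))
  if (baseline == "piecewise") {
    # knots at quantiles of the accelerated exit times under the centering fit
    b0 <- opt$par[seq_len(p)]
    eta0 <- if (p) as.numeric(prep$X %*% b0) else rep(0, length(prep$exit))
    te <- rowsum(exp(eta0) * (prep$exit - prep$entry), prep$uidx)[, 1L]
    base$knots <- unname(stats::quantile(te, probs = seq_len(n_knots - 1) /
                                           n_knots))
    lam0 <- 1 / mean(te)
    base$lambda <- rep(lam0, n_knots)
  }

  # ---- phase 2: adaptive MCMC ----
  ctl <- control
  n_scan <- ctl$n_burn + ctl$n_iter * ctl$thin
  beta <- opt$par[seq_len(p)]
  mu0 <- base$mu0
  logs0 <- log(base$sigma0)
  loglam <- if (baseline == "piecewise") log(base$lambda) else numeric(0)
  tau <- 0.5
  logphi <- if (frailty == "grf") mean(log(pr$phi_range)) else NA_real_
  z <- rep(0, if (frailty == "none") 0 else G)
  Lr <- if (frailty == "grf") {
    R <- grf_correlation(cmat, exp(logphi))
    t(tryCatch(chol(R), error = function(e)
      chol(R + ctl$jitter * diag(G))))
  } else NULL
  w_of <- function() {
    if (frailty == "none") NULL
    else if (frailty == "iid") tau * z
    else tau * as.numeric(Lr %*% z)
  }
  cur_base <- function() {
    if (baseline == "lognormal") list(type = "lognormal", mu0 = mu0,
                                      sigma0 = exp(logs0))
    else list(type = "piecewise", knots = base$knots, lambda = exp(loglam))
  }
  ll_cur <- aft_loglik(prep, beta, cur_base(), w_of())

  n_par <- p + 2 + length(loglam)
  ls_prop <- rep(log(0.1), n_par)      # scalar proposal log-sds
  ls_pcn <- log(0.5)                   # pCN step for z
  ls_tau <- log(0.3)
  ls_phi <- log(0.5)
  acc <- rep(0, n_par)
  acc_z <- acc_tau <- acc_phi <- 0
  n_acc_window <- 50L
  jitter_used <- FALSE

  keep <- matrix(NA_real_, ctl$n_iter,
                 n_par + 2 + (frailty == "grf"))
  parnames <- c(colnames(prep$X), "mu0", "log_sigma0",
                if (baseline == "piecewise") paste0("log_lambda",
                                                    seq_along(loglam)),
                "tau", if (frailty == "grf") "phi", "loglik")
  colnames(keep) <- parnames
  ll_unit_keep <- matrix(NA_real_, ctl$n_iter, prep$n_unit)
  w_keep <- if (frailty == "none") NULL else
    matrix(NA_real_, ctl$n_iter, G, dimnames = list(NULL, prep$groups))

  logprior_scalar <- function(j, val) {
    if (j <= p) stats::dnorm(val, 0, pr$beta_sd, log = TRUE)
    else if (j == p + 1) stats::dnorm(val, 0, pr$mu0_sd, log = TRUE)
    else if (j == p + 2) stats::dnorm(val, 0, pr$logsigma_sd, log = TRUE)
    else stats::dnorm(val, 0, 10, log = TRUE)  # log piecewise hazards
  }
  get_par <- function(j) {
    if (j <= p) beta[j]
    else if (j == p + 1) mu0
    else if (j == p + 2) logs0
    else loglam[j - p - 2]
  }
  set_par <- function(j, val) {
    if (j <= p) beta[j] <<- val
    else if (j == p + 1) mu0 <<- val
    else if (j == p + 2) logs0 <<- val
    else loglam[j - p - 2] <<- val
  }

  with_seed(seed, {
    kept <- 0L
    for (s in seq_len(n_scan)) {
      adapting <- s <= ctl$n_burn
      # scalar parameters
      for (j in seq_len(n_par)) {
        old <- get_par(j)
        newv <- old + stats::rnorm(1, 0, exp(ls_prop[j]))
        set_par(j, newv)
        ll_new <- aft_loglik(prep, beta, cur_base(), w_of())
        lr <- ll_new$total - ll_cur$total +
          logprior_scalar(j, newv) - logprior_scalar(j, old)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          ll_cur <- ll_new
          acc[j] <- acc[j] + 1
        } else {
          set_par(j, old)
        }
      }
      if (frailty != "none") {
        # whitened frailty block: preconditioned Crank-Nicolson
        rho <- min(exp(ls_pcn), 0.999)
        z_new <- sqrt(1 - rho^2) * z + rho * stats::rnorm(G)
        z_old <- z
        z <- z_new
        ll_new <- aft_loglik(prep, beta, cur_base(), w_of())
        if (is.finite(ll_new$total) &&
            log(stats::runif(1)) < ll_new$total - ll_cur$total) {
          ll_cur <- ll_new
          acc_z <- acc_z + 1
        } else {
          z <- z_old
        }
        # frailty scale tau (half-normal prior)
        tau_new <- tau * exp(stats::rnorm(1, 0, exp(ls_tau)))
        old_tau <- tau
        tau <- tau_new
        ll_new <- aft_loglik(prep, beta, cur_base(), w_of())
        lr <- ll_new$total - ll_cur$total +
          stats::dnorm(tau_new, 0, pr$tau_halfnormal_sd, log = TRUE) -
          stats::dnorm(old_tau, 0, pr$tau_halfnormal_sd, log = TRUE) +
          log(tau_new) - log(old_tau)  # log-scale proposal Jacobian
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          ll_cur <- ll_new
          acc_tau <- acc_tau + 1
        } else {
          tau <- old_tau
        }
        if (frailty == "grf") {
          phi_new <- logphi + stats::rnorm(1, 0, exp(ls_phi))
          if (phi_new >= log(pr$phi_range[1]) &&
              phi_new <= log(pr$phi_range[2])) {
            old_phi <- logphi
            old_L <- Lr
            logphi <- phi_new
            R <- grf_correlation(cmat, exp(logphi))
            Lr <- t(tryCatch(chol(R), error = function(e) {
              jitter_used <<- TRUE
              chol(R + ctl$jitter * diag(G))
            }))
            ll_new <- aft_loglik(prep, beta, cur_base(), w_of())
            if (is.finite(ll_new$total) &&
                log(stats::runif(1)) < ll_new$total - ll_cur$total) {
              ll_cur <- ll_new
              acc_phi <- acc_phi + 1
            } else {
              logphi <- old_phi
              Lr <- old_L
            }
          }
        }
      }
      # diminishing adaptation during burn-in only
      if (adapting && s %% n_acc_window == 0L) {
        gain <- min(0.25, 5 / sqrt(s))
        ls_prop <- ls_prop + gain * (acc / n_acc_window - ctl$target_accept)
        acc[] <- 0
        if (frailty != "none") {
          ls_pcn <- min(ls_pcn + gain * (acc_z / n_acc_window -
                                           ctl$target_accept), log(0.999))
          ls_tau <- ls_tau + gain * (acc_tau / n_acc_window -
                                       ctl$target_accept)
          if (frailty == "grf") {
            ls_phi <- ls_phi + gain * (acc_phi / n_acc_window -
                                         ctl$target_accept)
            acc_phi <- 0
          }
          acc_z <- acc_tau <- 0
        }
      }
      if (!is.finite(ll_cur$total)) {
        fail("divergence: non-finite log-likelihood at scan %d", s)
      }
      if (s > ctl$n_burn && (s - ctl$n_burn) %% ctl$thin == 0L) {
        kept <- kept + 1L
        row <- c(beta, mu0, logs0, loglam, tau,
                 if (frailty == "grf") exp(logphi), ll_cur$total)
        keep[kept, ] <- row
        ll_unit_keep[kept, ] <- ll_cur$by_unit
        if (frailty != "none") w_keep[kept, ] <- w_of()
      }
    }
  })

  out <- list(draws = as.data.frame(keep), w_draws = w_keep,
              ll_unit = ll_unit_keep, prep = prep, frailty = frailty,
              baseline = baseline, base_knots = base$knots,
              coords = cmat, control = ctl, seed = seed,
              centering = list(par = opt$par, value = -opt$value),
              priors = pr, jitter_used = jitter_used,
              acceptance = list(scalars = NA),
              formula = formula, call = match.call())
  class(out) <- "aft_fit"
  out
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("Bayesian AFT fit (%s baseline, %s frailty): %d units, %d spells\n",
              x$baseline, x$frailty, x$prep$n_unit, length(x$prep$exit)))
  cat(sprintf("  %d retained draws (burn-in %d, thin %d)\n",
              nrow(x$draws), x$control$n_burn, x$control$thin))
  b <- coef(x)
  if (length(b)) {
    cat("  posterior mean coefficients (standardized units):\n")
    for (n in names(b)) cat(sprintf("    %-24s %8.3f\n", n, b[n]))
  }
  invisible(x)
}

#' @export
coef.aft_fit <- function(object, ...) {
  p <- ncol(object$prep$X)
  if (p == 0) return(numeric(0))
  colMeans(object$draws[, seq_len(p), drop = FALSE])
}

#' Posterior summary with evidence ratios
#'
#' One row per coefficient: posterior mean, equal-tail credible interval,
#' the one-sided test direction implied by the sign of the mean, and its
#' evidence ratio and posterior probability.
#'
#' @param object an `aft_fit`.
#' @param level credible level (default 0.90, as reported).
#' @param ... unused.
#' @return data frame summary.
#' @export
summary.aft_fit <- function(object, level = 0.90, ...) {
  a <- (1 - level) / 2
  p <- ncol(object$prep$X)
  rows <- lapply(colnames(object$draws), function(n) {
    d <- object$draws[[n]]
    r <- data.frame(term = n, estimate = mean(d),
                    lcl = stats::quantile(d, a),
                    ucl = stats::quantile(d, 1 - a),
                    test = NA_character_, evidence = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
    if (n %in% colnames(object$prep$X)) {
      dir <- if (mean(d) >= 0) "greater" else "less"
      er <- evidence_ratio(d, direction = dir)
      r$test <- sprintf("%s 0", if (dir == "greater") ">" else "<")
      r$evidence <- er$er
      r$p <- er$p
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}

#' @export
plot.aft_fit <- function(x, which = NULL, ...) {
  nm <- which %||% setdiff(colnames(x$draws), "loglik")
  nm <- intersect(nm, colnames(x$draws))
  op <- graphics::par(mfrow = c(min(length(nm), 3), 1),
                      mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (n in nm[seq_len(min(length(nm), 3))]) {
    graphics::plot(x$draws[[n]], type = "l", ylab = n, xlab = "draw")
  }
  invisible(x)
}

#' Posterior predictive survival curve
#'
#' Baseline-scale survival `S0(tau(t))` at the posterior means, for a
#' constant covariate row.
#'
#' @param object an `aft_fit`.
#' @param newdata one-row data frame of covariates (original scale);
#'   omitted covariates sit at their standardization centre.
#' @param times evaluation times.
#' @param ... unused.
#' @return data frame with `time` and `surv`.
#' @export
predict.aft_fit <- function(object, newdata = NULL, times, ...) {
  p <- ncol(object$prep$X)
  b <- coef(object)
  xrow <- rep(0, p)
  if (!is.null(newdata) && p > 0) {
    mm <- stats::model.matrix(stats::delete.response(object$prep$terms),
                              newdata)
    mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    xrow <- (as.numeric(mm[1, colnames(object$prep$X)]) -
               object$prep$center) / object$prep$scale
  }
  base <- fitted_baseline(object)
  rate <- exp(sum(xrow * b))
  data.frame(time = times,
             surv = exp(baseline_logS(times * rate, base)))
}

fitted_baseline <- function(fit) {
  d <- fit$draws
  if (fit$baseline == "lognormal") {
    list(type = "lognormal", mu0 = mean(d$mu0),
         sigma0 = exp(mean(d$log_sigma0)))
  } else {
    lam <- exp(colMeans(d[, grep("^log_lambda", colnames(d)), drop = FALSE]))
    list(type = "piecewise", knots = fit$base_knots, lambda = unname(lam))
  }
}
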