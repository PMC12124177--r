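# Nonparametric survival and cause-specific cumulative incidence with left
# truncation (delayed entry) and competing risks.
#
# Survival uses the product-limit (Kaplan-Meier) estimator with counting-
# process risk sets {entry < t <= exit}. Cumulative incidence uses a
# weighted product-limit estimator of the subdistribution: subjects who
# failed from a competing cause remain in the cause-specific risk set with a
# time-dependent weight derived from the product-limit estimates of the
# censoring and truncation distributions, which makes the estimator
# algebraically identical to Aalen-Johansen (the property the tests assert).

#' Kaplan-Meier survival with delayed entry
#'
#' Product-limit estimator on counting-process spells: the risk set at time
#' t is every spell with `entry < t <= exit`, so left-truncated individuals
#' contribute only after they enter observation. Ties follow the standard
#' convention (deaths at a tied time aggregated, censorings after deaths).
#'
#' @param spells data frame with numeric `entry`, `exit` and 0/1 `event`
#'   columns (one row per spell; multi-row individuals are fine because KM
#'   only sees risk-set membership).
#' @param group optional label stored on the curve.
#' @param conf_level confidence level for the complementary log-log
#'   (Greenwood-based) interval. Default 0.95.
#' @return an object of class `survcurve`: a data frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `se`, `lcl`, `ucl`.
#' @export
km_survival <- function(spells, group = NULL, conf_level = 0.95) {
  if (is.null(spells) || nrow(spells) == 0L) fail("empty group: no spells")
  stopifnot(all(c("entry", "exit", "event") %in% names(spells)))
  if (any(spells$exit <= spells$entry)) fail("exit <= entry in spells")
  fit <- survival::survfit(
    survival::Surv(entry, exit, event) ~ 1,
    data = spells, conf.type = "log-log", conf.int = conf_level
  )
  out <- data.frame(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    se = fit$surv * fit$std.err,
    lcl = fit$lower,
    ucl = fit$upper
  )
  ev <- out$n_event > 0
  if (any(ev) && any(out$surv[ev] <= 0 & out$time[ev] < max(out$time[ev]))) {
    warning("risk set exhausted before the last event time; ",
            "later estimates are degenerate", call. = FALSE)
  }
  structure(out, group = group, conf_level = conf_level,
            class = c("survcurve", "data.frame"))
}

#' @export
print.survcurve <- function(x, ...) {
  g <- attr(x, "group")
  cat("Kaplan-Meier survival curve",
      if (!is.null(g)) sprintf(" [%s]", g), "\n", sep = "")
  cat(sprintf("  %d time points, %d events, final S(t) = %.3f\n",
              nrow(x), sum(x$n_event), x$surv[nrow(x)]))
  invisible(x)
}

#' @export
plot.survcurve <- function(x, xlab = "time", ylab = "survival", ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1),
                 main = attr(x, "group") %||% "", ...)
  graphics::lines(stats::stepfun(x$time, c(1, x$lcl)), do.points = FALSE,
                  lty = 2)
  graphics::lines(stats::stepfun(x$time, c(1, x$ucl)), do.points = FALSE,
                  lty = 2)
  invisible(x)
}

#' Step-function lookup
#'
#' Value of a right-continuous step curve at arbitrary times; `before` is
#' returned for times earlier than the first step.
#'
#' @param times,values step positions and values.
#' @param t query times.
#' @param before value before the first step (1 for survival curves).
#' @return numeric vector.
#' @export
step_lookup <- function(times, values, t, before = 1) {
  vapply(t, function(ti) {
    i <- findInterval(ti, times)
    if (i == 0L) before else values[i]
  }, numeric(1))
}

#' Median survival time with confidence interval
#'
#' The median is the smallest time at which the survival estimate reaches
#' 0.5 or below; its confidence interval is read off where the pointwise
#' confidence bands cross 0.5 (band-crossing rule). `NA` where the curve
#' (or a band) never reaches 0.5.
#'
#' @param curve a `survcurve` from [km_survival()].
#' @return a list with elements `median`, `lcl`, `ucl` (times, `NA` if
#'   undefined).
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "survcurve"))
  cross <- function(v) {
    i <- which(v <= 0.5)
    if (length(i)) curve$time[min(i)] else NA_real_
  }
  # the lower band reaches 0.5 earliest -> earliest plausible median
  list(median = cross(curve$surv), lcl = cross(curve$lcl),
       ucl = cross(curve$ucl))
}

#' Conditional survival
#'
#' Probability of surviving to `t` given survival to `s`, i.e. S(t)/S(s)
#' from a fitted curve.
#'
#' @param curve a `survcurve`.
#' @param s,t times with `s <= t`.
#' @return numeric conditional survival probability.
#' @export
conditional_survival <- function(curve, s, t) {
  stopifnot(inherits(curve, "survcurve"), s <= t)
  Ss <- step_lookup(curve$time, curve$surv, s)
  if (Ss == 0) fail("S(s) = 0: conditional survival undefined")
  step_lookup(curve$time, curve$surv, t) / Ss
}

# Risk-set size at each time in `at` for counting-process spells.
risk_set_size <- function(spells, at) {
  vapply(at, function(t) sum(spells$entry < t & spells$exit >= t), numeric(1))
}

#' Cause-specific cumulative incidence under competing risks
#'
#' Weighted product-limit estimation of the cumulative incidence function
#' (CIF) of each mortality cause, with left truncation. For the cause under
#' analysis, individuals who failed from a competing cause stay in the risk
#' set beyond their failure with a time-dependent weight obtained from
#' product-limit estimates of the censoring and truncation distributions; the
#' weighted risk set at a cause-k event time s equals
#' n(s) (1 - F_k(s-)) / S(s-), which makes the estimator exactly equal to
#' the Aalen-Johansen estimator on the same data.
#'
#' @param spells data frame with `entry`, `exit`, `event` and `cause`
#'   (cause required on event rows).
#' @param causes optional character vector of admissible causes; event causes
#'   outside this set raise an error. Defaults to the causes observed.
#' @param group optional label stored on the curves.
#' @param conf_level confidence level for the log(-log)-transformed interval.
#' @return an object of class `cifcurve`: a data frame with columns `cause`,
#'   `time`, `cif`, `se`, `lcl`, `ucl`, `n_risk`, `n_weighted`, plus the
#'   overall KM survival as attribute `km` (a `survcurve`).
#' @export
cif_competing <- function(spells, causes = NULL, group = NULL,
                          conf_level = 0.95) {
  if (is.null(spells) || nrow(spells) == 0L) fail("empty group: no spells")
  # snap nearly-equal floating-point times exactly as survfit's timefix does,
  # so tie conventions agree with the product-limit survival estimate
  snapped <- survival::aeqSurv(
    survival::Surv(spells$entry, spells$exit, spells$event))
  spells$entry <- snapped[, 1L]
  spells$exit <- snapped[, 2L]
  ev <- spells$event == 1
  obs_causes <- unique(spells$cause[ev])
  if (is.null(causes)) causes <- sort(obs_causes)
  extra <- setdiff(obs_causes, causes)
  if (length(extra)) fail("cause label(s) outside the configured set: %s",
                          paste(extra, collapse = ", "))
  times <- sort(unique(spells$exit[ev]))
  n <- risk_set_size(spells, times)
  d_k <- sapply(causes, function(k) {
    vapply(times, function(t) sum(ev & spells$exit == t & spells$cause == k),
           numeric(1))
  })
  d_k <- matrix(d_k, nrow = length(times),
                dimnames = list(NULL, causes))
  d <- rowSums(d_k)

  K <- length(causes)
  S_prev <- 1
  Fk <- matrix(0, length(times), K, dimnames = list(NULL, causes))
  n_tilde <- matrix(NA_real_, length(times), K, dimnames = list(NULL, causes))
  varterm <- rep(0, K)
  vark <- matrix(0, length(times), K)
  Fk_prev <- rep(0, K)
  for (i in seq_along(times)) {
    # weighted (subdistribution) risk set per cause
    n_tilde[i, ] <- n[i] * (1 - Fk_prev) / S_prev
    jump <- S_prev * d_k[i, ] / n[i]
    Fk[i, ] <- Fk_prev + jump
    # weighted Greenwood accumulation on the subdistribution scale
    inc <- ifelse(d_k[i, ] > 0 & n_tilde[i, ] > d_k[i, ],
                  d_k[i, ] / (n_tilde[i, ] * (n_tilde[i, ] - d_k[i, ])), 0)
    varterm <- varterm + inc
    vark[i, ] <- (1 - Fk[i, ])^2 * varterm
    Fk_prev <- Fk[i, ]
    S_prev <- S_prev * (1 - d[i] / n[i])
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- do.call(rbind, lapply(seq_len(K), function(j) {
    G <- 1 - Fk[, j]  # subdistribution "survival"
    se <- sqrt(vark[, j])
    # log(-log) interval on G keeps the CIF inside [0, 1]
    ok <- G > 0 & G < 1 & se > 0
    lcl <- ucl <- rep(NA_real_, length(G))
    theta <- rep(NA_real_, length(G))
    theta[ok] <- z * se[ok] / (G[ok] * log(G[ok]))
    lcl[ok] <- 1 - G[ok]^exp(-theta[ok])
    ucl[ok] <- 1 - G[ok]^exp(theta[ok])
    lcl[!ok] <- Fk[!ok, j]
    ucl[!ok] <- Fk[!ok, j]
    data.frame(cause = causes[j], time = times, cif = Fk[, j], se = se,
               lcl = pmin(lcl, ucl), ucl = pmax(lcl, ucl),
               n_risk = n, n_weighted = n_tilde[, j])
  }))
  rownames(out) <- NULL
  structure(out, group = group, conf_level = conf_level,
            km = km_survival(spells, group = group, conf_level = conf_level),
            class = c("cifcurve", "data.frame"))
}

#' @export
print.cifcurve <- function(x, ...) {
  g <- attr(x, "group")
  cat("Cumulative incidence curves",
      if (!is.null(g)) sprintf(" [%s]", g), "\n", sep = "")
  for (k in unique(x$cause)) {
    xi <- x[x$cause == k, ]
    cat(sprintf("  %-14s final CIF = %.3f (%d events)\n", k,
                xi$cif[nrow(xi)], sum(xi$n_risk > 0 & c(TRUE, rep(TRUE, nrow(xi) - 1)))))
  }
  invisible(x)
}

#' @export
plot.cifcurve <- function(x, xlab = "time", ylab = "cumulative incidence", ...) {
  ks <- unique(x$cause)
  graphics::plot(NULL, xlim = range(0, x$time), ylim = c(0, max(x$ucl, x$cif)),
                 xlab = xlab, ylab = ylab, main = attr(x, "group") %||% "")
  for (j in seq_along(ks)) {
    xi <- x[x$cause == ks[j], ]
    graphics::lines(stats::stepfun(xi$time, c(0, xi$cif)), do.points = FALSE,
                    col = j)
  }
  graphics::legend("topleft", legend = ks, col = seq_along(ks), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Time-dependent truncation and censoring weights
#'
#' Product-limit estimates of the censoring survival G(t) (tracking ends
#' without death) and of the entry-time distribution H(t) (left truncation),
#' evaluated at each spell's exit. These are the ingredients of the weighted
#' product-limit CIF: a competing-cause failure at time u re-enters the
#' cause-specific risk set at a later time s with relative weight
#' [G(s-) H(s)] / [G(u-) H(u)].
#'
#' @param spells data frame with `entry`, `exit`, `event`.
#' @return the spells with columns `cens_weight` (G at exit-) and
#'   `trunc_weight` (H at exit) appended.
#' @export
weighted_records <- function(spells) {
  ev_t <- sort(unique(spells$exit[spells$event == 0]))
  n_c <- risk_set_size(spells, ev_t)
  d_tot <- vapply(ev_t, function(t) sum(spells$exit == t & spells$event == 1),
                  numeric(1))
  d_c <- vapply(ev_t, function(t) sum(spells$exit == t & spells$event == 0),
                numeric(1))
  # censorings processed after deaths at tied times
  G <- cumprod(1 - d_c / pmax(n_c - d_tot, 1))
  entries <- sort(unique(spells$entry), decreasing = TRUE)
  # reverse product-limit over entry times: H(t) = P(entry <= t)
  m <- vapply(entries, function(l) sum(spells$entry <= l & spells$exit >= l),
              numeric(1))
  a <- vapply(entries, function(l) sum(spells$entry == l), numeric(1))
  Hrev <- cumprod(1 - a / pmax(m, 1))
  H_at <- function(t) {
    later <- entries > t
    if (!any(later)) 1 else prod(1 - a[later] / pmax(m[later], 1))
  }
  eps <- min(diff(sort(unique(c(spells$entry, spells$exit))))) / 2
  spells$cens_weight <- step_lookup(ev_t, G, spells$exit - eps, before = 1)
  spells$trunc_weight <- vapply(spells$exit, H_at, numeric(1))
  spells
}

#' Annual survival and cause-specific mortality rates by group
#'
#' One-cycle (365-day) Kaplan-Meier survival and cumulative incidence
#' point estimates with standard errors on the recurrent annual time scale,
#' for each combination of the grouping columns. Broad cause groups (e.g.
#' anthropogenic = illegal + legal hunting + vehicle) are obtained by summing
#' the member-cause CIFs, with delta-method standard errors assuming
#' independence between member causes within a group.
#'
#' @param spells annual-scale spell data frame (see [build_annual_scale()];
#'   run [assign_age_class()] first if grouping on age class).
#' @param areas optional data frame with `id`, `management`, joined on
#'   `study_area` to provide a `management` column.
#' @param by character vector of grouping columns present in the spells.
#' @param cause_groups named list of cause vectors to aggregate.
#' @param time evaluation horizon in days (default 365).
#' @param empty `"error"` (default) to fail on a grouping cell with no
#'   exposure, or `"drop"` to omit such cells.
#' @return data frame with grouping columns, `quantity`, `estimate`, `se`,
#'   `lcl`, `ucl`, `n_events`.
#' @export
annual_rates <- function(spells, areas = NULL,
                         by = c("age_class", "sex", "management"),
                         cause_groups = list(
                           anthropogenic = c("illegal", "legal_hunting", "vehicle"),
                           nonhunting = c("natural", "illegal", "vehicle", "unknown")
                         ),
                         time = 365, empty = c("error", "drop")) {
  empty <- match.arg(empty)
  if (!is.null(areas)) {
    spells$management <- areas$management[match(spells$study_area, areas$id)]
  }
  miss <- setdiff(by, names(spells))
  if (length(miss)) fail("grouping column(s) absent from spells: %s",
                         paste(miss, collapse = ", "))
  key <- interaction(spells[by], drop = FALSE, sep = "|")
  cells <- levels(key)
  rows <- list()
  for (cell in cells) {
    sub <- spells[key == cell, , drop = FALSE]
    labs <- strsplit(cell, "|", fixed = TRUE)[[1]]
    if (nrow(sub) == 0L) {
      if (empty == "error") fail("no exposure in group %s", cell)
      next
    }
    km <- km_survival(sub)
    Sv <- step_lookup(km$time, km$surv, time)
    Sse <- step_lookup(km$time, km$se, time, before = 0)
    Sl <- step_lookup(km$time, km$lcl, time, before = NA_real_)
    Su <- step_lookup(km$time, km$ucl, time, before = NA_real_)
    base <- stats::setNames(as.data.frame(as.list(labs),
                                          stringsAsFactors = FALSE), by)
    rows[[length(rows) + 1L]] <- cbind(base, data.frame(
      quantity = "survival", estimate = Sv, se = Sse, lcl = Sl, ucl = Su,
      n_events = sum(sub$event)))
    if (any(sub$event == 1)) {
      cif <- cif_competing(sub)
      est <- se <- numeric(0)
      for (k in unique(cif$cause)) {
        ci <- cif[cif$cause == k, ]
        est[k] <- step_lookup(ci$time, ci$cif, time, before = 0)
        se[k] <- step_lookup(ci$time, ci$se, time, before = 0)
        rows[[length(rows) + 1L]] <- cbind(base, data.frame(
          quantity = k, estimate = est[k], se = se[k],
          lcl = step_lookup(ci$time, ci$lcl, time, before = 0),
          ucl = step_lookup(ci$time, ci$ucl, time, before = 0),
          n_events = sum(sub$event == 1 & sub$cause == k)))
      }
      z <- stats::qnorm(0.975)
      for (g in names(cause_groups)) {
        mem <- intersect(cause_groups[[g]], names(est))
        if (!length(mem)) next
        e <- sum(est[mem])
        s <- sqrt(sum(se[mem]^2))
        rows[[length(rows) + 1L]] <- cbind(base, data.frame(
          quantity = g, estimate = e, se = s,
          lcl = max(0, e - z * s), ucl = min(1, e + z * s),
          n_events = sum(sub$event == 1 & sub$cause %in% mem)))
      }
    }
  }
  if (!length(rows)) fail("no groups with exposure")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
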