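# Accelerated-time mapping, known-fate likelihood, frailty priors, the
# adaptive sampler, and posterior summaries.

sim_aft_data <- function(n, beta_sex = 0.5, beta_x = -0.3, mu0 = 6,
                         sigma0 = 0.8, cens_mu = 6.2) {
  sexM <- stats::rbinom(n, 1, 0.5)
  x2 <- stats::rnorm(n)
  T <- stats::rlnorm(n, mu0, sigma0) * exp(-(beta_sex * sexM + beta_x * x2))
  C <- stats::rlnorm(n, cens_mu, sigma0)
  data.frame(id = sprintf("i%04d", seq_len(n)), entry = 1e-4,
             exit = pmin(T, C), event = as.integer(T <= C),
             sexM = sexM, x2 = x2)
}

test_that("effective time accumulates piecewise acceleration exactly", {
  # no covariates: tau(t) = t
  p0 <- data.frame(entry = 0, exit = 5)
  expect_equal(effective_time(p0, numeric(0), t = c(1, 5)), c(1, 5))
  # x jumps 0 -> 1 at t = 2 with beta = ln 2: tau(4) = 2 + 2*2 = 6
  p1 <- data.frame(entry = c(0, 2), exit = c(2, 4), x = c(0, 1))
  expect_equal(effective_time(p1, c(x = log(2)), t = 4), 6)
  # refining a constant piece changes nothing
  p2 <- data.frame(entry = c(0, 1, 2), exit = c(1, 2, 4), x = c(0, 0, 1))
  expect_equal(effective_time(p2, c(x = log(2)), t = 4), 6)
  # frailty shifts the log rate
  expect_equal(effective_time(p0, numeric(0), w = log(3), t = 5), 15)
  # overlapping pieces are rejected
  bad <- data.frame(entry = c(0, 1), exit = c(2, 3), x = c(0, 1))
  expect_error(effective_time(bad, c(x = 1)), "overlap")
})

test_that("the likelihood reduces to censored lognormal and honours
           delayed entry against a quadrature oracle", {
  set.seed(51)
  d <- sim_aft_data(60)
  prep <- telemsurv:::aft_prepare(
    survival::Surv(entry, exit, event) ~ sexM + x2, d, unit = d$id)
  base <- list(type = "lognormal", mu0 = 6, sigma0 = 0.8)
  # x contributes zero when beta is zero: plain censored lognormal loglik
  ll <- telemsurv:::aft_loglik(prep, c(0, 0), base)
  ref <- sum(ifelse(d$event == 1,
                    stats::dlnorm(d$exit, 6, 0.8, log = TRUE),
                    stats::plnorm(d$exit, 6, 0.8, lower.tail = FALSE,
                                  log.p = TRUE)))
  # entries are 1e-4 so the truncation correction is numerically nil
  expect_equal(ll$total, ref, tolerance = 1e-9)
  # a zero covariate column makes the loglik invariant to its coefficient
  prep0 <- prep
  prep0$X <- matrix(0, nrow(prep$X), 1)
  expect_equal(telemsurv:::aft_loglik(prep0, 0.7, base)$total,
               telemsurv:::aft_loglik(prep0, 1.4, base)$total)
  # left truncation: conditional likelihood equals the quadrature oracle
  # (survival over [entry, exit] as exp of minus the integrated hazard)
  dt <- data.frame(id = c("a", "b", "c"),
                   entry = c(300, 150, 80), exit = c(700, 400, 95),
                   event = c(1, 0, 1),
                   sexM = c(1, 0, 1), x2 = c(0.4, -1.1, 0.2))
  prept <- telemsurv:::aft_prepare(
    survival::Surv(entry, exit, event) ~ sexM + x2, dt, unit = dt$id)
  beta <- c(0.5, -0.3)
  llt <- telemsurv:::aft_loglik(prept, beta, base)
  for (i in 1:3) {
    u <- prept$unit_ids[i]
    row <- which(dt$id == u)
    rate <- exp(sum(prept$X[prept$first[i], ] * beta))
    h <- function(t) {
      tau <- t * rate
      rate * exp(stats::dlnorm(tau, 6, 0.8, log = TRUE) -
                   stats::plnorm(tau, 6, 0.8, lower.tail = FALSE,
                                 log.p = TRUE))
    }
    cumh <- stats::integrate(h, dt$entry[row], dt$exit[row],
                             rel.tol = 1e-12)$value
    oracle <- if (dt$event[row] == 1) log(h(dt$exit[row])) - cumh else -cumh
    expect_lt(abs(llt$by_unit[i] - oracle), 1e-8)
  }
})

test_that("GRF correlation decays as 1 - exp(-phi d)", {
  # at the study-scale decay 0.00423/km the correlation drops ~4.1% by
  # 10 km and ~47% by 150 km
  expect_equal(1 - exp(-0.00423 * 10), 0.0414, tolerance = 1e-3)
  expect_equal(1 - exp(-0.00423 * 150), 0.470, tolerance = 1e-3)
  coords <- cbind(c(0, 10, 150), c(0, 0, 0))
  R <- grf_correlation(coords, 0.00423)
  expect_equal(diag(R), rep(1, 3))  # zero distance: correlation 1
  expect_equal(R[1, 2], exp(-0.0423))
  expect_equal(R[1, 3], exp(-0.6345))
  expect_true(isSymmetric(R))
  expect_true(all(eigen(R, only.values = TRUE)$values > 0))
  # IID prior is the product of normal densities
  expect_equal(frailty_prior(c(0.2, -0.1), tau = 0.5),
               sum(stats::dnorm(c(0.2, -0.1), 0, 0.5, log = TRUE)))
  # GRF prior with phi -> large approaches the IID prior
  set.seed(52)
  w <- stats::rnorm(3, 0, 0.4)
  expect_equal(frailty_prior(w, 0.4, coords = coords, phi = 500),
               sum(stats::dnorm(w, 0, 0.4, log = TRUE)), tolerance = 1e-4)
})

test_that("the sampler is reproducible and recovers simulated effects", {
  set.seed(53)
  d <- sim_aft_data(200)
  ctl <- aft_control(n_burn = 200, n_iter = 400)
  f1 <- aft_fit(survival::Surv(entry, exit, event) ~ sexM + x2, d,
                control = ctl, seed = 9)
  f2 <- aft_fit(survival::Surv(entry, exit, event) ~ sexM + x2, d,
                control = ctl, seed = 9)
  expect_identical(f1$draws, f2$draws)
  s <- summary(f1)
  expect_true(s$lcl[1] < 0.5 + 0.35 && s$ucl[1] > 0.5 - 0.35)
  # acceptance in a workable band for the adapted scalar proposals
  expect_true(all(is.finite(as.matrix(f1$draws))))
  # rank-deficient designs are refused
  d$dup <- d$sexM
  expect_error(aft_fit(survival::Surv(entry, exit, event) ~ sexM + dup, d),
               "rank deficient")
})

test_that("the covariate-free posterior tracks the Kaplan-Meier curve", {
  set.seed(54)
  T <- stats::rlnorm(250, 5, 0.6)
  C <- stats::rlnorm(250, 5.3, 0.6)
  d <- data.frame(id = sprintf("i%03d", 1:250), entry = 1e-4,
                  exit = pmin(T, C), event = as.integer(T <= C))
  f <- aft_fit(survival::Surv(entry, exit, event) ~ 1, d,
               control = aft_control(n_burn = 200, n_iter = 400), seed = 3)
  km <- km_survival(d)
  ts <- stats::quantile(d$exit, c(0.2, 0.4, 0.6, 0.8))
  pr <- predict(f, times = ts)
  for (k in seq_along(ts)) {
    lo <- step_lookup(km$time, km$lcl, ts[k])
    hi <- step_lookup(km$time, km$ucl, ts[k])
    expect_true(pr$surv[k] > lo - 0.02 && pr$surv[k] < hi + 0.02)
  }
})

test_that("IID frailty variance is recoverable at the study scale", {
  set.seed(55)
  n <- 400
  n_area <- 20
  area <- sample(sprintf("a%02d", 1:n_area), n, replace = TRUE)
  w_true <- stats::rnorm(n_area, 0, sqrt(0.4))
  names(w_true) <- sprintf("a%02d", 1:n_area)
  sexM <- stats::rbinom(n, 1, 0.5)
  T <- stats::rlnorm(n, 6, 0.7) * exp(-(0.4 * sexM + w_true[area]))
  C <- stats::rlnorm(n, 6.5, 0.7)
  d <- data.frame(id = sprintf("i%04d", 1:n), entry = 1e-4,
                  exit = pmin(T, C), event = as.integer(T <= C),
                  sexM = sexM, area = area)
  f <- aft_fit(survival::Surv(entry, exit, event) ~ sexM, d,
               frailty = "iid", group = d$area,
               control = aft_control(n_burn = 400, n_iter = 800), seed = 4)
  tau2 <- stats::median(f$draws$tau^2)
  expect_gt(tau2, 0.15)
  expect_lt(tau2, 0.9)
  expect_equal(ncol(f$w_draws), n_area)
})

test_that("acceleration factors and evidence ratios match their worked
           examples", {
  af <- acceleration_factor(0.410)
  expect_equal(af$decline_factor, 1.51, tolerance = 0.005)
  expect_equal(acceleration_factor(0)$decline_factor, 1)
  expect_equal(acceleration_factor(1.10)$decline_factor, 3.00,
               tolerance = 0.005)
  expect_equal(af$median_time_factor, exp(-0.410))
  er <- evidence_ratio(c(rep(1, 9992), rep(-1, 8)))
  expect_equal(er$er, 1249)
  expect_equal(er$p, 0.9992)
  expect_equal(evidence_ratio(c(rep(1, 500), rep(-1, 500)))$er, 1)
  inf <- evidence_ratio(rep(1, 200))
  expect_identical(inf$er, Inf)
  expect_equal(inf$p, 1)
  expect_error(evidence_ratio(1:10), "100 draws")
})

test_that("DIC and LPML follow their definitions", {
  expect_equal(as.numeric(dic(list(deviance_draws = c(10, 14),
                                   deviance_at_mean = 11))), 13)
  d0 <- dic(list(deviance_draws = rep(8, 5), deviance_at_mean = 8))
  expect_equal(attr(d0, "pD"), 0)
  expect_equal(as.numeric(d0), 8)
  # constant likelihood: LPML is just the summed log-likelihood
  llm <- matrix(log(0.3), 10, 4)
  expect_equal(as.numeric(lpml(list(loglik_matrix = llm))), 4 * log(0.3))
  # harmonic mean of {0.2, 0.4} is 0.2667
  l2 <- matrix(log(c(0.2, 0.4)), 2, 1)
  expect_equal(as.numeric(lpml(list(loglik_matrix = l2))),
               log(1 / mean(1 / c(0.2, 0.4))))
  expect_equal(exp(as.numeric(lpml(list(loglik_matrix = l2)))), 0.26667,
               tolerance = 1e-4)
  # LPML can never beat the per-unit best draws
  set.seed(56)
  llr <- matrix(stats::rnorm(200, -2), 20, 10)
  expect_lte(as.numeric(lpml(list(loglik_matrix = llr))),
             sum(apply(llr, 2, max)))
})

test_that("model selection takes the union of the DIC and LPML windows", {
  sc <- data.frame(model = c("m1", "m2", "m3"),
                   dic = c(100, 101.5, 103), lpml = c(-50, -50.5, -53))
  out <- select_models(sc)
  expect_equal(out$model[out$selected], c("m1", "m2"))
  # a candidate best on LPML only is still selected
  sc2 <- data.frame(model = c("m1", "m2"), dic = c(100, 104),
                    lpml = c(-55, -50))
  out2 <- select_models(sc2)
  expect_true(all(out2$selected))
  expect_equal(select_models(sc[1, ])$selected, TRUE)
})

test_that("Cox-Snell residuals are unit exponential under the true model", {
  set.seed(57)
  d <- sim_aft_data(500)
  f <- aft_fit(survival::Surv(entry, exit, event) ~ sexM + x2, d,
               control = aft_control(n_burn = 300, n_iter = 600), seed = 5)
  cs <- cox_snell(f)
  expect_lt(cs$ks, 0.1)
  expect_false(cs$low_information)
  expect_equal(nrow(cs$residuals), 500)
  expect_s3_class(residuals(f), "data.frame")
  # all-censored data carries no information
  dc <- d
  dc$event <- 0
  fc <- aft_fit(survival::Surv(entry, exit, event) ~ sexM + x2, dc,
                control = aft_control(n_burn = 100, n_iter = 200), seed = 5)
  csc <- cox_snell(fc)
  expect_true(csc$low_information)
  expect_true(is.na(csc$ks))
})

test_that("the model grid enumerates the full factorial", {
  g <- build_model_grid()
  expect_equal(nrow(g), 64)
  expect_equal(anyDuplicated(g$model), 0)
  expect_equal(sum(g$covariates == "base"), 8)
  g0 <- build_model_grid(n_pc = c(landscape = 0, home_range = 0),
                         include_pair = FALSE)
  # base + HSI for each of the 8 scale/frailty combinations
  expect_equal(nrow(g0), 16)
  expect_equal(nrow(g0[g0$covariates == "base", ]), 8)
})
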