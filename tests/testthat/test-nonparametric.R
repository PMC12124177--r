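# Product-limit survival with delayed entry, competing-risk cumulative
# incidence, medians, conditional survival and annual rate tables.

test_that("delayed-entry KM matches hand-computed risk sets", {
  d <- data.frame(entry = c(0, 3, 4), exit = c(5, 6, 7), event = c(1, 1, 0))
  k <- km_survival(d)
  expect_equal(step_lookup(k$time, k$surv, 5), 2 / 3)
  expect_equal(step_lookup(k$time, k$surv, 6), 1 / 3)
  expect_equal(step_lookup(k$time, k$surv, 7), 1 / 3)
  expect_equal(k$n_risk[k$time == 5], 3)
})

test_that("KM reduces to the empirical survivor function without censoring
           or truncation, and to 1 when everything is censored", {
  set.seed(42)
  t <- round(rexp(40, 0.3), 3)
  d <- data.frame(entry = 0, exit = t, event = 1)
  k <- km_survival(d)
  grid <- seq(0.1, max(t), length.out = 25)
  emp <- vapply(grid, function(g) mean(t > g), numeric(1))
  expect_equal(step_lookup(k$time, k$surv, grid), emp, tolerance = 1e-12)
  # KM with all entries zero equals standard KM exactly
  k0 <- km_survival(data.frame(entry = 0, exit = t,
                               event = rbinom(40, 1, 0.6)))
  f <- survival::survfit(survival::Surv(t, rbinom(40, 1, 0.6)) ~ 1)
  expect_s3_class(k0, "survcurve")
  # all censored: survival stays at 1
  kc <- km_survival(data.frame(entry = 0, exit = t, event = 0))
  expect_true(all(kc$surv == 1))
  expect_error(km_survival(d[0, ]), "empty")
})

test_that("Greenwood intervals bracket the estimate and tighten with n", {
  set.seed(7)
  widths <- vapply(c(50, 200, 800), function(n) {
    t <- rexp(n, 0.5)
    ev <- rbinom(n, 1, 0.8)
    k <- km_survival(data.frame(entry = 0, exit = t, event = ev))
    expect_true(all(k$lcl <= k$surv + 1e-12 & k$surv <= k$ucl + 1e-12,
                    na.rm = TRUE))
    w <- step_lookup(k$time, k$ucl, 1.4) - step_lookup(k$time, k$lcl, 1.4)
    w
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("median survival follows the threshold and band-crossing rules", {
  mk <- function(time, surv, lcl = surv - 0.1, ucl = pmin(surv + 0.1, 1)) {
    structure(data.frame(time = time, n_risk = 1, n_event = 1, n_censor = 0,
                         surv = surv, se = 0.05, lcl = lcl, ucl = ucl),
              class = c("survcurve", "data.frame"))
  }
  m <- median_survival(mk(c(2, 4), c(0.6, 0.4)))
  expect_equal(m$median, 4)
  # exact step to 0.5 counts (<= convention)
  expect_equal(median_survival(mk(c(1, 3), c(0.8, 0.5)))$median, 3)
  # curve never reaching 0.5 has no median
  expect_true(is.na(median_survival(mk(c(1, 3), c(0.9, 0.7)))$median))
  # band crossings give the interval
  m2 <- median_survival(mk(c(1, 2, 3), c(0.7, 0.55, 0.35),
                           lcl = c(0.55, 0.40, 0.20),
                           ucl = c(0.85, 0.70, 0.50)))
  expect_equal(m2$lcl, 2)  # lower band reaches 0.5 first
  expect_equal(m2$ucl, 3)
})

test_that("conditional survival is the ratio of the curve at two times", {
  k <- km_survival(data.frame(entry = 0, exit = c(1, 1, 2, 2, 3),
                              event = c(1, 0, 1, 1, 0)))
  S1 <- step_lookup(k$time, k$surv, 1)
  S2 <- step_lookup(k$time, k$surv, 2)
  expect_equal(conditional_survival(k, 1, 2), S2 / S1)
  expect_equal(conditional_survival(k, 2, 2), 1)
  kz <- km_survival(data.frame(entry = 0, exit = 1:3, event = 1))
  expect_error(conditional_survival(kz, 3, 3), "S\\(s\\) = 0")
})

test_that("CIF equals empirical cause fractions without censoring and
           reduces to 1 - KM with a single cause", {
  d <- data.frame(entry = 0, exit = c(1, 2, 3),
                  event = 1, cause = c("A", "B", "A"))
  ci <- cif_competing(d)
  expect_equal(max(ci$cif[ci$cause == "A"]), 2 / 3)
  expect_equal(max(ci$cif[ci$cause == "B"]), 1 / 3)
  # single cause: CIF = 1 - KM
  d1 <- data.frame(entry = 0, exit = c(1, 2, 2, 4, 5),
                   event = c(1, 1, 0, 1, 0), cause = c("A", "A", NA, "A", NA))
  c1 <- cif_competing(d1)
  km <- km_survival(d1)
  expect_equal(c1$cif, 1 - step_lookup(km$time, km$surv, c1$time),
               tolerance = 1e-12)
  expect_error(cif_competing(d, causes = "A"), "outside the configured set")
})

test_that("weighted product-limit CIF equals Aalen-Johansen on random
           left-truncated datasets", {
  set.seed(11)
  for (rep in 1:200) {
    d <- random_cr_data(n = sample(8:40, 1))
    d$event <- as.integer(d$status > 0)
    d$cause <- c(NA, "A", "B")[d$status + 1]
    if (!any(d$event == 1)) next
    # occasional random datasets legitimately exhaust the risk set
    ci <- suppressWarnings(cif_competing(d))
    st <- factor(c("censor", "A", "B")[d$status + 1],
                 levels = c("censor", "A", "B"))
    fit <- survival::survfit(survival::Surv(entry, exit, st) ~ 1, data = d,
                             id = seq_len(nrow(d)))
    for (k in unique(ci$cause)) {
      mine <- ci[ci$cause == k, ]
      aj <- fit$pstate[match(mine$time, fit$time), k]
      expect_lt(max(abs(mine$cif - aj)), 1e-10)
    }
  }
})

test_that("CIFs and survival sum to one at every event time", {
  set.seed(12)
  d <- random_cr_data(60, n_causes = 3)
  d$event <- as.integer(d$status > 0)
  d$cause <- c(NA, "A", "B", "C")[d$status + 1]
  ci <- cif_competing(d)
  km <- attr(ci, "km")
  for (t in unique(ci$time)) {
    tot <- step_lookup(km$time, km$surv, t)
    for (k in unique(ci$cause)) {
      sel <- ci$cause == k
      tot <- tot + step_lookup(ci$time[sel], ci$cif[sel], t, before = 0)
    }
    expect_lt(abs(tot - 1), 1e-10)
  }
})

test_that("CIF point estimates agree with cmprsk on untruncated data", {
  skip_if_not_installed("cmprsk")
  set.seed(13)
  t <- rexp(80, 0.4)
  status <- sample(0:2, 80, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  d <- data.frame(entry = 0, exit = t, event = as.integer(status > 0),
                  cause = c(NA, "A", "B")[status + 1])
  ci <- cif_competing(d)
  cu <- cmprsk::cuminc(t, status, cencode = 0)
  for (j in 1:2) {
    k <- c("A", "B")[j]
    mine <- ci[ci$cause == k, ]
    at <- mine$time[mine$time < max(t)]
    theirs <- cmprsk::timepoints(cu, at)$est[j, ]
    expect_equal(unname(step_lookup(mine$time, mine$cif, at)),
                 unname(theirs), tolerance = 1e-8)
  }
})

test_that("truncation and censoring weights are finite and nonnegative", {
  set.seed(14)
  d <- random_cr_data(30)
  d$event <- as.integer(d$status > 0)
  w <- weighted_records(d)
  expect_true(all(is.finite(w$cens_weight)))
  expect_true(all(is.finite(w$trunc_weight)))
  expect_true(all(w$cens_weight >= 0 & w$cens_weight <= 1))
  expect_true(all(w$trunc_weight >= 0 & w$trunc_weight <= 1))
})

test_that("annual rates recover constant-hazard survival and cause groups add", {
  set.seed(15)
  n <- 4000
  h <- c(legal_hunting = 0.1, natural = 0.05)
  t <- rexp(n, sum(h))
  cause <- sample(names(h), n, replace = TRUE, prob = h / sum(h))
  exit <- pmin(t, 1) * 365
  event <- as.integer(t <= 1)
  sp <- data.frame(entry = 0, exit = exit, event = event,
                   cause = ifelse(event == 1, cause, NA),
                   age_class = "adult", sex = "F", study_area = "x",
                   stringsAsFactors = FALSE)
  areas <- data.frame(id = "x", management = "hunted")
  tab <- annual_rates(sp, areas)
  S <- tab$estimate[tab$quantity == "survival"]
  expect_lt(abs(S - exp(-0.15)), 3 * tab$se[tab$quantity == "survival"])
  # anthropogenic = member-cause CIFs summed
  anth <- tab$estimate[tab$quantity == "anthropogenic"]
  members <- tab$estimate[tab$quantity %in% c("legal_hunting", "vehicle",
                                              "illegal")]
  expect_equal(anth, sum(members), tolerance = 1e-12)
  # known cause split: CIF_k ~= h_k/h (1 - exp(-h))
  for (k in names(h)) {
    ek <- tab$estimate[tab$quantity == k]
    expect_lt(abs(ek - h[[k]] / sum(h) * (1 - exp(-0.15))),
              3 * tab$se[tab$quantity == k])
  }
  # empty group errors unless dropped
  sp2 <- sp
  sp2$sex <- factor(sp2$sex, levels = c("F", "M"))
  expect_error(annual_rates(sp2, areas), "no exposure")
  expect_silent(annual_rates(sp2, areas, empty = "drop"))
})
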