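# The synthetic telemetry generator: reproducibility, cohort structure and
# agreement with the closed-form distributions it is built from.

const_hazard <- function(rates) {
  hazard_spec(cause_rates = rates,
              season_multipliers = c(spring = 1, summer = 1, autumn = 1,
                                     winter = 1),
              sex_multiplier = 1,
              age_multipliers = c(juvenile = 1, subadult = 1, adult = 1))
}

one_individual <- function() {
  data.frame(id = "i1", sex = "F", study_area = "alpine",
             birth_date = as.Date("2008-05-01"),
             capture_date = as.Date("2010-08-15"),
             fix_rate = 3.8, stringsAsFactors = FALSE)
}

test_that("population generation is reproducible and respects the config", {
  cfg <- sim_config(n = 100)
  p1 <- generate_population(cfg, seed = 1)
  p2 <- generate_population(cfg, seed = 1)
  expect_identical(p1, p2)
  p3 <- generate_population(cfg, seed = 2)
  expect_false(identical(p1$individuals, p3$individuals))
  expect_true(all(p1$individuals$study_area %in% p1$areas$id))
  expect_true(all(p1$individuals$birth_date <= p1$individuals$capture_date))
  expect_true(all(format(p1$individuals$birth_date, "%m-%d") == "05-01"))
  # sex ratio within 3 binomial SE at n = 10,000
  big <- generate_population(sim_config(n = 10000), seed = 3)
  f <- mean(big$individuals$sex == "F")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 10000))
  # age-class mixture close to the configured 48/17/35 cohort
  tab <- prop.table(table(big$individuals$age_class_at_capture))
  expect_equal(unname(tab["adult"]), 0.48, tolerance = 0.05)
  expect_error(generate_population(sim_config(n = 0)), "positive")
  expect_error(sim_config(areas = list()), "at least one")
})

test_that("event times follow the competing-exponential closed forms", {
  ind <- one_individual()
  areas <- data.frame(id = "alpine", management = "protected")
  cal <- season_calendar()
  hz <- const_hazard(c(natural = 0.2))
  ev <- with_seed(101, simulate_event_times(ind, hz, censor_rate = 0,
                                            areas, cal, reps = 10000))
  yrs <- ev$days / 365
  # median of Exp(0.2) is ln 2 / 0.2 = 3.466 y; MC error of the median at
  # n = 10,000 is about 1.25 * 5 / sqrt(n) = 0.06
  expect_lt(abs(median(yrs) - log(2) / 0.2), 4 * 1.253 * 5 / sqrt(10000))
  # only the rare horizon-outliving replicate is censored
  expect_lt(mean(ev$fate == "censored"), 0.02)
  # one-year survival matches exp(-h)
  expect_lt(abs(mean(yrs > 1) - exp(-0.2)), 3 * sqrt(0.17 / 10000))
  # equal hazards split causes 50/50
  hz2 <- const_hazard(c(natural = 0.1, illegal = 0.1))
  ev2 <- with_seed(102, simulate_event_times(ind, hz2, censor_rate = 0,
                                             areas, cal, reps = 4000))
  dead2 <- ev2$cause[ev2$fate == "death"]
  expect_lt(abs(mean(dead2 == "natural") - 0.5),
            3 * sqrt(0.25 / length(dead2)))
  # overwhelming censoring censors everyone
  ev3 <- with_seed(103, simulate_event_times(ind, hz, censor_rate = 1e6,
                                             areas, cal, reps = 50))
  expect_true(all(ev3$fate == "censored"))
  # no terminating event at all is an error
  expect_error(
    simulate_event_times(ind, const_hazard(c(natural = 0)), 0, areas, cal),
    "no terminating event")
})

test_that("cause frequencies are proportional to cause hazards", {
  ind <- one_individual()
  areas <- data.frame(id = "alpine", management = "protected")
  cal <- season_calendar()
  rates <- c(natural = 0.05, illegal = 0.15, vehicle = 0.05)
  ev <- with_seed(104, simulate_event_times(ind, const_hazard(rates), 0,
                                            areas, cal, reps = 10000))
  obs <- table(factor(ev$cause, levels = names(rates)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = rates / sum(rates)))
  expect_gt(gof$p.value, 0.01)
})

test_that("hunting-window hazards act only in hunted areas and windows", {
  cal <- season_calendar(hunting_windows = list(h = c("12-01", "02-28")))
  areas <- data.frame(id = c("h", "p"), management = c("hunted", "protected"))
  hz <- const_hazard(c(legal_hunting = 3))
  ind <- one_individual()
  ind$study_area <- "p"
  # protected: the only hazard never applies, censoring must terminate
  ev <- with_seed(105, simulate_event_times(ind, hz, censor_rate = 0.5,
                                            areas, cal, reps = 200))
  expect_true(all(ev$fate == "censored"))
  ind$study_area <- "h"
  ev2 <- with_seed(106, simulate_event_times(ind, hz, censor_rate = 0.05,
                                             areas, cal, reps = 300))
  dead <- ev2[ev2$fate == "death", ]
  expect_gt(nrow(dead), 0)
  when <- format(ind$capture_date + floor(dead$days), "%m-%d")
  expect_true(all(when >= "12-01" | when <= "02-28"))
})

test_that("cohort simulation yields valid tracking records", {
  pop <- generate_population(sim_config(n = 80), seed = 5)
  rec <- simulate_cohort(pop, hazard_spec(), censor_rate = 0.3, seed = 6)
  expect_silent(invisible(build_age_scale(rec)))
  rec2 <- simulate_cohort(pop, hazard_spec(), censor_rate = 0.3, seed = 6)
  expect_identical(rec, rec2)
  expect_true(all(rec$end_date > rec$capture_date))
  expect_true(all(is.na(rec$cause) == (rec$fate == "censored")))
  expect_true(all(rec$end_date <= pop$study_end + 1))
})

test_that("location counts follow the Poisson oracle and respect step scale", {
  ind <- one_individual()
  ind$end_date <- ind$capture_date + 100
  counts <- with_seed(107, vapply(1:300, function(i) {
    nrow(simulate_locations(ind, c(0, 0), step_scale = 1))
  }, numeric(1)))
  # mean count 3.8/day * 100 d = 380
  expect_lt(abs(mean(counts) - 380), 3 * sqrt(380 / 300))
  fx <- with_seed(108, simulate_locations(ind, c(5, -3), step_scale = 0))
  expect_true(all(fx$x_km == 5 & fx$y_km == -3))
  f1 <- with_seed(109, simulate_locations(ind, c(0, 0), step_scale = 2))
  f2 <- with_seed(109, simulate_locations(ind, c(0, 0), step_scale = 2))
  expect_identical(f1, f2)
  expect_error(simulate_locations(transform(ind, fix_rate = 0), c(0, 0)),
               "fix_rate")
  expect_error(simulate_locations(ind, c(0, 0), step_scale = -1),
               "step_scale")
})

test_that("rate sets encode the generating regime in expectation", {
  # definition checks with noise switched (effectively) off; the h = 0 area
  # is clipped to the (0, 1) interior, which raises the truncation counter
  rs <- suppressWarnings(generate_rate_sets("compensatory", S0 = 0.85,
                                            n_areas = 5, noise_sd = 1e-9,
                                            seed = 1))
  expect_gt(attr(rs, "truncated"), 0)
  S <- rs$estimate[rs$quantity == "survival"]
  expect_equal(S, rep(0.85, 5), tolerance = 1e-6)
  h_true <- seq(0, 0.1, length.out = 5)
  rs2 <- suppressWarnings(generate_rate_sets("additive", S0 = 0.9,
                                             n_areas = 5, noise_sd = 1e-9,
                                             seed = 1, h_max = 0.1))
  S2 <- rs2$estimate[rs2$quantity == "survival"]
  expect_equal(S2, 0.9 * (1 - h_true), tolerance = 1e-5)
  # partial sits between the two
  rs3 <- suppressWarnings(generate_rate_sets("partial", S0 = 0.9,
                                             n_areas = 5, noise_sd = 1e-9,
                                             seed = 1, h_max = 0.1))
  S3 <- rs3$estimate[rs3$quantity == "survival"]
  expect_true(all(S3[-1] < 0.9 + 1e-6 & S3[-1] > 0.9 * (1 - h_true[-1]) - 1e-6))
  expect_error(generate_rate_sets("additive", n_areas = 2), "at least 3")
  expect_error(generate_rate_sets("additive", S0 = 1.2), "S0")
  # rates stay inside (0, 1) and derived quantities add up
  rs4 <- suppressWarnings(generate_rate_sets("additive", S0 = 0.85,
                                             n_areas = 12, noise_sd = 0.03,
                                             seed = 2))
  expect_true(all(rs4$estimate > 0 & rs4$estimate < 1))
  wide <- split(rs4$estimate, rs4$quantity)
  expect_equal(wide$anthropogenic,
               wide$hunting + wide$illegal + wide$vehicle, tolerance = 1e-9)
})

test_that("synthetic rasters are standardized with the requested correlation", {
  r <- generate_raster(100, 100, range = 5, seed = 1)
  expect_lt(abs(mean(r$values)), 0.05)
  expect_true(stats::sd(r$values) > 0.95 && stats::sd(r$values) < 1.05)
  # neighbouring cells correlate under a wide kernel ...
  v <- r$values
  expect_gt(stats::cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)])), 0.5)
  # ... and not in the white-noise limit
  w <- generate_raster(100, 100, range = 0.01, seed = 1)$values
  expect_lt(abs(stats::cor(as.vector(w[, -1]), as.vector(w[, -ncol(w)]))),
            0.05)
  expect_identical(generate_raster(50, 40, range = 3, seed = 9),
                   generate_raster(50, 40, range = 3, seed = 9))
  expect_error(generate_raster(0, 10, range = 1), "positive")
  expect_error(generate_raster(10, 10, range = 0), "range")
})

test_that("ASCII grid round-trips preserve the raster", {
  r <- generate_raster(12, 17, range = 2, xll = 3, yll = -8, cellsize = 2.5,
                       seed = 4, name = "human_modification")
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path, name = "human_modification")
  expect_equal(r2$values, r$values, tolerance = 1e-6)
  expect_equal(r2$cellsize, r$cellsize)
  expect_equal(r2$xll, r$xll)
  unlink(path)
})

test_that("raster point lookup uses cell centres with row 1 at the top", {
  m <- matrix(1:6, nrow = 2, byrow = TRUE)  # rows: top (1 2 3), bottom (4 5 6)
  r <- ts_raster(m, xll = 0, yll = 0, cellsize = 1)
  expect_equal(raster_value_at(r, 0.5, 0.5), 4)  # bottom-left
  expect_equal(raster_value_at(r, 2.5, 1.5), 3)  # top-right
  expect_error(raster_value_at(r, 5, 0.5), "outside")
})
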