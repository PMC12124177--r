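# Synthetic telemetry generator. Emulates the statistical structure a
# continental known-fate lynx study assumes: 1 May births, age-class-
# dependent capture (left truncation), cause-specific piecewise-constant
# hazards varying by sex, season, age class and management type,
# collar-failure censoring, and GPS/VHF fix rates. Event simulation is
# exact: competing exponentials advanced segment by segment over the
# season x age-class x hunting-window partition, with no time
# discretisation.

#' Study-area specification
#'
#' @param id area label.
#' @param management `"hunted"` or `"protected"`. A hunting window is
#'   required iff the area is hunted.
#' @param centroid numeric `c(x, y)` planar coordinates in km.
#' @param hunting_window `c(start, end)` month-day strings, or `NULL`.
#' @param latitude_band one of `">65N"`, `"55-65N"`, `"<55N"`.
#' @return an object of class `study_area`.
#' @export
study_area <- function(id, management = c("hunted", "protected"),
                       centroid = c(0, 0), hunting_window = NULL,
                       latitude_band = c("55-65N", ">65N", "<55N")) {
  management <- match.arg(management)
  latitude_band <- match.arg(latitude_band)
  if (!all(is.finite(centroid)) || length(centroid) != 2L) {
    fail("centroid must be two finite planar km coordinates")
  }
  if (management == "hunted" && is.null(hunting_window)) {
    fail("hunted area '%s' needs a hunting window", id)
  }
  if (management == "protected" && !is.null(hunting_window)) {
    fail("protected area '%s' must not have a hunting window", id)
  }
  structure(list(id = id, management = management, centroid = centroid,
                 hunting_window = hunting_window,
                 latitude_band = latitude_band),
            class = "study_area")
}

areas_table <- function(areas) {
  data.frame(
    id = vapply(areas, `[[`, "", "id"),
    management = vapply(areas, `[[`, "", "management"),
    x = vapply(areas, function(a) a$centroid[1], numeric(1)),
    y = vapply(areas, function(a) a$centroid[2], numeric(1)),
    latitude_band = vapply(areas, `[[`, "", "latitude_band"),
    stringsAsFactors = FALSE
  )
}

areas_calendar <- function(areas, seasons = NULL) {
  hw <- lapply(areas, `[[`, "hunting_window")
  names(hw) <- vapply(areas, `[[`, "", "id")
  hw <- hw[!vapply(hw, is.null, logical(1))]
  if (is.null(seasons)) season_calendar(hunting_windows = hw)
  else season_calendar(seasons = seasons, hunting_windows = hw)
}

#' Cause-specific hazard specification
#'
#' Baseline per-year hazards by mortality cause, with multiplicative
#' modifiers for season, sex (males) and age class. The `legal_hunting`
#' hazard operates only inside the hunting window of hunted areas, so its
#' rate is the within-window hazard. Defaults are tuned to the adult rates
#' a continental lynx study reports (annual survival roughly 0.76-0.86,
#' illegal killing the leading cause).
#'
#' @param cause_rates named per-year hazards; names must be a subset of
#'   `natural`, `illegal`, `legal_hunting`, `vehicle`, `unknown`.
#' @param season_multipliers named positive factors by season.
#' @param sex_multiplier positive hazard factor for males.
#' @param age_multipliers named positive factors by age class.
#' @return an object of class `hazard_spec`.
#' @export
hazard_spec <- function(cause_rates = c(natural = 0.04, illegal = 0.08,
                                        legal_hunting = 0.45,
                                        vehicle = 0.015, unknown = 0.015),
                        season_multipliers = c(spring = 1, summer = 1,
                                               autumn = 1, winter = 1.3),
                        sex_multiplier = 1.5,
                        age_multipliers = c(juvenile = 1.4, subadult = 1.2,
                                            adult = 1)) {
  extra <- setdiff(names(cause_rates), CAUSE_LEVELS)
  if (length(extra)) fail("unknown cause(s) in hazard spec: %s",
                          paste(extra, collapse = ", "))
  if (any(cause_rates < 0)) fail("cause rates must be >= 0")
  if (any(c(season_multipliers, sex_multiplier, age_multipliers) <= 0)) {
    fail("hazard multipliers must be > 0")
  }
  structure(list(cause_rates = cause_rates,
                 season_multipliers = season_multipliers,
                 sex_multiplier = sex_multiplier,
                 age_multipliers = age_multipliers),
            class = "hazard_spec")
}

#' Generator settings
#'
#' @param n number of individuals.
#' @param areas list of [study_area()] objects.
#' @param sex_ratio probability an individual is female.
#' @param age_class_probs capture age-class mixture; the default matches the
#'   cohort composition of a continental lynx data set (48% adults, 17%
#'   subadults, 35% juveniles).
#' @param capture_window `c(first, last)` capture dates.
#' @param study_end administrative censoring date.
#' @param gps_fraction fraction of individuals on GPS collars.
#' @param fix_rates locations/day for VHF and GPS collars.
#' @param adult_extra_years mean of the geometric spread (in years) added
#'   beyond the minimum age for adults at capture.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n = 120,
                       areas = default_areas(),
                       sex_ratio = 0.5,
                       age_class_probs = c(juvenile = 0.35, subadult = 0.17,
                                           adult = 0.48),
                       capture_window = as.Date(c("2005-06-01", "2015-12-31")),
                       study_end = as.Date("2018-12-31"),
                       gps_fraction = 0.5,
                       fix_rates = c(vhf = 1.6, gps = 3.8),
                       adult_extra_years = 1.5) {
  if (n <= 0) fail("n must be positive")
  if (length(areas) == 0L) fail("at least one study area is required")
  stopifnot(abs(sum(age_class_probs) - 1) < 1e-8)
  structure(list(n = n, areas = areas, sex_ratio = sex_ratio,
                 age_class_probs = age_class_probs,
                 capture_window = as.Date(capture_window),
                 study_end = as.Date(study_end),
                 gps_fraction = gps_fraction, fix_rates = fix_rates,
                 adult_extra_years = adult_extra_years),
            class = "sim_config")
}

#' Default study-area set
#'
#' Four areas (two hunted with December-February windows, two protected)
#' with centroids spread over a few hundred km, covering all latitude bands.
#' @return list of [study_area()] objects.
#' @export
default_areas <- function() {
  list(
    study_area("alpine", "protected", c(0, 0), latitude_band = "<55N"),
    study_area("carpathian", "protected", c(260, 40), latitude_band = "<55N"),
    study_area("baltic", "hunted", c(180, 320),
               hunting_window = c("12-01", "02-28"), latitude_band = "55-65N"),
    study_area("boreal", "hunted", c(40, 520),
               hunting_window = c("02-01", "03-31"), latitude_band = ">65N")
  )
}

#' Generate a synthetic telemetry population
#'
#' Draws individuals with sexes, study areas, 1 May birth dates implied by
#' the capture age class (adults get extra whole years beyond the minimum
#' age), capture dates, and collar fix rates. Fates are filled in by
#' [simulate_cohort()].
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the output is reproducible.
#' @return list with `individuals` (data frame) and `areas` (data frame).
#' @export
generate_population <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  at <- areas_table(config$areas)
  with_seed(seed, {
    n <- config$n
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
    area <- at$id[sample.int(nrow(at), n, replace = TRUE)]
    span <- as.numeric(diff(config$capture_window))
    capture <- config$capture_window[1] +
      round(stats::runif(n) * span)
    acl <- names(config$age_class_probs)[
      sample.int(length(config$age_class_probs), n, replace = TRUE,
                 prob = config$age_class_probs)]
    birth <- estimate_birth_date(acl, capture)
    extra <- ifelse(acl == "adult",
                    stats::rgeom(n, 1 / (1 + config$adult_extra_years)), 0L)
    birth <- as.Date(sprintf("%d-05-01",
                             as.integer(format(birth, "%Y")) - extra))
    gps <- stats::runif(n) < config$gps_fraction
    fix_rate <- ifelse(gps, config$fix_rates[["gps"]],
                       config$fix_rates[["vhf"]])
    list(
      individuals = data.frame(
        id = sprintf("ind%04d", seq_len(n)),
        sex = sex,
        study_area = area,
        birth_date = birth,
        birth_confidence = ifelse(acl == "adult", "low",
                                  ifelse(acl == "subadult", "medium", "high")),
        capture_date = capture,
        age_class_at_capture = acl,
        collar = ifelse(gps, "gps", "vhf"),
        fix_rate = fix_rate,
        stringsAsFactors = FALSE
      ),
      areas = at,
      calendar = areas_calendar(config$areas),
      study_end = config$study_end
    )
  })
}

# Hazard segments for one individual from capture onward: boundaries at
# month changes, hunting-window edges and birthdays, out to `horizon` days.
hazard_path <- function(birth_date, capture_date, sex, hunted, window,
                        hz, calendar, horizon_days = 366 * 25) {
  end <- capture_date + horizon_days
  brk <- capture_date
  d <- first_of_next_month(capture_date)
  while (d < end) {
    brk <- c(brk, d)
    d <- first_of_next_month(d)
  }
  if (hunted) {
    wb <- window_breaks(capture_date, end, window)
    brk <- c(brk, wb[wb > capture_date & wb < end])
  }
  yrs <- as.integer(format(birth_date, "%Y")) + 1:30
  bdays <- as.Date(sprintf("%d-05-01", yrs))  # births follow the 1 May rule
  brk <- c(brk, bdays[bdays > capture_date & bdays < end])
  brk <- sort(unique(brk))
  starts <- brk
  ends <- c(brk[-1L], end)
  map <- month_of_season(calendar)
  season <- map[as.integer(format(starts, "%m"))]
  in_window <- if (hunted) in_hunting_window(starts, window) else
    rep(FALSE, length(starts))
  age_yrs <- floor(as.numeric(starts - birth_date) / 365.2425)
  age_class <- AGE_CLASS_LEVELS[pmin(age_yrs, 2) + 1]
  seas_m <- hz$season_multipliers[season]
  sex_m <- if (sex == "M") hz$sex_multiplier else 1
  age_m <- hz$age_multipliers[age_class]
  rates <- matrix(0, length(starts), length(hz$cause_rates),
                  dimnames = list(NULL, names(hz$cause_rates)))
  for (k in names(hz$cause_rates)) {
    r <- hz$cause_rates[[k]] * seas_m * sex_m * age_m
    if (k == "legal_hunting") r <- r * in_window
    rates[, k] <- r
  }
  list(starts = starts, ends = ends, rates = rates)
}

# Exact competing-exponential simulation along a piecewise-constant hazard
# path. Returns days since capture and the cause, or Inf if the horizon is
# outlived.
draw_event <- function(path) {
  len_yr <- as.numeric(path$ends - path$starts) / 365
  tot <- rowSums(path$rates)
  cum <- cumsum(tot * len_yr)
  E <- stats::rexp(1)
  seg <- which(cum >= E)[1]
  if (is.na(seg)) return(list(days = Inf, cause = NA_character_))
  prev <- if (seg == 1L) 0 else cum[seg - 1L]
  within_yr <- (E - prev) / tot[seg]
  day <- as.numeric(path$starts[seg] - path$starts[1L]) + within_yr * 365
  cause <- sample(colnames(path$rates), 1L, prob = path$rates[seg, ])
  list(days = day, cause = cause)
}

#' Simulate event times for one individual
#'
#' Competing-risk event simulation from capture onward (left truncation is
#' respected by construction), segment by segment over the season, hunting
#' window and age-class partition of the hazard path, with independent
#' exponential collar-failure censoring. The hazard path is built once and
#' reused across replicates, so large Monte Carlo runs are cheap.
#'
#' @param ind one-row individual data frame (see [generate_population()]).
#' @param hz a [hazard_spec()].
#' @param censor_rate collar-failure rate per year.
#' @param areas areas data frame.
#' @param calendar a [season_calendar()] carrying hunting windows.
#' @param study_end administrative censoring date (`NA` to disable).
#' @param reps number of independent replicates.
#' @return data frame with `days` (continuous days since capture), `fate`
#'   and `cause`.
#' @export
simulate_event_times <- function(ind, hz, censor_rate, areas, calendar,
                                 study_end = NA, reps = 1) {
  hunted <- areas$management[match(ind$study_area, areas$id)] == "hunted"
  window <- calendar$hunting_windows[[ind$study_area]]
  path <- hazard_path(ind$birth_date, ind$capture_date, ind$sex, hunted,
                      window, hz, calendar)
  if (all(path$rates == 0) && censor_rate <= 0 && is.na(study_end)) {
    fail("no terminating event possible: all hazards and censoring are zero")
  }
  admin <- if (!is.na(study_end)) {
    as.numeric(as.Date(study_end) - ind$capture_date)
  } else Inf
  horizon <- as.numeric(max(path$ends) - ind$capture_date)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    ev <- draw_event(path)
    cens <- if (censor_rate > 0) stats::rexp(1, censor_rate) * 365 else Inf
    # outliving the simulation horizon censors at the horizon
    death <- is.finite(ev$days) && ev$days <= min(cens, admin, horizon)
    out[[r]] <- data.frame(
      days = min(ev$days, cens, admin, horizon),
      fate = if (death) "death" else "censored",
      cause = if (death) ev$cause else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate one life history
#'
#' One replicate of [simulate_event_times()], returned as the record fields
#' (end date at day resolution, fate, cause).
#'
#' @inheritParams simulate_event_times
#' @return list with `end_date`, `fate` (`"death"`/`"censored"`), `cause`.
#' @export
simulate_life_history <- function(ind, hz, censor_rate, areas, calendar,
                                  study_end = NA) {
  ev <- simulate_event_times(ind, hz, censor_rate, areas, calendar, study_end)
  list(
    end_date = ind$capture_date + max(ceiling(ev$days), 1),
    fate = ev$fate,
    cause = if (ev$fate == "death") ev$cause else NA_character_
  )
}

#' Simulate fates for a whole population
#'
#' Applies [simulate_life_history()] to every individual of a generated
#' population and returns the completed tracking-record table.
#'
#' @param pop output of [generate_population()].
#' @param hz a [hazard_spec()].
#' @param censor_rate collar-failure rate per year (default 0.3; the source
#'   study does not report one).
#' @param seed integer seed.
#' @return data frame of tracking records ready for the time-scale builders.
#' @export
simulate_cohort <- function(pop, hz = hazard_spec(), censor_rate = 0.3,
                            seed = 1) {
  ind <- pop$individuals
  with_seed(seed, {
    out <- lapply(seq_len(nrow(ind)), function(i) {
      simulate_life_history(ind[i, ], hz, censor_rate, pop$areas,
                            pop$calendar, pop$study_end)
    })
    ind$end_date <- as.Date(vapply(out, function(o) as.character(o$end_date),
                                   ""))
    ind$fate <- vapply(out, `[[`, "", "fate")
    ind$cause <- vapply(out, function(o) o$cause %||% NA_character_,
                        NA_character_)
    ind
  })
}

#' Simulate location fixes
#'
#' Fix times are a Poisson process at the collar's rate between capture and
#' end of tracking; positions follow a stationary first-order autoregression
#' around the individual's home-range centre, so the marginal spread equals
#' `step_scale` regardless of fix count.
#'
#' @param ind one-row individual data frame with `capture_date`, `end_date`,
#'   `fix_rate`.
#' @param center numeric `c(x, y)` home-range centre (km).
#' @param step_scale marginal standard deviation of positions around the
#'   centre (km). Must be `>= 0`; 0 puts every fix at the centre.
#' @param ar autocorrelation of successive deviations.
#' @return data frame `id`, `timestamp` (date), `x_km`, `y_km`.
#' @export
simulate_locations <- function(ind, center, step_scale = 2, ar = 0.8) {
  if (ind$fix_rate <= 0) fail("fix_rate must be positive")
  if (step_scale < 0) fail("step_scale must be nonnegative")
  days <- as.numeric(ind$end_date - ind$capture_date)
  n <- stats::rpois(1, ind$fix_rate * days)
  if (n == 0L) {
    return(data.frame(id = character(0), timestamp = as.Date(character(0)),
                      x_km = numeric(0), y_km = numeric(0)))
  }
  tday <- sort(stats::runif(n, 0, days))
  innov_sd <- step_scale * sqrt(1 - ar^2)
  dx <- stats::filter(stats::rnorm(n, 0, innov_sd), ar, "recursive",
                      init = stats::rnorm(1, 0, step_scale))
  dy <- stats::filter(stats::rnorm(n, 0, innov_sd), ar, "recursive",
                      init = stats::rnorm(1, 0, step_scale))
  data.frame(id = ind$id, timestamp = ind$capture_date + floor(tday),
             x_km = center[1] + as.numeric(dx),
             y_km = center[2] + as.numeric(dy))
}

#' Simulate location fixes for a whole population
#'
#' Home-range centres are scattered around each individual's study-area
#' centroid.
#'
#' @param pop output of [generate_population()] with fates filled in (i.e.
#'   the records from [simulate_cohort()] as `records`).
#' @param records tracking-record table from [simulate_cohort()].
#' @param center_scatter standard deviation of centre placement around the
#'   area centroid (km).
#' @param step_scale marginal spread of fixes around the centre (km).
#' @param seed integer seed.
#' @return data frame of fixes plus a `centers` attribute (one row per
#'   individual, used as GRF coordinates downstream).
#' @export
simulate_population_locations <- function(pop, records, center_scatter = 20,
                                          step_scale = 2, seed = 1) {
  with_seed(seed, {
    at <- pop$areas
    cx <- at$x[match(records$study_area, at$id)] +
      stats::rnorm(nrow(records), 0, center_scatter)
    cy <- at$y[match(records$study_area, at$id)] +
      stats::rnorm(nrow(records), 0, center_scatter)
    fixes <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
      simulate_locations(records[i, ], c(cx[i], cy[i]),
                         step_scale = step_scale)
    }))
    attr(fixes, "centers") <- data.frame(id = records$id, x = cx, y = cy,
                                         stringsAsFactors = FALSE)
    fixes
  })
}

#' Generate study-area rate sets under a known mortality regime
#'
#' Produces the survival / cause-specific mortality table the compensation
#' module consumes, with a known generating regime: under `compensatory`
#' the expected survival stays at `S0` whatever the hunting rate (other
#' causes absorb the difference); under `additive` expected survival is
#' `S0 * (1 - h)`; under `partial` it is `S0 * (1 - 0.5 h)`. Hunting rates
#' are spread evenly over `[0, h_max]`; non-hunting mortality is divided
#' among natural, illegal, vehicle and unknown causes in fixed shares.
#' Gaussian noise of standard deviation `noise_sd` (survival) and
#' `noise_sd / 2` (cause rates) is added and reported as the standard error.
#'
#' @param regime `"compensatory"`, `"additive"` or `"partial"`.
#' @param S0 baseline (no hunting) survival in (0, 1).
#' @param n_areas number of study areas (>= 3).
#' @param noise_sd sampling noise for survival estimates.
#' @param seed integer seed.
#' @param h_max largest hunting mortality; defaults to `0.8 * (1 - S0)` so
#'   hunting never exceeds total mortality under compensation.
#' @return data frame `area`, `quantity`, `estimate`, `se` with attribute
#'   `truncated` counting rates clipped into (0, 1).
#' @export
generate_rate_sets <- function(regime = c("compensatory", "additive", "partial"),
                               S0 = 0.85, n_areas = 12, noise_sd = 0.03,
                               seed = 1, h_max = 0.8 * (1 - S0)) {
  regime <- match.arg(regime)
  if (S0 <= 0 || S0 >= 1) fail("S0 must be in (0, 1)")
  if (n_areas < 3) fail("n_areas must be at least 3")
  shares <- c(natural = 0.35, illegal = 0.45, vehicle = 0.10, unknown = 0.10)
  with_seed(seed, {
    h <- seq(0, h_max, length.out = n_areas)
    S <- switch(regime,
                compensatory = rep(S0, n_areas),
                additive = S0 * (1 - h),
                partial = S0 * (1 - 0.5 * h))
    M <- 1 - S
    other <- M - h
    if (any(other < 0)) fail("hunting exceeds total mortality; lower h_max")
    truncated <- 0L
    clip <- function(x) {
      bad <- x <= 0 | x >= 1
      truncated <<- truncated + sum(bad)
      pmin(pmax(x, 1e-3), 1 - 1e-3)
    }
    noisy <- function(x, sd) clip(x + stats::rnorm(length(x), 0, sd))
    est <- list(
      survival = noisy(S, noise_sd),
      hunting = noisy(h, noise_sd / 2),
      natural = noisy(shares[["natural"]] * other, noise_sd / 2),
      illegal = noisy(shares[["illegal"]] * other, noise_sd / 2),
      vehicle = noisy(shares[["vehicle"]] * other, noise_sd / 2),
      unknown = noisy(shares[["unknown"]] * other, noise_sd / 2)
    )
    est$anthropogenic <- clip(est$hunting + est$illegal + est$vehicle)
    est$nonhunting <- clip(est$natural + est$illegal + est$vehicle +
                             est$unknown)
    ses <- c(survival = noise_sd, hunting = noise_sd / 2,
             natural = noise_sd / 2, illegal = noise_sd / 2,
             vehicle = noise_sd / 2, unknown = noise_sd / 2,
             anthropogenic = noise_sd * sqrt(3) / 2,
             nonhunting = noise_sd)
    out <- do.call(rbind, lapply(names(est), function(q) {
      data.frame(area = sprintf("area%02d", seq_len(n_areas)), quantity = q,
                 estimate = est[[q]], se = ses[[q]],
                 stringsAsFactors = FALSE)
    }))
    if (truncated > 0) {
      warning(sprintf("%d rate(s) truncated into (0, 1)", truncated),
              call. = FALSE)
    }
    attr(out, "truncated") <- truncated
    attr(out, "regime") <- regime
    attr(out, "S0") <- S0
    out
  })
}

#' Generate a spatially autocorrelated covariate surface
#'
#' White noise smoothed with a Gaussian kernel (by FFT, wrap-around edges)
#' whose standard deviation is the correlation range, then standardised to
#' mean 0 and unit variance over cells. A range of (near) zero returns pure
#' white noise.
#'
#' @param nrow,ncol grid dimensions.
#' @param range correlation range in cells (> 0).
#' @param xll,yll,cellsize georeferencing of the output grid (km).
#' @param seed integer seed.
#' @param name covariate name.
#' @return a [ts_raster()].
#' @export
generate_raster <- function(nrow = 100, ncol = 100, range = 5,
                            xll = 0, yll = 0, cellsize = 1, seed = 1,
                            name = NULL) {
  if (nrow <= 0 || ncol <= 0) fail("raster dimensions must be positive")
  if (range <= 0) fail("correlation range must be positive")
  with_seed(seed, {
    z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
    if (range > 0.25) {
      ix <- c(0:(floor(nrow / 2)), -((ceiling(nrow / 2) - 1):1))
      iy <- c(0:(floor(ncol / 2)), -((ceiling(ncol / 2) - 1):1))
      kx <- exp(-ix^2 / (2 * range^2))
      ky <- exp(-iy^2 / (2 * range^2))
      kern <- outer(kx, ky)
      sm <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE))
    } else {
      sm <- z
    }
    sm <- (sm - mean(sm)) / stats::sd(sm)
    ts_raster(sm, xll = xll, yll = yll, cellsize = cellsize, name = name)
  })
}
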