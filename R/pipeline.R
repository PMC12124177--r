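# Orchestration: synthetic generation -> time scales -> nonparametric
# tables -> compensation tests -> landscape exposures -> AFT fits and
# model comparison -> report files. One global seed fans out to per-stage
# child seeds so stages are independently re-runnable yet reproducible.
# Every stage writes plain CSV/YAML artifacts into the run directory and
# logs record counts.

#' Default run configuration
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outdir output directory for stage artifacts.
#' @param n number of synthetic individuals.
#' @param censor_rate collar-failure rate per year.
#' @param regime generating mortality regime for the compensation stage's
#'   study-area rate sets.
#' @param n_rate_areas study areas in the compensation rate sets.
#' @param n_draws compensation resampling draws.
#' @param covariate_names synthetic landscape covariate surfaces to
#'   generate.
#' @param raster_dim,raster_range synthetic raster size (cells) and
#'   correlation range.
#' @param mcmc_schedule `"desk"` or `"study"` (see [aft_control()]).
#' @param aft_models data frame of AFT candidates to fit (columns
#'   `covariates` in `base`/`PC1`, `frailty` in `IID`/`GRF`); the default
#'   fits the base model with each frailty on the age scale.
#' @return a list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, outdir = tempfile("telemsurv_run_"),
                               n = 150, censor_rate = 0.3,
                               regime = "partial", n_rate_areas = 12,
                               n_draws = 1000,
                               covariate_names = c("human_modification",
                                                   "forest_integrity",
                                                   "ruggedness"),
                               raster_dim = 120, raster_range = 8,
                               mcmc_schedule = "desk",
                               aft_models = data.frame(
                                 covariates = c("base", "base"),
                                 frailty = c("IID", "GRF"),
                                 stringsAsFactors = FALSE)) {
  structure(list(seed = seed, outdir = outdir, n = n,
                 censor_rate = censor_rate, regime = regime,
                 n_rate_areas = n_rate_areas, n_draws = n_draws,
                 covariate_names = covariate_names,
                 raster_dim = raster_dim, raster_range = raster_range,
                 mcmc_schedule = mcmc_schedule, aft_models = aft_models),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys absent from the file fall back to [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (k in names(raw)) {
    cfg[[k]] <- if (k == "aft_models") as.data.frame(raw[[k]]) else raw[[k]]
  }
  cfg
}

config_hash <- function(cfg) {
  s <- yaml::as.yaml(cfg[setdiff(names(cfg), "outdir")])
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)))
}

#' Validate input tables
#'
#' Schema, date-ordering and fate/cause consistency checks for the
#' tracking-record table, plus orphan / out-of-window checks for location
#' fixes. Violations are split into fatal errors and warnings; offending
#' record ids are reported.
#'
#' @param records tracking-record data frame.
#' @param fixes optional location data frame (`id`, `timestamp`, `x_km`,
#'   `y_km`).
#' @return list with `errors` (character), `warnings` (character), and
#'   `fixes` with out-of-window rows dropped.
#' @export
validate_inputs <- function(records, fixes = NULL) {
  errors <- character(0)
  warns <- character(0)
  need <- c("id", "sex", "study_area", "birth_date", "capture_date",
            "end_date", "fate")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    errors <- c(errors, sprintf("records lack column(s): %s",
                                paste(miss, collapse = ", ")))
    return(list(errors = errors, warnings = warns, fixes = fixes))
  }
  bad <- records$id[records$end_date <= records$capture_date]
  if (length(bad)) errors <- c(errors, sprintf(
    "end_date <= capture_date: %s", paste(bad, collapse = ", ")))
  bad <- records$id[records$birth_date > records$capture_date]
  if (length(bad)) errors <- c(errors, sprintf(
    "birth after capture: %s", paste(bad, collapse = ", ")))
  dead <- records$fate == "death"
  bad <- records$id[dead & (is.na(records$cause) | records$cause == "")]
  if (length(bad)) errors <- c(errors, sprintf(
    "death without cause: %s", paste(bad, collapse = ", ")))
  bad <- records$id[!dead & !is.na(records$cause) & records$cause != ""]
  if (length(bad)) errors <- c(errors, sprintf(
    "cause present with fate = censored: %s", paste(bad, collapse = ", ")))
  extra <- setdiff(stats::na.omit(unique(records$cause[dead])), CAUSE_LEVELS)
  if (length(extra)) errors <- c(errors, sprintf(
    "unknown cause label(s): %s", paste(extra, collapse = ", ")))
  if (!is.null(fixes)) {
    orphan <- !(fixes$id %in% records$id)
    if (any(orphan)) {
      warns <- c(warns, sprintf("%d orphan fix(es) dropped", sum(orphan)))
      fixes <- fixes[!orphan, , drop = FALSE]
    }
    m <- match(fixes$id, records$id)
    out <- fixes$timestamp < records$capture_date[m] |
      fixes$timestamp > records$end_date[m]
    if (any(out)) {
      warns <- c(warns, sprintf(
        "%d fix(es) outside the tracking window dropped", sum(out)))
      fixes <- fixes[!out, , drop = FALSE]
    }
  }
  list(errors = errors, warnings = warns, fixes = fixes)
}

stage_log <- function(log, stage, ...) {
  msg <- sprintf(...)
  log[[stage]] <- c(log[[stage]], msg)
  log
}

# Seasonal tracking periods of one record: [capture, end) split at season
# boundaries.
seasonal_periods <- function(record, calendar = season_calendar()) {
  sp <- split_by_season(build_age_scale(record), calendar)
  data.frame(period = sprintf("%s_%s", format(sp$date0, "%Y"), sp$season),
             start = sp$date0,
             end = sp$date0 + (sp$exit - sp$entry),
             season = sp$season, stringsAsFactors = FALSE)
}

#' Build seasonal covariate exposures for a population
#'
#' For each individual and seasonal tracking period: the landscape-scale
#' use area (kernel isopleth / buffer / carried forward by the fix-count
#' rule) with covariate means over that area, and home-range-scale
#' covariate means at the period's fixes.
#'
#' @param records tracking records.
#' @param fixes location fixes.
#' @param areas areas table (provides the latitude band).
#' @param rasters named list of covariate [ts_raster()]s.
#' @param calendar a [season_calendar()].
#' @return data frame keyed by (`id`, `period`, `scale`) with one column
#'   per covariate, plus `method`, `start`, `end`.
#' @export
build_exposures <- function(records, fixes, areas, rasters,
                            calendar = season_calendar()) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    periods <- seasonal_periods(r, calendar)
    fx <- fixes[fixes$id == r$id, , drop = FALSE]
    band <- areas$latitude_band[match(r$study_area, areas$id)]
    ups <- suppressWarnings(
      build_use_polygons(fx, periods, r$sex, band))
    for (j in seq_len(nrow(periods))) {
      pid <- periods$period[j]
      up <- ups[[pid]]
      if (is.null(up)) next
      land <- try(extract_covariates(up, rasters, "landscape"),
                  silent = TRUE)
      if (inherits(land, "try-error")) next
      sel <- fx$timestamp >= periods$start[j] & fx$timestamp < periods$end[j]
      hr <- if (any(sel)) {
        extract_covariates(fx[sel, , drop = FALSE], rasters, "home_range")
      } else land  # carried-forward periods fall back to the area means
      base <- data.frame(id = r$id, period = pid,
                         start = periods$start[j], end = periods$end[j],
                         method = up$method, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- rbind(
        cbind(base, scale = "landscape", as.data.frame(as.list(land))),
        cbind(base, scale = "home_range", as.data.frame(as.list(hr))))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a telemetry data set, builds both survival time scales,
#' estimates the nonparametric rate table and median survival ages, runs
#' the compensation hypothesis tests on generated study-area rate sets,
#' builds landscape exposures with PCA reduction, fits the configured AFT
#' candidates with DIC/LPML comparison, and writes every table to
#' `config$outdir` stamped with the config hash and seed.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param stages subset of
#'   `c("simulate", "timescales", "surv", "compensation", "exposure",
#'   "aft", "report")` to run; earlier stage outputs are read from
#'   `outdir` when a stage is re-run alone.
#' @return list with the main tables and the per-stage log (invisibly
#'   written to `outdir`).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "timescales", "surv",
                                    "compensation", "exposure", "aft",
                                    "report")) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  res <- list(config = config)
  path <- function(f) file.path(config$outdir, f)
  run_stage <- function(stage, f) {
    tryCatch(f(), error = function(e) {
      fail("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      cfg <- sim_config(n = config$n)
      pop <- generate_population(cfg, seed = child_seed(config$seed, "pop"))
      rec <- simulate_cohort(pop, hazard_spec(),
                             censor_rate = config$censor_rate,
                             seed = child_seed(config$seed, "fate"))
      fx <- simulate_population_locations(
        pop, rec, seed = child_seed(config$seed, "fixes"))
      v <- validate_inputs(rec, fx)
      if (length(v$errors)) fail(paste(v$errors, collapse = "; "))
      utils::write.csv(rec, path("records.csv"), row.names = FALSE)
      utils::write.csv(v$fixes, path("fixes.csv"), row.names = FALSE)
      utils::write.csv(pop$areas, path("areas.csv"), row.names = FALSE)
      utils::write.csv(attr(fx, "centers"), path("centers.csv"),
                       row.names = FALSE)
      log <<- stage_log(log, "simulate", "%d records, %d fixes, %d areas",
                        nrow(rec), nrow(v$fixes), nrow(pop$areas))
      res$records <<- rec
    })
  }

  if (!file.exists(path("records.csv"))) {
    fail("no cached records in '%s'; run the 'simulate' stage first",
         config$outdir)
  }
  records <- utils::read.csv(path("records.csv"),
                             colClasses = c(birth_date = "Date",
                                            capture_date = "Date",
                                            end_date = "Date"))
  areas <- utils::read.csv(path("areas.csv"))
  calendar <- season_calendar(
    hunting_windows = stats::setNames(
      lapply(areas$id[areas$management == "hunted"],
             function(a) c("12-01", "02-28")),
      areas$id[areas$management == "hunted"]))

  if ("timescales" %in% stages) {
    run_stage("timescales", function() {
      age <- assign_age_class(
        apply_hunting_periods(
          split_by_season(build_age_scale(records), calendar),
          areas, calendar, mode = "age"))
      ann <- assign_age_class(
        apply_hunting_periods(build_annual_scale(records), areas, calendar,
                              mode = "annual"))
      utils::write.csv(age, path("spells_age.csv"), row.names = FALSE)
      utils::write.csv(ann, path("spells_annual.csv"), row.names = FALSE)
      log <<- stage_log(log, "timescales",
                        "%d age-scale and %d annual-scale spells",
                        nrow(age), nrow(ann))
    })
  }

  if ("surv" %in% stages) {
    run_stage("surv", function() {
      ann <- utils::read.csv(path("spells_annual.csv"))
      rates <- annual_rates(ann, areas, empty = "drop")
      utils::write.csv(rates, path("rates_table.csv"), row.names = FALSE)
      age <- utils::read.csv(path("spells_age.csv"))
      med <- do.call(rbind, lapply(split(age, list(age$sex)), function(g) {
        m <- median_survival(km_survival(g))
        data.frame(sex = g$sex[1], median_days = m$median,
                   lcl = m$lcl, ucl = m$ucl)
      }))
      utils::write.csv(med, path("median_survival.csv"), row.names = FALSE)
      log <<- stage_log(log, "surv", "%d rate rows, %d median rows",
                        nrow(rates), nrow(med))
      res$rates <<- rates
    })
  }

  if ("compensation" %in% stages) {
    run_stage("compensation", function() {
      rs <- suppressWarnings(generate_rate_sets(
        config$regime, n_areas = config$n_rate_areas,
        seed = child_seed(config$seed, "rates")))
      comp <- run_hypothesis_tests(rs, n_draws = config$n_draws,
                                   seed = child_seed(config$seed, "comp"))
      utils::write.csv(summary(comp), path("compensation.csv"),
                       row.names = FALSE)
      log <<- stage_log(log, "compensation", "6 hypotheses on %d draws",
                        config$n_draws)
      res$compensation <<- comp
    })
  }

  if ("exposure" %in% stages) {
    run_stage("exposure", function() {
      fixes <- utils::read.csv(path("fixes.csv"),
                               colClasses = c(timestamp = "Date"))
      ext <- range(c(fixes$x_km, fixes$y_km))
      pad <- 30
      cell <- max(1, ceiling(diff(ext) + 2 * pad) / config$raster_dim)
      rasters <- stats::setNames(lapply(
        seq_along(config$covariate_names), function(k) {
          generate_raster(config$raster_dim, config$raster_dim,
                          range = config$raster_range,
                          xll = ext[1] - pad, yll = ext[1] - pad,
                          cellsize = cell,
                          seed = child_seed(config$seed, paste0("ras", k)),
                          name = config$covariate_names[k])
        }), config$covariate_names)
      for (nm in names(rasters)) {
        write_ascii_grid(rasters[[nm]], path(sprintf("raster_%s.asc", nm)))
      }
      expo <- build_exposures(records, fixes, areas, rasters, calendar)
      utils::write.csv(expo, path("exposure.csv"), row.names = FALSE)
      scores <- list()
      for (sc in c("landscape", "home_range")) {
        sub <- expo[expo$scale == sc, , drop = FALSE]
        pc <- pca_reduce(sub[, config$covariate_names, drop = FALSE])
        scs <- as.data.frame(pc$scores[, pc$retained, drop = FALSE])
        names(scs) <- paste0("PC", pc$retained)
        scores[[sc]] <- cbind(sub[, c("id", "period", "start", "end")],
                              scale = sc, scs)
      }
      utils::write.csv(do.call(rbind, scores), path("pc_scores.csv"),
                       row.names = FALSE)
      log <<- stage_log(log, "exposure", "%d exposure rows", nrow(expo))
      res$exposure <<- expo
    })
  }

  if ("aft" %in% stages) {
    run_stage("aft", function() {
      age <- utils::read.csv(path("spells_age.csv"),
                             colClasses = c(date0 = "Date"))
      age$season <- stats::relevel(factor(age$season), ref = "autumn")
      centers <- utils::read.csv(path("centers.csv"))
      scores <- utils::read.csv(path("pc_scores.csv"),
                                colClasses = c(start = "Date",
                                               end = "Date"))
      ctl <- aft_control(schedule = config$mcmc_schedule)
      fits <- list()
      comp_rows <- list()
      coef_rows <- list()
      for (i in seq_len(nrow(config$aft_models))) {
        mspec <- config$aft_models[i, ]
        dat <- age
        form <- survival::Surv(entry, exit, event) ~ sex + season
        if (mspec$covariates == "PC1") {
          sc1 <- scores[scores$scale == "landscape", ]
          # join the period whose [start, end) holds the spell start
          idx <- mapply(function(id, d0) {
            j <- which(sc1$id == id & sc1$start <= d0 & d0 < sc1$end)
            if (length(j)) j[1] else NA_integer_
          }, dat$id, dat$date0)
          dat$PC1 <- sc1$PC1[idx]
          dat <- dat[!is.na(dat$PC1), , drop = FALSE]
          form <- survival::Surv(entry, exit, event) ~ sex + season + PC1
        }
        frl <- tolower(mspec$frailty)
        fit <- aft_fit(form, dat, unit = dat$id,
                       frailty = if (frl == "grf") "grf" else "iid",
                       group = dat$id,
                       coords = if (frl == "grf") centers else NULL,
                       control = ctl,
                       seed = child_seed(config$seed, paste0("aft", i)))
        label <- sprintf("%s %s", mspec$covariates, mspec$frailty)
        fits[[label]] <- fit
        comp_rows[[label]] <- data.frame(model = label,
                                         dic = as.numeric(dic(fit)),
                                         lpml = as.numeric(lpml(fit)))
        sm <- summary(fit)
        sm$model <- label
        coef_rows[[label]] <- sm
      }
      comparison <- select_models(do.call(rbind, comp_rows))
      utils::write.csv(comparison, path("model_comparison.csv"),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, coef_rows), path("coefficients.csv"),
                       row.names = FALSE)
      log <<- stage_log(log, "aft", "%d models fitted", length(fits))
      res$model_comparison <<- comparison
      res$fits <<- fits
    })
  }

  if ("report" %in% stages) {
    run_stage("report", function() {
      info <- list(seed = config$seed, config_hash = config_hash(config),
                   stages = names(log),
                   log = lapply(log, identity))
      yaml::write_yaml(info, path("run_info.yaml"))
      log <<- stage_log(log, "report", "run_info.yaml written")
    })
  }

  res$log <- log
  invisible(res)
}
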