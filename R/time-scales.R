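# Transformation of raw tracking records into analysis-ready spells on the
# age and recurrent annual time scales, with season / hunting-period / age-
# class splitting under the piecewise-constant-hazard convention.
#
# Conventions (documented in the methods vignette):
#   * dates at day resolution; intervals half-open [entry, exit) in days;
#   * age-class boundaries closed on the left (age exactly 1.0 -> subadult);
#   * the annual cycle starts on 1 May; a cycle year may hold 366 days;
#   * every spell row carries `date0`, the calendar date at `entry`, so the
#     calendar is always recoverable as date0 + (t - entry).

SEASON_LEVELS <- c("autumn", "winter", "hunting", "spring", "summer")
AGE_CLASS_LEVELS <- c("juvenile", "subadult", "adult")
CAUSE_LEVELS <- c("natural", "illegal", "legal_hunting", "vehicle", "unknown")

#' Season calendar
#'
#' Defines the month composition of the four calendar seasons and, per study
#' area, the legal hunting window as a pair of month-day strings (wrap-around
#' across the year boundary allowed, e.g. `c("12-01", "02-28")`).
#'
#' @param seasons named list mapping season name to the calendar months it
#'   spans. The default is the standard meteorological partition: spring
#'   March--May, summer June--August, autumn September--November, winter
#'   December--February.
#' @param hunting_windows named list, one entry per hunted study area, each a
#'   character vector `c(start, end)` of `"mm-dd"` strings. The window is
#'   inclusive of both endpoints; a window whose start equals its end is
#'   treated as empty.
#' @return an object of class `season_calendar`.
#' @export
season_calendar <- function(seasons = list(spring = 3:5, summer = 6:8,
                                           autumn = 9:11, winter = c(12L, 1L, 2L)),
                            hunting_windows = list()) {
  months <- sort(unlist(seasons, use.names = FALSE))
  if (!identical(months, 1:12)) {
    fail("seasons must partition the 12 calendar months")
  }
  for (a in names(hunting_windows)) {
    w <- hunting_windows[[a]]
    if (!is.null(w) && (length(w) != 2L || anyNA(parse_md(w)))) {
      fail("hunting window for area '%s' must be two 'mm-dd' strings", a)
    }
  }
  structure(list(seasons = seasons, hunting_windows = hunting_windows),
            class = "season_calendar")
}

# "mm-dd" -> list(month, day); vectorised.
parse_md <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2})-([0-9]{1,2})$", x))
  out <- vapply(m, function(g) {
    if (length(g) != 3L) return(c(NA_integer_, NA_integer_))
    c(as.integer(g[2L]), as.integer(g[3L]))
  }, integer(2))
  list(month = out[1L, ], day = out[2L, ])
}

month_of_season <- function(calendar) {
  map <- character(12L)
  for (s in names(calendar$seasons)) map[calendar$seasons[[s]]] <- s
  map
}

#' Estimate a birth date from the age class at capture
#'
#' Births are assumed to fall on 1 May (the start of the birthing season), so
#' the age class at first capture pins down the birth year: juveniles were
#' born on the most recent 1 May on or before capture, subadults one year
#' before that, and adults (minimum age, >2 years) two years before that.
#'
#' @param age_class character vector, `"juvenile"`, `"subadult"` or `"adult"`.
#' @param capture_date `Date` vector of first-capture dates.
#' @return `Date` vector of estimated birth dates (always a 1 May).
#' @examples
#' estimate_birth_date("juvenile", as.Date("2012-11-01"))  # 2012-05-01
#' estimate_birth_date("adult", as.Date("2012-04-30"))     # 2009-05-01
#' @export
estimate_birth_date <- function(age_class, capture_date) {
  age_class <- match.arg(age_class, AGE_CLASS_LEVELS, several.ok = TRUE)
  capture_date <- as.Date(capture_date)
  n <- max(length(age_class), length(capture_date))
  age_class <- rep_len(age_class, n)
  capture_date <- rep_len(capture_date, n)
  yr <- as.integer(format(capture_date, "%Y"))
  may1 <- as.Date(sprintf("%d-05-01", yr))
  yr <- ifelse(capture_date < may1, yr - 1L, yr)
  back <- c(juvenile = 0L, subadult = 1L, adult = 2L)[age_class]
  as.Date(sprintf("%d-05-01", yr - back))
}

check_records <- function(records) {
  need <- c("id", "sex", "study_area", "birth_date", "capture_date",
            "end_date", "fate")
  miss <- setdiff(need, names(records))
  if (length(miss)) fail("tracking records lack column(s): %s",
                         paste(miss, collapse = ", "))
  records$birth_date <- as.Date(records$birth_date)
  records$capture_date <- as.Date(records$capture_date)
  records$end_date <- as.Date(records$end_date)
  if (is.null(records$cause)) records$cause <- NA_character_
  bad <- which(records$end_date <= records$capture_date)
  if (length(bad)) fail("end_date <= capture_date for record(s): %s",
                        paste(records$id[bad], collapse = ", "))
  bad <- which(records$birth_date > records$capture_date)
  if (length(bad)) fail("birth_date after capture_date for record(s): %s",
                        paste(records$id[bad], collapse = ", "))
  dead <- records$fate == "death"
  if (any(dead & is.na(records$cause))) {
    fail("fate = death without a cause for record(s): %s",
         paste(records$id[dead & is.na(records$cause)], collapse = ", "))
  }
  if (any(!dead & !is.na(records$cause))) {
    fail("cause present with fate = censored for record(s): %s",
         paste(records$id[!dead & !is.na(records$cause)], collapse = ", "))
  }
  unknown <- setdiff(stats::na.omit(unique(records$cause)), CAUSE_LEVELS)
  if (length(unknown)) fail("unknown mortality cause(s): %s",
                            paste(unknown, collapse = ", "))
  records
}

spell_frame <- function(records, entry, exit, date0, scale, cycle_year = NA_integer_) {
  data.frame(
    id = records$id,
    sex = records$sex,
    study_area = records$study_area,
    scale = scale,
    entry = as.numeric(entry),
    exit = as.numeric(exit),
    event = as.integer(records$fate == "death"),
    cause = ifelse(records$fate == "death", records$cause, NA_character_),
    date0 = date0,
    birth_date = records$birth_date,
    cycle_year = cycle_year,
    stringsAsFactors = FALSE
  )
}

#' Build spells on the continuous age time scale
#'
#' One spell per individual, with delayed entry: time zero is birth, entry is
#' the age at capture in days, exit the age at death or censoring. The
#' conditioning on survival from birth to capture (left truncation) is what
#' downstream risk sets must honour.
#'
#' @param records data frame of tracking records with columns `id`, `sex`,
#'   `study_area`, `birth_date`, `capture_date`, `end_date`, `fate`
#'   (`"death"`/`"censored"`) and `cause` (required iff fate is death).
#' @return a spell data frame (`scale = "age"`, times in days since birth).
#' @export
build_age_scale <- function(records) {
  records <- check_records(records)
  spell_frame(records,
              entry = records$capture_date - records$birth_date,
              exit = records$end_date - records$birth_date,
              date0 = records$capture_date,
              scale = "age")
}

# Most recent cycle origin (1 May) on or before `date`.
cycle_start <- function(date) {
  yr <- as.integer(format(date, "%Y"))
  may1 <- as.Date(sprintf("%d-05-01", yr))
  as.Date(sprintf("%d-05-01", ifelse(date < may1, yr - 1L, yr)))
}

#' Build spells on the recurrent annual time scale
#'
#' Splits each tracking period at every 1 May, the cycle origin. Within each
#' cycle year the spell runs in elapsed days since that 1 May (0--366); only
#' the final spell of a dead individual carries its event, all earlier ones
#' are censored at the split.
#'
#' @inheritParams build_age_scale
#' @return a spell data frame (`scale = "annual"`) with a `cycle_year` column
#'   giving the calendar year of the cycle's 1 May origin.
#' @export
build_annual_scale <- function(records) {
  records <- check_records(records)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    starts <- r$capture_date
    cs <- cycle_start(r$capture_date)
    repeat {
      nxt <- as.Date(sprintf("%d-05-01", as.integer(format(cs, "%Y")) + 1L))
      if (nxt >= r$end_date) break
      starts <- c(starts, nxt)
      cs <- nxt
    }
    ends <- c(starts[-1L], r$end_date)
    cs_all <- cycle_start(starts)
    last <- length(starts)
    piece <- data.frame(
      id = r$id, sex = r$sex, study_area = r$study_area, scale = "annual",
      entry = as.numeric(starts - cs_all),
      exit = as.numeric(ends - cs_all),
      event = ifelse(seq_len(last) == last, as.integer(r$fate == "death"), 0L),
      cause = ifelse(seq_len(last) == last & r$fate == "death",
                     r$cause, NA_character_),
      date0 = starts,
      birth_date = r$birth_date,
      cycle_year = as.integer(format(cs_all, "%Y")),
      stringsAsFactors = FALSE
    )
    out[[i]] <- piece
  }
  do.call(rbind, out)
}

# Refine spell rows at the given calendar dates (interior breaks only).
# The event (and cause) stays on the chronologically last sub-piece of the
# row that carried it; all other pieces are censored at the split.
split_spells_at <- function(spells, break_fn) {
  out <- vector("list", nrow(spells))
  for (i in seq_len(nrow(spells))) {
    s <- spells[i, ]
    d_start <- s$date0
    d_end <- s$date0 + (s$exit - s$entry)
    br <- break_fn(s, d_start, d_end)
    br <- sort(unique(br[br > d_start & br < d_end]))
    bounds <- c(d_start, br, d_end)
    k <- length(bounds) - 1L
    piece <- s[rep(1L, k), , drop = FALSE]
    piece$entry <- s$entry + as.numeric(bounds[-length(bounds)] - d_start)
    piece$exit <- s$entry + as.numeric(bounds[-1L] - d_start)
    piece$date0 <- bounds[-length(bounds)]
    piece$event <- c(rep(0L, k - 1L), s$event)
    piece$cause <- c(rep(NA_character_, k - 1L), s$cause)
    out[[i]] <- piece
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

first_of_next_month <- function(d) {
  yr <- as.integer(format(d, "%Y"))
  mo <- as.integer(format(d, "%m"))
  as.Date(sprintf("%d-%02d-01", yr + (mo == 12L), (mo %% 12L) + 1L))
}

#' Split spells at calendar-month season boundaries
#'
#' Refines each spell at the month boundaries where the season changes and
#' labels every sub-spell with its calendar season. Durations are conserved
#' exactly and the event stays on the last sub-spell.
#'
#' @param spells a spell data frame from [build_age_scale()] or
#'   [build_annual_scale()].
#' @param calendar a [season_calendar()].
#' @return the refined spell data frame with a `season` column.
#' @export
split_by_season <- function(spells, calendar = season_calendar()) {
  stopifnot(inherits(calendar, "season_calendar"))
  map <- month_of_season(calendar)
  res <- split_spells_at(spells, function(s, d0, d1) {
    br <- as.Date(character(0))
    d <- first_of_next_month(d0)
    while (d < d1) {
      br <- c(br, d)
      d <- first_of_next_month(d)
    }
    # keep only boundaries where the season actually changes
    if (!length(br)) return(br)
    keep <- map[as.integer(format(br, "%m"))] !=
      map[as.integer(format(br - 1L, "%m"))]
    br[keep]
  })
  res$season <- map[as.integer(format(res$date0, "%m"))]
  res
}

# Hunting window membership for a vector of dates; inclusive endpoints,
# wrap-around allowed. A start == end window is empty.
in_hunting_window <- function(dates, window) {
  if (is.null(window) || anyNA(window)) return(rep(FALSE, length(dates)))
  md <- parse_md(window)
  key <- function(m, d) m * 100L + d
  k0 <- key(md$month[1L], md$day[1L])
  k1 <- key(md$month[2L], md$day[2L])
  if (k0 == k1) return(rep(FALSE, length(dates)))
  kd <- key(as.integer(format(dates, "%m")), as.integer(format(dates, "%d")))
  if (k0 < k1) kd >= k0 & kd <= k1 else kd >= k0 | kd <= k1
}

# Window boundary dates (window start; day after window end) falling strictly
# inside [d0, d1].
window_breaks <- function(d0, d1, window) {
  if (is.null(window) || anyNA(window)) return(as.Date(character(0)))
  md <- parse_md(window)
  if (md$month[1L] == md$month[2L] && md$day[1L] == md$day[2L]) {
    return(as.Date(character(0)))
  }
  yrs <- seq(as.integer(format(d0, "%Y")) - 1L, as.integer(format(d1, "%Y")) + 1L)
  starts <- as.Date(sprintf("%d-%02d-%02d", yrs, md$month[1L], md$day[1L]))
  ends <- as.Date(sprintf("%d-%02d-%02d", yrs, md$month[2L], md$day[2L])) + 1L
  c(starts, ends)
}

#' Label spells with hunting-period exposure
#'
#' Splits spells of individuals in hunted study areas at the boundaries of
#' the area's legal hunting window. On the age time scale
#' (`mode = "age"`) the calendar season label inside the window is replaced
#' by the level `"hunting"`, giving the five-level season factor. On the
#' annual time scale (`mode = "annual"`) a binary `hunting` column
#' (`"hunting"` / `"nonhunting"`) is added instead. Spells in protected
#' areas are never relabelled (they receive `"nonhunting"` in annual mode).
#'
#' @param spells a spell data frame; for `mode = "age"` it must already
#'   carry a `season` column (see [split_by_season()]).
#' @param areas data frame with columns `id` and `management`
#'   (`"hunted"`/`"protected"`); hunted areas must have a window in
#'   `calendar`.
#' @param calendar a [season_calendar()] holding per-area hunting windows.
#' @param mode `"age"` (5-level season factor) or `"annual"` (binary label).
#' @return the refined spell data frame.
#' @export
apply_hunting_periods <- function(spells, areas, calendar, mode = c("age", "annual")) {
  mode <- match.arg(mode)
  stopifnot(inherits(calendar, "season_calendar"))
  if (mode == "age" && is.null(spells$season)) {
    fail("age-scale hunting labels need season labels first (split_by_season)")
  }
  hunted <- areas$id[areas$management == "hunted"]
  for (a in hunted) {
    if (is.null(calendar$hunting_windows[[a]])) {
      fail("hunted area '%s' has no hunting window in the calendar", a)
    }
  }
  res <- split_spells_at(spells, function(s, d0, d1) {
    if (!(s$study_area %in% hunted)) return(as.Date(character(0)))
    window_breaks(d0, d1, calendar$hunting_windows[[s$study_area]])
  })
  inside <- rep(FALSE, nrow(res))
  for (a in hunted) {
    sel <- res$study_area == a
    if (any(sel)) {
      inside[sel] <- in_hunting_window(res$date0[sel],
                                       calendar$hunting_windows[[a]])
    }
  }
  if (mode == "age") {
    res$season[inside] <- "hunting"
  } else {
    res$hunting <- ifelse(inside, "hunting", "nonhunting")
  }
  res
}

#' Assign time-varying age classes
#'
#' Splits spells at each individual's first and second birthdays and labels
#' the pieces juvenile (age < 1), subadult (1 <= age < 2) and adult
#' (age >= 2). Boundaries are closed on the left: a spell entering exactly at
#' age 1.0 is subadult.
#'
#' @param spells a spell data frame carrying `birth_date`.
#' @return the refined spell data frame with an `age_class` column.
#' @export
assign_age_class <- function(spells) {
  if (is.null(spells$birth_date)) fail("spells lack birth_date")
  anniversary <- function(birth, k) {
    yr <- as.integer(format(birth, "%Y")) + k
    md <- format(birth, "-%m-%d")
    # birthdays of 29 Feb roll to 1 Mar in non-leap years
    d <- suppressWarnings(as.Date(paste0(yr, md)))
    d[is.na(d)] <- as.Date(sprintf("%d-03-01", yr[is.na(d)]))
    d
  }
  res <- split_spells_at(spells, function(s, d0, d1) {
    c(anniversary(s$birth_date, 1L), anniversary(s$birth_date, 2L))
  })
  age_yrs <- ifelse(res$date0 >= anniversary(res$birth_date, 2L), 2,
                    ifelse(res$date0 >= anniversary(res$birth_date, 1L), 1, 0))
  res$age_class <- AGE_CLASS_LEVELS[age_yrs + 1]
  res
}
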