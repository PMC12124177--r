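# Shared fixtures, built in code.

# A minimal tracking-record table with known calendar arithmetic.
micro_records <- function() {
  data.frame(
    id = c("a", "b", "c"),
    sex = c("F", "M", "F"),
    study_area = c("north", "north", "south"),
    birth_date = as.Date(c("2010-05-01", "2011-05-01", "2012-05-01")),
    capture_date = as.Date(c("2012-11-01", "2012-11-01", "2012-08-15")),
    end_date = as.Date(c("2013-02-01", "2013-06-30", "2013-05-10")),
    fate = c("death", "censored", "death"),
    cause = c("illegal", NA, "natural"),
    stringsAsFactors = FALSE
  )
}

micro_areas <- function() {
  data.frame(
    id = c("north", "south"),
    management = c("hunted", "protected"),
    stringsAsFactors = FALSE
  )
}

micro_calendar <- function() {
  season_calendar(hunting_windows = list(north = c("12-01", "02-28")))
}

# Records spanning several cycle years, seasons and fates, used for the
# conservation / tiling properties.
check_conservation_records <- function() {
  data.frame(
    id = sprintf("r%02d", 1:6),
    sex = c("F", "M", "F", "M", "F", "M"),
    study_area = c("north", "north", "south", "south", "north", "south"),
    birth_date = as.Date(c("2009-05-01", "2010-05-01", "2011-05-01",
                           "2008-05-01", "2012-05-01", "2010-05-01")),
    capture_date = as.Date(c("2010-03-10", "2011-11-23", "2012-02-29",
                             "2010-05-01", "2012-12-31", "2011-07-04")),
    end_date = as.Date(c("2013-08-15", "2012-01-02", "2014-06-30",
                         "2012-04-30", "2013-05-01", "2011-07-05")),
    fate = c("death", "censored", "death", "censored", "death", "death"),
    cause = c("illegal", NA, "natural", NA, "legal_hunting", "vehicle"),
    stringsAsFactors = FALSE
  )
}

# Random small left-truncated competing-risks datasets for oracle checks.
random_cr_data <- function(n, n_causes = 2) {
  entry <- round(rexp(n, 1), 3)
  gap <- round(rexp(n, 0.5) + 0.01, 3)
  exit <- entry + gap
  status <- sample(0:n_causes, n, replace = TRUE)
  data.frame(entry = entry, exit = exit, status = status)
}

expect_days <- function(x, y) expect_equal(as.numeric(x), as.numeric(y))
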