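# Shared internal helpers: argument checks, clock arithmetic, seeding.

SLOT_SECONDS <- 600L      # native feed resolution: one report every 10 minutes
SLOTS_PER_DAY <- 144L
SLOTS_PER_HOUR <- 6L

stop_bad_arg <- function(msg) abort(msg, class = "outagegrid_invalid_argument")

check_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != trunc(x)) {
    stop_bad_arg(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < lo || x > hi) {
    stop_bad_arg(sprintf("`%s` must be a single number in [%s, %s].", name, lo, hi))
  }
  as.numeric(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_bad_arg(sprintf("`%s` is missing required column(s): %s.",
                         name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' @noRd
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

# Floor a POSIXct to the start of its clock hour (UTC arithmetic, no DST).
floor_hour <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 3600) * 3600, origin = "1970-01-01", tz = "UTC")
}

utc_date <- function(t) as.Date(t, tz = "UTC")
utc_year <- function(t) as.integer(format(t, "%Y", tz = "UTC"))
utc_hour <- function(t) as.integer(format(t, "%H", tz = "UTC"))
utc_month <- function(t) as.integer(format(t, "%m", tz = "UTC"))

days_in_year <- function(year) {
  ifelse(year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0), 366L, 365L)
}

# Calendar week index 1..53 used for the weekly temperature climatology:
# day-of-year blocks of 7 days (week 53 covers the final 1-2 days).
week_of_year <- function(date) {
  yday <- as.integer(format(date, "%j"))
  pmin(53L, ((yday - 1L) %/% 7L) + 1L)
}

# Derive a reproducible child seed from a parent seed, so each module draws
# from its own substream and can be regenerated independently.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 73L + offset * 9973) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
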