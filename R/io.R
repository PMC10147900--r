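# Table I/O contracts: each pipeline artifact has a declared schema; tables
# are type-checked and invariant-checked on read and written with canonical
# column order, UTF-8, and ISO-8601 timestamps.

table_schemas <- function() {
  list(
    registry = list(
      cols = c(county_id = "c", state_id = "c", households = "i",
               businesses = "i", customers_total = "i", grid_row = "i",
               grid_col = "i", utc_offset_hours = "i"),
      validate = function(df) {
        bad <- which(df$customers_total != df$households + df$businesses)
        if (length(bad)) {
          sprintf("customers_total != households + businesses at row %d", bad[1])
        } else if (anyDuplicated(df$county_id)) {
          "duplicate county_id"
        } else if (any(df$households < 0 | df$businesses < 0)) {
          sprintf("negative count at row %d",
                  which(df$households < 0 | df$businesses < 0)[1])
        } else {
          NULL
        }
      }
    ),
    stream = list(
      cols = c(county_id = "c", timestamp = "T", customers_out = "i"),
      optional = c(customers_tracked = "i"),
      validate = function(df) {
        bad <- which(df$customers_out < 0)
        if (length(bad)) sprintf("negative customers_out at row %d", bad[1]) else NULL
      }
    ),
    calendar = list(
      cols = c(county_id = "c", date = "D", heat = "i", cold = "i",
               precip = "i", snow = "i", lightning = "i", cyclone = "i",
               wildfire = "i"),
      validate = function(df) {
        flags <- as.matrix(df[c("heat", "cold", "precip", "snow", "lightning",
                                "cyclone", "wildfire")])
        bad <- which(!(flags %in% c(0L, 1L)))
        if (length(bad)) {
          sprintf("flag value outside {0,1} at row %d", ((bad[1] - 1) %% nrow(df)) + 1)
        } else {
          NULL
        }
      }
    ),
    vulnerability = list(
      cols = c(county_id = "c", svi = "d",
               setNames(rep("d", length(SVI_COMPONENTS)), SVI_COMPONENTS),
               dme_per_1000 = "d"),
      optional = c(outage_rate_multiplier = "d"),
      validate = function(df) {
        if (any(df$svi < 0 | df$svi > 1)) {
          "svi outside [0,1]"
        } else if (any(df$dme_per_1000 < 0 | df$dme_per_1000 > 1000)) {
          "dme_per_1000 outside [0,1000]"
        } else {
          NULL
        }
      }
    ),
    assessment = list(
      cols = c(county_id = "c", year = "i", reporting_fraction = "d",
               coverage_fraction = "d", reliable = "l"),
      validate = function(df) {
        fr <- c(df$reporting_fraction, df$coverage_fraction)
        if (any(fr < 0 | fr > 1)) "fraction outside [0,1]" else NULL
      }
    ),
    tiers = list(
      cols = c(county_id = "c", years_reliable = "i", tier_1plus = "l",
               tier_2plus = "l", tier_full = "l"),
      validate = function(df) NULL
    ),
    events = list(
      cols = c(county_id = "c", start_hour = "T", duration_hours = "i",
               peak_customers_out = "i", event_customer_hours = "d"),
      validate = function(df) {
        if (any(df$duration_hours < 1)) "duration_hours < 1" else NULL
      }
    ),
    lisa = list(
      cols = c(county_id = "c", local_stat = "d", pseudo_p = "d",
               p_adjusted = "d", fdr_significant = "l", cluster_label = "c"),
      validate = function(df) {
        if (any(df$pseudo_p <= 0 | df$pseudo_p > 1)) "pseudo_p outside (0,1]" else NULL
      }
    )
  )
}

#' Write a pipeline table with its declared schema
#'
#' Columns are reordered canonically; timestamps are written as ISO-8601
#' UTC. Logical flag columns of the calendar schema are written as 0/1.
#'
#' @param df Table to write.
#' @param schema Schema name; one of
#'   `names(outagegrid:::table_schemas())`.
#' @param path Output CSV path.
#' @return `df`, invisibly.
#' @export
write_table <- function(df, schema, path) {
  sc <- table_schemas()[[schema]]
  if (is.null(sc)) stop_bad_arg(sprintf("unknown schema '%s'.", schema))
  cols <- names(sc$cols)
  opt <- intersect(names(sc$optional %||% character()), names(df))
  check_columns(df, cols, "df")
  out <- df[c(cols, opt)]
  if (schema == "calendar") {
    flag_cols <- setdiff(cols, c("county_id", "date"))
    out <- out %>% mutate(across(dplyr::all_of(flag_cols), as.integer))
  }
  readr::write_csv(out, path)
  invisible(df)
}

#' Read and validate a pipeline table
#'
#' Missing required columns are an error; unknown columns produce a warning
#' and are kept; schema invariant violations raise an error naming the
#' offending row.
#'
#' @param path CSV path.
#' @param schema Schema name.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema) {
  sc <- table_schemas()[[schema]]
  if (is.null(sc)) stop_bad_arg(sprintf("unknown schema '%s'.", schema))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- names(sc$cols)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "outagegrid_schema_error")
  }
  known <- c(required, names(sc$optional %||% character()))
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warn(sprintf("%s: unknown column(s) kept as-is: %s", path,
                 paste(unknown, collapse = ", ")))
  }
  # Coerce declared types.
  type_map <- c(sc$cols, sc$optional %||% character())
  for (col in intersect(names(type_map), names(df))) {
    df[[col]] <- switch(
      type_map[[col]],
      c = as.character(df[[col]]),
      i = as.integer(df[[col]]),
      d = as.numeric(df[[col]]),
      l = as.logical(df[[col]]),
      D = as.Date(df[[col]]),
      T = as_utc(df[[col]])
    )
  }
  msg <- sc$validate(df)
  if (!is.null(msg)) {
    abort(sprintf("%s: schema violation: %s", path, msg),
          class = "outagegrid_schema_error")
  }
  df
}

write_truth_json <- function(truth, path) {
  jsonlite::write_json(prepare_truth(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", na = "null")
  invisible(truth)
}

prepare_truth <- function(x) {
  if (inherits(x, "POSIXct")) return(format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  if (inherits(x, "Date")) return(format(x))
  if (is.data.frame(x)) return(purrr::map(as.list(x), prepare_truth))
  if (is.list(x)) return(purrr::map(x, prepare_truth))
  x
}
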