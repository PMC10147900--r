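#' Generate a synthetic county registry on a rectangular lattice
#'
#' Creates `n_rows * n_cols` synthetic counties laid out on a lattice, each
#' with a FIPS-like identifier, a state assignment (vertical bands of
#' columns), household and business establishment counts, and a fixed UTC
#' offset. The electricity-customer denominator is `households + businesses`,
#' mirroring the common practice of estimating county customers from census
#' household and business-establishment counts.
#'
#' Lattice coordinates (`grid_row`, `grid_col`) stand in for geography:
#' contiguity-based spatial weights are derived from them with
#' [lattice_adjacency()], which keeps adjacency explicit and testable.
#'
#' @param n_rows,n_cols Lattice dimensions (positive integers).
#' @param customer_range Length-2 numeric: inclusive range from which each
#'   county's total customer count is drawn uniformly.
#' @param seed Integer seed; the registry is bit-reproducible given the seed.
#' @param states_per_band Number of lattice columns per synthetic state.
#' @return A tibble with one row per county and columns `county_id`,
#'   `state_id`, `households`, `businesses`, `customers_total`, `grid_row`,
#'   `grid_col`, `utc_offset_hours`.
#' @examples
#' reg <- generate_registry(3, 3, customer_range = c(5000, 20000), seed = 1)
#' reg
#' lattice_adjacency(reg, scheme = "queen")
#' @export
generate_registry <- function(n_rows, n_cols,
                              customer_range = c(5000, 200000),
                              seed = 1L,
                              states_per_band = 5L) {
  n_rows <- check_count(n_rows, "n_rows", min = 1)
  n_cols <- check_count(n_cols, "n_cols", min = 1)
  if (length(customer_range) != 2 || any(customer_range <= 0) ||
      customer_range[2] < customer_range[1]) {
    stop_bad_arg("`customer_range` must be a positive, non-decreasing length-2 range.")
  }
  with_seed(child_seed(seed, 1L), {
    grid <- tidyr::expand_grid(grid_row = seq_len(n_rows), grid_col = seq_len(n_cols))
    n <- nrow(grid)
    state_num <- ((grid$grid_col - 1L) %/% states_per_band) + 1L
    customers <- floor(runif(n, customer_range[1], customer_range[2] + 1))
    customers <- pmin(customers, customer_range[2])
    businesses <- round(customers * runif(n, 0.10, 0.30))
    grid %>%
      mutate(
        state_id = sprintf("%02d", state_num),
        county_id = sprintf("%02d%03d", state_num,
                            stats::ave(state_num, state_num, FUN = seq_along)),
        customers_total = as.integer(customers),
        businesses = as.integer(businesses),
        households = as.integer(customers - businesses),
        utc_offset_hours = -5L - ((state_num - 1L) %% 4L)
      ) %>%
      select("county_id", "state_id", "households", "businesses",
             "customers_total", "grid_row", "grid_col", "utc_offset_hours")
  })
}

#' Contiguity adjacency for a lattice registry
#'
#' Enumerates neighbouring county pairs on the registry's lattice under rook
#' (shared edge) or queen (shared edge or corner) contiguity. The result is
#' symmetric: each unordered pair appears in both directions.
#'
#' @param registry A county registry from [generate_registry()] (needs
#'   `county_id`, `grid_row`, `grid_col`).
#' @param scheme `"queen"` (default) or `"rook"`.
#' @return A tibble with columns `county_id`, `neighbor_id`.
#' @export
lattice_adjacency <- function(registry, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  check_columns(registry, c("county_id", "grid_row", "grid_col"), "registry")
  if (anyDuplicated(registry[c("grid_row", "grid_col")])) {
    stop_bad_arg("lattice coordinates must be unique per county.")
  }
  offsets <- if (scheme == "rook") {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(dr = rep(-1L:1L, each = 3L), dc = rep(-1L:1L, 3L))[-5L, , drop = FALSE]
  }
  key <- function(r, c) paste(r, c, sep = "_")
  lookup <- setNames(registry$county_id, key(registry$grid_row, registry$grid_col))
  purrr::map_dfr(seq_len(nrow(offsets)), function(k) {
    nb <- lookup[key(registry$grid_row + offsets[k, "dr"],
                     registry$grid_col + offsets[k, "dc"])]
    tibble(county_id = registry$county_id, neighbor_id = unname(nb))
  }) %>%
    filter(!is.na(.data$neighbor_id)) %>%
    arrange(.data$county_id, .data$neighbor_id)
}
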