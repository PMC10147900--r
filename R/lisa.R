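# Bivariate local Moran (LISA) with conditional permutation inference and
# FDR-controlled cluster labelling.

#' Build row-standardized spatial weights from an adjacency list
#'
#' @param adjacency Symmetric adjacency tibble (`county_id`, `neighbor_id`),
#'   e.g. from [lattice_adjacency()]. Asymmetry is an error.
#' @param ids Optional id universe; defaults to all ids appearing in the
#'   adjacency. Ids with no neighbors (islands) are flagged and excluded
#'   from LISA computations.
#' @return Object of class `"spatial_weights"`: list with `ids`, dense
#'   row-standardized matrix `w`, and `islands`.
#' @export
build_spatial_weights <- function(adjacency, ids = NULL) {
  check_columns(adjacency, c("county_id", "neighbor_id"), "adjacency")
  pair_key <- paste(adjacency$county_id, adjacency$neighbor_id)
  rev_key <- paste(adjacency$neighbor_id, adjacency$county_id)
  if (!all(pair_key %in% rev_key)) {
    abort("adjacency is not symmetric.", class = "outagegrid_invalid_input")
  }
  ids <- ids %||% sort(unique(c(adjacency$county_id, adjacency$neighbor_id)))
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  w[cbind(match(adjacency$county_id, ids), match(adjacency$neighbor_id, ids))] <- 1
  deg <- rowSums(w)
  islands <- ids[deg == 0]
  nz <- deg > 0
  w[nz, ] <- w[nz, , drop = FALSE] / deg[nz]
  structure(list(ids = ids, w = w, islands = islands),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Row-standardized spatial weights: %d units, %d island(s)\n",
              length(x$ids), length(x$islands)))
  invisible(x)
}

# Standardize to zero mean and unit variance using population (n-denominator)
# moments.
standardize_pop <- function(v) {
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) {
    abort("zero variance: cannot standardize.",
          class = "outagegrid_degenerate_input")
  }
  (v - m) / s
}

#' Bivariate local Moran statistic with conditional permutation inference
#'
#' For each county *i*, the statistic is `x_i * lag_i`, where `x` is the
#' vulnerability variable, `lag_i = sum_j w_ij y_j` is the spatial lag of
#' the outage variable among *i*'s neighbors, and both variables are
#' standardized to zero mean and unit variance (population moments) over the
#' included counties. Inference is by conditional permutation: holding `x_i`
#' and `y_i` fixed, the remaining `n - 1` values of `y` are randomly
#' reassigned to *i*'s neighbors `n_permutations` times, and the two-sided
#' pseudo p-value is `(1 + #{|perm| >= |observed|}) / (n_permutations + 1)`.
#' The quadrant is taken from the signs of `x_i` and the observed lag.
#'
#' @param data Tibble with `county_id` and the two analysis variables.
#' @param x,y Column names (strings) of the vulnerability variable and the
#'   outage variable.
#' @param weights `spatial_weights` from [build_spatial_weights()]; islands
#'   are excluded.
#' @param n_permutations Number of conditional permutations (>= 99);
#'   published practice uses 99,999.
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @return Tibble of class `"lisa_result"`: `county_id`, `x_std`, `lag_y`,
#'   `local_stat`, `pseudo_p`, `quadrant`. Attributes: `n_permutations`,
#'   `global_moran` (= mean of the local statistics), `islands`.
#' @export
bivariate_local_moran <- function(data, x, y, weights, n_permutations = 999L,
                                  seed = 1L) {
  stopifnot(inherits(weights, "spatial_weights"))
  n_permutations <- check_count(n_permutations, "n_permutations", min = 99)
  check_columns(data, c("county_id", x, y), "data")
  keep_ids <- setdiff(weights$ids, weights$islands)
  df <- data %>% filter(.data$county_id %in% keep_ids)
  if (!setequal(df$county_id, keep_ids)) {
    abort("`data` must cover every non-island county in `weights`.",
          class = "outagegrid_invalid_input")
  }
  df <- df[match(keep_ids, df$county_id), , drop = FALSE]
  w <- weights$w[keep_ids, keep_ids, drop = FALSE]
  # Re-standardize rows in case island removal dropped neighbors.
  deg <- rowSums(w > 0)
  if (any(deg == 0)) {
    abort("removing islands disconnected further counties; prune the adjacency first.",
          class = "outagegrid_invalid_input")
  }
  w <- w / rowSums(w)

  xs <- standardize_pop(df[[x]])
  ys <- standardize_pop(df[[y]])
  n <- length(xs)
  lag_obs <- as.numeric(w %*% ys)
  local_obs <- xs * lag_obs

  with_seed(child_seed(seed, 6L), {
    pseudo_p <- vapply(seq_len(n), function(i) {
      nb <- which(w[i, ] > 0)
      k <- length(nb)
      wt <- w[i, nb]
      pool <- ys[-i]
      idx <- sample_distinct_rows(n - 1L, k, n_permutations)
      vals <- matrix(pool[idx], nrow = n_permutations, ncol = k)
      perm_local <- xs[i] * as.numeric(vals %*% wt)
      (1 + sum(abs(perm_local) >= abs(local_obs[i]))) / (n_permutations + 1)
    }, numeric(1))

    out <- tibble(
      county_id = keep_ids,
      x_std = xs,
      lag_y = lag_obs,
      local_stat = local_obs,
      pseudo_p = pseudo_p,
      quadrant = dplyr::case_when(
        xs >= 0 & lag_obs >= 0 ~ "high-high",
        xs < 0 & lag_obs < 0 ~ "low-low",
        xs >= 0 & lag_obs < 0 ~ "high-low",
        TRUE ~ "low-high"
      )
    )
    structure(out,
              class = c("lisa_result", class(tibble())),
              n_permutations = n_permutations,
              global_moran = mean(local_obs),
              islands = weights$islands)
  })
}

# nperm rows of k distinct indices drawn uniformly from 1..n_pool, fully
# vectorized: sample with replacement, then redraw rows containing
# duplicates until none remain.
sample_distinct_rows <- function(n_pool, k, nperm) {
  if (k > n_pool) stop_bad_arg("more neighbors than candidate values.")
  m <- matrix(sample.int(n_pool, nperm * k, replace = TRUE), nperm, k)
  if (k == 1) return(m)
  repeat {
    bad <- rep(FALSE, nrow(m))
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        bad <- bad | m[, a] == m[, b]
      }
    }
    if (!any(bad)) break
    m[bad, ] <- matrix(sample.int(n_pool, sum(bad) * k, replace = TRUE),
                       sum(bad), k)
  }
  m
}

#' Global bivariate Moran statistic
#'
#' Computed directly as `x' W y / n` on population-standardized variables;
#' equals the average of the local statistics with the same weights.
#'
#' @inheritParams bivariate_local_moran
#' @return A single number.
#' @export
global_bivariate_moran <- function(data, x, y, weights) {
  keep_ids <- setdiff(weights$ids, weights$islands)
  df <- data %>% filter(.data$county_id %in% keep_ids)
  df <- df[match(keep_ids, df$county_id), , drop = FALSE]
  w <- weights$w[keep_ids, keep_ids, drop = FALSE]
  w <- w / rowSums(w)
  xs <- standardize_pop(df[[x]])
  ys <- standardize_pop(df[[y]])
  as.numeric(crossprod(xs, w %*% ys)) / length(xs)
}

#' FDR-controlled cluster labelling of LISA results
#'
#' Applies Benjamini-Hochberg step-up control at level `alpha` over the
#' pseudo p-values of all tested counties; significant counties keep their
#' quadrant as `cluster_label`, all others become `"not-significant"`.
#'
#' @param results `lisa_result` tibble from [bivariate_local_moran()].
#' @param alpha Significance level; default 0.05.
#' @return The input with `p_adjusted`, `fdr_significant`, `cluster_label`
#'   columns.
#' @export
fdr_classify_clusters <- function(results, alpha = 0.05) {
  check_columns(results, c("pseudo_p", "quadrant"), "results")
  check_fraction(alpha, "alpha", lo = 1e-12, hi = 1)
  out <- results %>%
    mutate(
      p_adjusted = p.adjust(.data$pseudo_p, method = "BH"),
      fdr_significant = .data$p_adjusted <= alpha,
      cluster_label = dplyr::if_else(.data$fdr_significant, .data$quadrant,
                                     "not-significant")
    )
  attributes(out)[c("n_permutations", "global_moran", "islands")] <-
    attributes(results)[c("n_permutations", "global_moran", "islands")]
  class(out) <- unique(c("lisa_result", class(out)))
  out
}

#' @export
tidy.lisa_result <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.lisa_result <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_permutations = attr(x, "n_permutations") %||% NA_integer_,
    global_moran = attr(x, "global_moran") %||% NA_real_,
    n_islands = length(attr(x, "islands") %||% character()),
    n_significant = if ("fdr_significant" %in% names(x)) {
      sum(x$fdr_significant)
    } else {
      NA_integer_
    }
  )
}
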