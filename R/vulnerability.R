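# Vulnerability analysis: quartile assignment, a tie-aware rank-sum test
# (exact by enumeration at small n), and Welch contrasts of SVI components
# between dual-burden clusters and all other counties.

#' Assign quartile labels to a numeric vector
#'
#' Cut points are the 25th/50th/75th percentiles by linear interpolation
#' (`stats::quantile(type = 7)`); intervals are left-open/right-closed above
#' the first quartile (`(q1, q2]` style), so ties sitting exactly on a cut
#' point fall into the lower quartile.
#'
#' @param x Numeric vector with at least 4 finite values.
#' @return Integer vector of quartiles 1-4 (NA for non-finite input), with a
#'   `boundaries` attribute carrying the three cut points.
#' @examples
#' assign_quartiles(c(1, 2, 3, 4))
#' @export
assign_quartiles <- function(x) {
  finite <- is.finite(x)
  if (sum(finite) < 4) stop_bad_arg("`x` needs at least 4 finite values.")
  cuts <- quantile(x[finite], probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  q <- rep(NA_integer_, length(x))
  q[finite] <- 1L + (x[finite] > cuts[1]) + (x[finite] > cuts[2]) +
    (x[finite] > cuts[3])
  structure(q, boundaries = cuts)
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-sided rank-sum test using midranks for ties. When the combined sample
#' size is at most `exact_max` (default 12) the null distribution of the
#' group-A rank sum is enumerated over all assignments of ranks to group A,
#' giving an exact p-value even with ties; otherwise a normal approximation
#' with tie correction and continuity correction is used. The two-sided
#' p-value is `min(1, 2 * min(lower tail, upper tail))`, tails inclusive.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param exact_max Largest combined n for exact enumeration.
#' @return Object of class `"rank_sum_test"`: list with `statistic` (rank
#'   sum of `a`), `p_value`, `method`, `n_a`, `n_b`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exactly 0.1
#' @export
rank_sum_test <- function(a, b, exact_max = 12L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    abort("both groups must be nonempty.", class = "outagegrid_invalid_input")
  }
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))            # midranks
  w <- sum(r[seq_len(n_a)])
  if (n <= exact_max) {
    sums <- colSums(matrix(r[combn(n, n_a)], nrow = n_a))
    p_lo <- mean(sums <= w)
    p_hi <- mean(sums >= w)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    e_w <- n_a * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v_w <- n_a * n_b / 12 * ((n + 1) - tie_term)
    z <- (w - e_w - sign(w - e_w) * 0.5) / sqrt(v_w)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  structure(
    list(statistic = w, p_value = p, method = method, n_a = n_a, n_b = n_b),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("Rank-sum test (", x$method, ")\n", sep = "")
  cat(sprintf("  W = %g (n_a = %d, n_b = %d), two-sided p = %.4g\n",
              x$statistic, x$n_a, x$n_b, x$p_value))
  invisible(x)
}

#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method)
}

#' @export
glance.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, n.a = x$n_a, n.b = x$n_b,
         method = x$method)
}

#' Compare SVI components between a county set and all others
#'
#' For each SVI component column, reports group means for the selected
#' counties (typically a high-high LISA cluster) versus all remaining
#' counties, with a Welch two-sided t-test per component. Components where
#' either group has fewer than 2 counties get `NA` p-values and are flagged.
#'
#' @param vulnerability Vulnerability tibble (`county_id` + component
#'   columns).
#' @param cluster_ids Character vector of county ids in the cluster.
#' @param components Component column names; defaults to the 16 standard SVI
#'   component columns present in the table.
#' @return Tibble: `component`, `mean_cluster`, `mean_other`, `difference`,
#'   `p_value`, `testable`.
#' @export
compare_svi_components <- function(vulnerability, cluster_ids,
                                   components = NULL) {
  check_columns(vulnerability, "county_id", "vulnerability")
  components <- components %||% intersect(SVI_COMPONENTS, names(vulnerability))
  if (!length(components)) stop_bad_arg("no component columns found.")
  in_cluster <- vulnerability$county_id %in% cluster_ids
  if (!any(in_cluster) || all(in_cluster)) {
    abort("both the cluster and its complement must be nonempty.",
          class = "outagegrid_invalid_input")
  }
  purrr::map_dfr(components, function(cmp) {
    x <- vulnerability[[cmp]][in_cluster]
    y <- vulnerability[[cmp]][!in_cluster]
    testable <- length(x) >= 2 && length(y) >= 2
    p <- if (testable) {
      # degenerate (constant) data has no defined t statistic
      tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
    } else {
      NA_real_
    }
    tibble(component = cmp, mean_cluster = mean(x), mean_other = mean(y),
           difference = mean(x) - mean(y), p_value = p, testable = testable)
  })
}
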