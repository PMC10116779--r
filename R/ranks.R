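#' Weighted fractional rank over an ordered deprivation scale
#'
#' Each record's fractional rank is its weighted midpoint position in the
#' cumulative deprivation ordering: categories are taken most-deprived
#' first, and a record's rank is (cumulative weight of strictly
#' more-deprived categories + half its own category's weight) divided by the
#' total weight. Records sharing a category share the mid-rank (no
#' jittering), and the weighted mean rank is exactly 0.5.
#'
#' With the package's coding (higher level = more deprived) the most
#' deprived end up near rank 0, so an outcome concentrated among the
#' deprived has negative rank covariance and a negative concentration index.
#'
#' @param levels Factor (or integer codes) on a deprivation-ordered scale
#'   whose coding order runs least- to most-deprived.
#' @param weights Positive weights, one per record (default: equal).
#' @return Numeric vector of fractional ranks in (0, 1).
#' @export
#' @examples
#' weighted_fractional_rank(factor(1:5, levels = 1:5)) # 0.9 0.7 0.5 0.3 0.1
weighted_fractional_rank <- function(levels, weights = NULL) {
  f <- if (is.factor(levels)) levels else factor(levels, levels = sort(unique(levels)))
  if (anyNA(f)) {
    stop_healthineq("unknown or missing level in deprivation scale",
                    "healthineq_input_error")
  }
  n <- length(f)
  w <- weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w > 0))

  r_cat <- category_fractional_ranks(f, w)
  unname(r_cat[as.character(f)])
}

## mid-rank per category, named by level, most deprived (highest code) first
category_fractional_ranks <- function(f, w) {
  cat_order <- rev(levels(f))
  w_cat <- vapply(cat_order, function(l) sum(w[f == l]), numeric(1))
  total <- sum(w_cat)
  setNames((cumsum(w_cat) - w_cat / 2) / total, cat_order)
}

#' Weighted covariance (population form)
#'
#' `sum(w * (y - mu) * (r - rbar)) / sum(w)` with weighted means `mu`,
#' `rbar`; reduces to the population (divide-by-n) covariance when all
#' weights are equal.
#'
#' @param y,r Numeric vectors of equal length (>= 2).
#' @param w Positive weights (default: equal).
#' @return The weighted covariance.
#' @export
#' @examples
#' weighted_cov(c(1, 0), c(0.25, 0.75)) # -0.125
weighted_cov <- function(y, r, w = NULL) {
  n <- length(y)
  if (n < 2) {
    stop_healthineq("need at least 2 records for a covariance",
                    "healthineq_input_error")
  }
  stopifnot(length(r) == n)
  w <- w %||% rep(1, n)
  stopifnot(length(w) == n, all(w > 0))
  mu <- wmean(y, w)
  rbar <- wmean(r, w)
  sum(w * (y - mu) * (r - rbar)) / sum(w)
}

#' Bundle an outcome with its deprivation ranks
#'
#' Constructs the ranked-outcome object the concentration indices operate
#' on: the outcome `y` with declared bounds `(a, b)`, weights, the weighted
#' fractional ranks over the deprivation scale, and the weighted mean.
#'
#' @param y Outcome per record: a 0/1 flag (bounds 0, 1) or a bounded
#'   continuous measure such as BMI.
#' @param levels Deprivation-ordered factor, see
#'   [weighted_fractional_rank()].
#' @param weights Positive weights (default: equal).
#' @param bounds Length-2 numeric `c(a, b)` with `a < b`; defaults to
#'   `c(0, 1)` for binary outcomes.
#' @param rank_table Optional named per-category rank vector (from a wider
#'   reference population, e.g. national ranks carried into a regional
#'   stratum); by default ranks are computed from `levels` and `weights`
#'   themselves, in which case the weighted mean rank is exactly 0.5.
#' @return Object of class `ranked_vector`: list with `y`, `a`, `b`, `w`,
#'   `r`, `mu`, `levels`.
#' @export
ranked_vector <- function(y, levels, weights = NULL, bounds = c(0, 1),
                          rank_table = NULL) {
  n <- length(y)
  stopifnot(length(levels) == n, length(bounds) == 2)
  a <- bounds[1]; b <- bounds[2]
  if (!(a < b)) {
    stop_healthineq("bounds must satisfy a < b", "healthineq_input_error")
  }
  if (anyNA(y)) {
    stop_healthineq("outcome has missing values; subset to responders first",
                    "healthineq_input_error")
  }
  if (min(y) < a || max(y) > b) {
    stop_healthineq(
      sprintf("outcome outside declared bounds [%g, %g]", a, b),
      "healthineq_input_error"
    )
  }
  w <- weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w > 0))
  r <- if (is.null(rank_table)) {
    weighted_fractional_rank(levels, w)
  } else {
    rr <- unname(rank_table[as.character(levels)])
    if (anyNA(rr)) {
      stop_healthineq("rank_table missing some observed levels",
                      "healthineq_input_error")
    }
    rr
  }
  structure(
    list(y = as.numeric(y), a = a, b = b, w = as.numeric(w), r = r,
         mu = wmean(y, w), levels = levels, rank_table = rank_table),
    class = "ranked_vector"
  )
}

#' @export
print.ranked_vector <- function(x, ...) {
  cat(sprintf("<ranked_vector> n=%d, bounds [%g, %g], weighted mean %.4f\n",
              length(x$y), x$a, x$b, x$mu))
  invisible(x)
}
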