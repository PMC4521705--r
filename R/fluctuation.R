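#' Lea-Coulson method-of-the-median estimate of m
#'
#' Solves the Lea-Coulson median equation `r/m - ln(m) = 1.24` for `m`, the
#' expected number of mutation events per culture, given the median mutant
#' count `r` of a fluctuation assay. The left side is strictly decreasing in
#' `m`, so the root is unique; it is found by bracketed bisection to a
#' relative tolerance of 1e-10. A median of 0 maps to `m = 0`.
#'
#' @param median_count Median mutant colony count (non-negative real; may be
#'   a half-integer for even numbers of cultures).
#' @return The estimate `m` (non-negative real).
#' @examples
#' lea_coulson_m(1.24)  # exactly m = 1
#' @export
lea_coulson_m <- function(median_count) {
  if (length(median_count) != 1L || is.na(median_count) || median_count < 0)
    stop("'median_count' must be a single non-negative number", call. = FALSE)
  if (median_count == 0) return(0)
  f <- function(m) median_count / m - log(m) - 1.24
  # bracket: f > 0 for small m, f < 0 for large m
  lo <- median_count / (1.24 + log(1 + median_count) + 50)
  while (f(lo) < 0) lo <- lo / 2
  hi <- max(1, median_count)
  while (f(hi) > 0) hi <- hi * 2
  repeat {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) / hi < 1e-10) break
  }
  (lo + hi) / 2
}

#' Dixon-Massey order-statistic ranks for a CI on the median
#'
#' Finds the largest symmetric pair of ranks `(k, n - k + 1)` whose binomial
#' coverage `P(k <= B <= n - k)` with `B ~ Binomial(n, 1/2)` is at least the
#' nominal level; the order statistics at those ranks bound the median
#' nonparametrically.
#'
#' @param n Number of observations (>= 1).
#' @param level Nominal confidence level (default 0.95).
#' @return Integer vector `c(lower, upper)` of ranks; `c(1, n)` when even the
#'   extreme ranks do not reach the level.
#' @examples
#' dixon_massey_ranks(10)  # ranks 2 and 9 (coverage 0.9785)
#' @export
dixon_massey_ranks <- function(n, level = 0.95) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (n <= 2) return(c(1L, as.integer(n)))
  for (k in rev(seq_len(floor((n + 1) / 2)))) {
    coverage <- 1 - 2 * stats::pbinom(k - 1, n, 0.5)
    if (coverage >= level) return(c(as.integer(k), as.integer(n - k + 1)))
  }
  c(1L, as.integer(n))
}

#' Mutation rate from a fluctuation assay
#'
#' Method-of-the-median mutation-rate estimation: the median mutant count
#' (divided by the plating fraction when only part of each culture was
#' plated) is converted to the expected mutations per culture `m` by
#' [lea_coulson_m()], and the rate per cell per generation is `mu = m / n_t`
#' with `n_t` the final cells per culture. The 95% confidence interval is
#' nonparametric: Dixon-Massey order-statistic bounds on the median count,
#' each mapped through the same `m -> mu` transform.
#'
#' @param experiment A [fluctuation_experiment()].
#' @param level Confidence level for the Dixon-Massey interval.
#' @return A one-row data frame with columns `strain`, `n_cultures`,
#'   `median_count`, `m_hat`, `mu_hat`, `ci_low`, `ci_high`.
#' @export
mutation_rate <- function(experiment, level = 0.95) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  adj <- sort(experiment$counts / experiment$plating_fraction)
  n <- length(adj)
  med <- stats::median(adj)
  ranks <- dixon_massey_ranks(n, level)
  lo_count <- adj[ranks[1]]
  hi_count <- adj[ranks[2]]
  to_mu <- function(r) lea_coulson_m(r) / experiment$n_t
  data.frame(strain = experiment$strain, n_cultures = n, median_count = med,
             m_hat = lea_coulson_m(med), mu_hat = to_mu(med),
             ci_low = to_mu(lo_count), ci_high = to_mu(hi_count))
}

#' Fold change between two mutation-rate estimates
#'
#' Ratio of point estimates, e.g. a mutator strain's rate over the wild-type
#' reference rate.
#'
#' @param test,reference One-row data frames from [mutation_rate()] (or any
#'   lists with a `mu_hat` field).
#' @return The ratio `test$mu_hat / reference$mu_hat`.
#' @export
rate_fold_change <- function(test, reference) {
  if (reference$mu_hat <= 0)
    stop("reference rate must be positive", call. = FALSE)
  test$mu_hat / reference$mu_hat
}

#' Pairwise Kruskal-Wallis tests between strains
#'
#' Rank-based comparison (with tie correction) of mutant-count distributions
#' for every unordered pair of strains, as used to compare median reversion
#' rates between mutator and non-mutator strains. Delegates each pair to
#' [stats::kruskal.test()]; with two groups the statistic is chi-square
#' distributed with 1 degree of freedom under the null.
#'
#' @param groups A named list mapping strain label to a numeric vector of
#'   counts (each of length >= 3).
#' @return A data frame with columns `strain_a`, `strain_b`, `H`, `p`.
#' @examples
#' kruskal_wallis_pairwise(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
kruskal_wallis_pairwise <- function(groups) {
  if (length(groups) < 2 || is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named list of at least two strains", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 3))
    stop("each group needs at least 3 values", call. = FALSE)
  pairs <- utils::combn(names(groups), 2)
  out <- apply(pairs, 2L, function(pr) {
    a <- groups[[pr[1]]]
    b <- groups[[pr[2]]]
    if (length(unique(c(a, b))) == 1L) {
      c(H = 0, p = 1)  # all values identical: no rank information
    } else {
      kt <- stats::kruskal.test(list(a, b))
      c(H = unname(kt$statistic), p = kt$p.value)
    }
  })
  data.frame(strain_a = pairs[1, ], strain_b = pairs[2, ],
             H = out["H", ], p = out["p", ], row.names = NULL)
}
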