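#' Generations completed between two population censuses
#'
#' Serial-transfer generation accounting: the number of doublings between an
#' initial and a final cell count, `log2(nt / n0)`. Negative when the
#' population shrank.
#'
#' @param n0 Cell count at the start of the interval (positive).
#' @param nt Cell count at the end of the interval (positive).
#' @return Generations completed (real).
#' @examples
#' generations(2e7, 2e9)  # a 100-fold expansion: ~6.64 doublings
#' @export
generations <- function(n0, nt) {
  if (any(n0 <= 0) || any(nt <= 0))
    stop("cell counts must be positive", call. = FALSE)
  log2(nt / n0)
}

#' Relative fitness from a marked competition assay
#'
#' The per-generation change in the ratio of a focal to a reference
#' population: `w = ((pt/qt) / (p0/q0))^(1/t)`. `w > 1` means the focal
#' population gained on the reference; `w = 1` exactly when the ratio is
#' unchanged.
#'
#' Zero colony counts make the ratio degenerate. No correction is applied
#' silently: set `pseudocount = 0.5` to apply a Haldane-style correction
#' (added to all four counts) explicitly.
#'
#' @param assay A [competition_assay()].
#' @param pseudocount Value added to all four counts before forming ratios
#'   (default 0: none).
#' @return The relative fitness `w` (positive real).
#' @examples
#' relative_fitness(competition_assay(100, 100, 146, 100, t = 7))
#' @export
relative_fitness <- function(assay, pseudocount = 0) {
  stopifnot(inherits(assay, "competition_assay"))
  counts <- c(assay$p0, assay$q0, assay$pt, assay$qt) + pseudocount
  if (any(counts == 0))
    stop("zero colony count makes the fitness ratio degenerate; ",
         "no correction is applied silently - pass pseudocount = 0.5 to use ",
         "a Haldane correction", call. = FALSE)
  ((counts[3] / counts[4]) / (counts[1] / counts[2]))^(1 / assay$t)
}

#' Summarize replicate competition assays
#'
#' Computes the per-assay relative fitness and reports the replicate mean,
#' its standard error (sd / sqrt(n)), and the replicate count, as fitness
#' tables are conventionally printed (mean +/- SEM, n).
#'
#' @param assays A non-empty list of [competition_assay()] objects sharing one
#'   medium.
#' @param pseudocount Passed to [relative_fitness()].
#' @return A one-row data frame with columns `medium`, `mean_w`, `sem_w`, `n`.
#' @export
summarize_fitness <- function(assays, pseudocount = 0) {
  if (length(assays) == 0) stop("need at least one assay", call. = FALSE)
  media <- unique(vapply(assays, function(a) a$medium, ""))
  if (length(media) > 1)
    stop("assays span multiple media (", paste(media, collapse = ", "),
         "); summarize each medium separately", call. = FALSE)
  w <- vapply(assays, relative_fitness, 0, pseudocount = pseudocount)
  n <- length(w)
  data.frame(medium = media, mean_w = mean(w),
             sem_w = if (n > 1) stats::sd(w) / sqrt(n) else 0,
             n = n)
}

#' One-way ANOVA for two groups of fitness values
#'
#' Classical fixed-effects one-way analysis of variance, computed from sums
#' of squares so the statistic is directly checkable against a permutation
#' oracle. Returns the F statistic and the upper-tail p-value from the F
#' distribution with (k - 1, N - k) degrees of freedom.
#'
#' When every value in both groups is identical the statistic is undefined
#' (0/0); by convention F = 0 and p = 1 are returned with the `degenerate`
#' flag set.
#'
#' @param group_a,group_b Numeric vectors of at least two values each.
#' @return A list with `F`, `p`, `df` (length 2) and `degenerate` (logical).
#' @examples
#' one_way_anova(c(1, 2, 3), c(2, 3, 4))
#' @export
one_way_anova <- function(group_a, group_b) {
  groups <- list(group_a, group_b)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  k <- length(groups)
  N <- length(x)
  grand <- mean(x)
  means <- tapply(x, g, mean)
  ns <- tabulate(g)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((x - means[g])^2)
  df <- c(k - 1, N - k)
  if (ss_within == 0 && ss_between == 0)
    return(list(F = 0, p = 1, df = df, degenerate = TRUE))
  if (ss_within == 0)
    return(list(F = Inf, p = 0, df = df, degenerate = TRUE))
  f <- (ss_between / df[1]) / (ss_within / df[2])
  list(F = f, p = stats::pf(f, df[1], df[2], lower.tail = FALSE),
       df = df, degenerate = FALSE)
}

#' Wilcoxon signed-rank test for paired growth readings
#'
#' Two-sided signed-rank test on paired observations (e.g. growth of the same
#' cultures under two conditions). Zero differences are dropped; the
#' statistic `W` is the sum of the ranks of positive differences. The exact
#' null distribution is enumerated (by convolution over signed ranks, so tied
#' ranks are handled) for n <= 15 non-zero pairs; above that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param paired_a,paired_b Numeric vectors of equal length.
#' @return A list with `W`, `p`, `n` (non-zero pairs) and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length", call. = FALSE)
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("no nonzero differences", call. = FALSE)
  if (n < 5) stop("need at least 5 nonzero differences", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 15) {
    # Exact: distribution of W over all 2^n sign assignments, built by
    # convolution on doubled ranks (doubling keeps midranks integral).
    r2 <- round(2 * r)
    total2 <- sum(r2)
    probs <- 1
    for (rr in r2) {
      shifted <- c(rep(0, rr), probs)
      probs <- c(probs, rep(0, rr)) + shifted
    }
    probs <- probs / 2^n
    W2 <- round(2 * W)
    p_ge <- sum(probs[(W2 + 1):(total2 + 1)])
    p_le <- sum(probs[1:(W2 + 1)])
    p <- min(1, 2 * min(p_ge, p_le))
    list(W = W, p = p, n = n, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    list(W = W, p = p, n = n, method = "normal")
  }
}
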