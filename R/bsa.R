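#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test of association for a 2x2 contingency table
#' `[[a, b], [c, d]]`, conditioning on both margins. The two-sided p-value
#' follows the probability-mass criterion: the sum of hypergeometric
#' probabilities of all tables with the same margins whose probability is at
#' most that of the observed table. Probabilities are compared in log space
#' with a relative tolerance of 1e-12 so floating-point representations of
#' exactly tied tables are counted consistently, and the sum is accumulated
#' from log probabilities for numerical stability at large counts.
#'
#' @param a,b,c,d Non-negative integer cell counts (row 1 = `a`, `b`;
#'   row 2 = `c`, `d`).
#' @return The two-sided p-value. Degenerate tables (an empty row or column
#'   margin) return 1.
#' @examples
#' fisher_exact_two_sided(1, 58, 54, 1)   # strong association
#' fisher_exact_two_sided(5, 5, 5, 5)     # perfectly balanced: p = 1
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- stats::dhyper(support, r1, r2, c1, log = TRUE)
  log_obs <- stats::dhyper(a, r1, r2, c1, log = TRUE)
  keep <- logp <= log_obs + log1p(1e-12)
  min(1, sum(exp(logp[keep])))
}

#' Remove ancestral variants from an evolved variant set
#'
#' Variants already present in the unevolved ancestor are experimental
#' background, not evolved changes, and are subtracted before linkage
#' analysis. Variant identity is `(chrom, pos, ref_allele, alt_allele)`.
#'
#' @param evolved A [variant_pool_counts()] data frame (or any data frame
#'   with the four identity columns).
#' @param ancestor A data frame with the same identity columns listing the
#'   ancestor's variants.
#' @return `evolved` with ancestral rows removed, order preserved.
#' @export
subtract_ancestral <- function(evolved, ancestor) {
  id <- function(df)
    paste(df$chrom, df$pos, df$ref_allele, df$alt_allele, sep = "\r")
  if (nrow(evolved) == 0 || nrow(ancestor) == 0) return(evolved)
  evolved[!id(evolved) %in% id(ancestor), , drop = FALSE]
}

#' Filter variants by calling quality
#'
#' Keeps variants whose quality score is at least the threshold; variants
#' with quality strictly below it are removed (so a score exactly at the
#' threshold is kept). Variants without a quality score (`NA`) are kept.
#'
#' @param variants A [variant_pool_counts()] data frame.
#' @param min_quality Threshold (default 75).
#' @return The filtered data frame.
#' @export
filter_quality <- function(variants, min_quality = 75) {
  if (nrow(variants) == 0) return(variants)
  keep <- is.na(variants$quality) | variants$quality >= min_quality
  variants[keep, , drop = FALSE]
}

#' Per-SNP linkage scan over pooled read counts
#'
#' Tests every variant for non-random segregation between the resistant and
#' sensitive pools with a two-sided Fisher exact test on the 2x2 table
#' `[[r_wt, r_snp], [s_wt, s_snp]]`. A variant is called linked when its
#' p-value is below `alpha`. The direction of the association is reported:
#' `alt_with_resistant` when the alternate allele is enriched in the
#' resistant pool, `alt_with_sensitive` for the reverse, `balanced` when the
#' cross products are equal. A Bonferroni-adjusted call (threshold
#' `alpha / n_variants`) is reported alongside, since a single scan tests
#' many variants.
#'
#' @param variants A [variant_pool_counts()] data frame (already filtered).
#' @param alpha Significance threshold for the linkage call (default 1e-4).
#' @return A data frame: the input columns plus `p_value`, `linked`,
#'   `linked_bonferroni` and `odds_direction`.
#' @examples
#' tab2 <- read_pool_counts_tsv(saltadapt_example("table2_pool_counts.tsv"))
#' linkage_scan(tab2)
#' @export
linkage_scan <- function(variants, alpha = 1e-4) {
  out <- as.data.frame(variants)
  n <- nrow(out)
  if (n == 0) {
    out$p_value <- numeric(0); out$linked <- logical(0)
    out$linked_bonferroni <- logical(0); out$odds_direction <- character(0)
    return(out)
  }
  out$p_value <- vapply(seq_len(n), function(i)
    fisher_exact_two_sided(out$r_wt[i], out$r_snp[i], out$s_wt[i], out$s_snp[i]),
    0)
  out$linked <- out$p_value < alpha
  out$linked_bonferroni <- out$p_value < alpha / n
  cross <- out$r_snp * out$s_wt - out$r_wt * out$s_snp
  out$odds_direction <- ifelse(cross > 0, "alt_with_resistant",
                               ifelse(cross < 0, "alt_with_sensitive", "balanced"))
  out
}
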