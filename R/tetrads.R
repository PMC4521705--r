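#' Classify the segregation pattern of one tetrad
#'
#' A trait controlled by a single heterozygous locus segregates 2 resistant :
#' 2 sensitive among the four spores of a tetrad. The class label is the
#' resistant:sensitive ratio (`"2:2"`, `"3:1"`, `"1:3"`, `"4:0"`, `"0:4"`);
#' any dead or unscored spore makes the tetrad `"incomplete"`.
#'
#' @param t A [tetrad_record()].
#' @return A class label (character).
#' @examples
#' classify_tetrad(tetrad_record(c("R", "R", "S", "S")))
#' @export
classify_tetrad <- function(t) {
  stopifnot(inherits(t, "tetrad_record"))
  if (any(t$spores == "dead")) return("incomplete")
  r <- sum(t$spores == "resistant")
  paste0(r, ":", 4L - r)
}

#' Dominance call from haploid and diploid phenotypes
#'
#' An evolved resistant haploid is crossed to an unevolved sensitive strain;
#' the phenotype of the resulting heterozygous diploid classifies the evolved
#' allele: a sensitive diploid means recessive transmission, a resistant one
#' dominant, an intermediate phenotype semi-dominant.
#'
#' @param haploid_pheno Phenotype of the evolved haploid; must be
#'   `"resistant"` for the call to be meaningful.
#' @param diploid_pheno One of `"resistant"`, `"sensitive"`,
#'   `"intermediate"`.
#' @return `"dominant"`, `"recessive"` or `"semi-dominant"`.
#' @export
dominance_call <- function(haploid_pheno, diploid_pheno) {
  if (!identical(haploid_pheno, "resistant"))
    stop("dominance is assessed for a resistant evolved haploid", call. = FALSE)
  diploid_pheno <- match.arg(diploid_pheno, c("resistant", "sensitive", "intermediate"))
  switch(diploid_pheno,
         sensitive = "recessive",
         resistant = "dominant",
         intermediate = "semi-dominant")
}

#' Summarize the tetrads of one cross
#'
#' Counts tetrads per segregation class and reports the fraction of complete
#' tetrads showing the single-locus 2:2 pattern. The 3:1 and 1:3 classes are
#' kept separate but their pooled count is also reported (these are the
#' "deviant" tetrads usually pooled in prose).
#'
#' @param tetrads A non-empty list of [tetrad_record()] objects.
#' @return A list with `counts` (named integer vector over classes `2:2`,
#'   `3:1`, `1:3`, `4:0`, `0:4`, `incomplete`), `deviant_3to1_pooled`,
#'   `n_complete`, and `fraction_2to2` (fraction of complete tetrads that
#'   are 2:2; `NA` and `degenerate = TRUE` when there are no complete
#'   tetrads).
#' @export
summarize_cross <- function(tetrads) {
  if (length(tetrads) == 0) stop("need at least one tetrad", call. = FALSE)
  classes <- vapply(tetrads, classify_tetrad, "")
  levels <- c("2:2", "3:1", "1:3", "4:0", "0:4", "incomplete")
  counts <- vapply(levels, function(l) sum(classes == l), 0L)
  n_complete <- sum(counts[setdiff(levels, "incomplete")])
  list(
    counts = counts,
    deviant_3to1_pooled = unname(counts["3:1"] + counts["1:3"]),
    n_complete = n_complete,
    fraction_2to2 = if (n_complete > 0) unname(counts["2:2"]) / n_complete else NA_real_,
    degenerate = n_complete == 0
  )
}
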