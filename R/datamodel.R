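#' Competition assay record
#'
#' One pairwise competition between a focal (e.g. MMR-incompatible) and a
#' reference (compatible) population, both carrying distinguishable markers.
#' Colony counts of each type are taken at the start and at the end of the
#' competition; `t` is the number of generations elapsed between the two
#' platings.
#'
#' @param p0,q0 Non-negative integer colony counts of the focal and reference
#'   populations at time zero.
#' @param pt,qt Colony counts of the focal and reference populations at the
#'   end of the competition.
#' @param t Elapsed generations (positive; defaults to 7, one 24 h cycle of
#'   growth in rich medium with salt).
#' @param medium Label for the growth medium, e.g. `"YPD"` or
#'   `"YPD+1.2M NaCl"`.
#' @return An object of class `competition_assay`.
#' @examples
#' competition_assay(p0 = 100, q0 = 100, pt = 146, qt = 100)
#' @export
competition_assay <- function(p0, q0, pt, qt, t = 7, medium = "YPD") {
  for (nm in c("p0", "q0", "pt", "qt")) {
    v <- get(nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v != floor(v))
      stop("'", nm, "' must be a single non-negative integer count", call. = FALSE)
  }
  if (p0 + q0 <= 0) stop("no colonies counted at time zero (p0 + q0 = 0)", call. = FALSE)
  if (pt + qt <= 0) stop("no colonies counted at assay end (pt + qt = 0)", call. = FALSE)
  if (length(t) != 1L || is.na(t) || t <= 0)
    stop("'t' must be a single positive number of generations", call. = FALSE)
  structure(
    list(medium = as.character(medium), p0 = as.numeric(p0), q0 = as.numeric(q0),
         pt = as.numeric(pt), qt = as.numeric(qt), t = as.numeric(t)),
    class = "competition_assay"
  )
}

#' @export
print.competition_assay <- function(x, ...) {
  cat(sprintf("<competition_assay> %s  t=%g gen  0h %g:%g  end %g:%g\n",
              x$medium, x$t, x$p0, x$q0, x$pt, x$qt))
  invisible(x)
}

#' Fluctuation-assay experiment
#'
#' Mutant (e.g. Lys+ revertant) colony counts from a set of parallel cultures
#' of one strain, together with the final number of cells per culture. The
#' mutant-count distribution across cultures is Luria-Delbruck distributed and
#' is the raw material for mutation-rate estimation.
#'
#' @param counts Non-negative integer vector, one mutant colony count per
#'   culture.
#' @param n_t Final cells per culture (positive).
#' @param plating_fraction Fraction of each culture plated, in (0, 1].
#' @param strain Strain label.
#' @return An object of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(counts, n_t, plating_fraction = 1, strain = "strain") {
  if (length(counts) == 0L) stop("'counts' must be non-empty", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  if (length(n_t) != 1L || is.na(n_t) || n_t <= 0)
    stop("'n_t' must be a single positive cell number", call. = FALSE)
  if (plating_fraction <= 0 || plating_fraction > 1)
    stop("'plating_fraction' must lie in (0, 1]", call. = FALSE)
  if (n_t < max(counts) / plating_fraction)
    stop("final population n_t is smaller than the largest (plating-adjusted) mutant count",
         call. = FALSE)
  structure(
    list(strain = as.character(strain), counts = as.numeric(counts),
         n_t = as.numeric(n_t), plating_fraction = as.numeric(plating_fraction)),
    class = "fluctuation_experiment"
  )
}

#' @export
print.fluctuation_experiment <- function(x, ...) {
  cat(sprintf("<fluctuation_experiment> %s  %d cultures, n_t = %.3g, median count %g\n",
              x$strain, length(x$counts), x$n_t, stats::median(x$counts)))
  invisible(x)
}

#' Per-SNP pooled read counts
#'
#' Builds the canonical data frame of per-variant read counts in the resistant
#' and sensitive spore pools of a bulk-segregant cross. One row per SNP.
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based positions.
#' @param ref_allele,alt_allele Reference (unevolved) and alternate (evolved)
#'   bases.
#' @param r_wt,r_snp Reads carrying the reference / alternate base in the
#'   resistant pool.
#' @param s_wt,s_snp Same in the sensitive pool.
#' @param quality Optional variant quality score (`NA` when the caller did not
#'   provide one).
#' @param line Optional label of the cross/line the variant was observed in.
#' @return A `data.frame` with class `variant_pool_counts`.
#' @export
variant_pool_counts <- function(chrom, pos, ref_allele, alt_allele,
                                r_wt, r_snp, s_wt, s_snp,
                                quality = NA_real_, line = NA_character_) {
  counts <- cbind(r_wt, r_snp, s_wt, s_snp)
  if (any(is.na(counts)) || any(counts < 0))
    stop("read counts must be non-negative", call. = FALSE)
  if (any(is.na(pos)) || any(pos < 1))
    stop("'pos' must be >= 1", call. = FALSE)
  if (any(!is.na(quality) & quality < 0))
    stop("'quality' must be non-negative when present", call. = FALSE)
  n <- length(chrom)
  quality <- rep(as.numeric(quality), length.out = n)
  line <- rep(as.character(line), length.out = n)
  ref_allele <- rep(as.character(ref_allele), length.out = n)
  alt_allele <- rep(as.character(alt_allele), length.out = n)
  df <- data.frame(
    line = as.character(line), chrom = as.character(chrom), pos = as.integer(pos),
    ref_allele = as.character(ref_allele), alt_allele = as.character(alt_allele),
    r_wt = as.integer(r_wt), r_snp = as.integer(r_snp),
    s_wt = as.integer(s_wt), s_snp = as.integer(s_snp),
    quality = as.numeric(quality),
    stringsAsFactors = FALSE
  )
  class(df) <- c("variant_pool_counts", "data.frame")
  df
}

#' Mutation call in CDS coordinates
#'
#' A single mutation expressed on the coding strand of a gene, 1-based from
#' the A of the start codon. Upstream (promoter) positions are negative;
#' there is no position 0.
#'
#' @param kind One of `"substitution"`, `"insertion"`,
#'   `"upstream_substitution"`.
#' @param position Integer CDS position (negative for upstream).
#' @param ref_base,alt_base Single bases, for substitutions.
#' @param inserted_seq Inserted bases, for insertions.
#' @return An object of class `mutation_call`.
#' @seealso [parse_mutation_notation()]
#' @export
mutation_call <- function(kind, position,
                          ref_base = NA_character_, alt_base = NA_character_,
                          inserted_seq = NA_character_) {
  kind <- match.arg(kind, c("substitution", "insertion", "upstream_substitution"))
  if (position == 0) stop("CDS coordinates have no position 0", call. = FALSE)
  if (kind == "substitution") {
    if (position < 1) stop("coding substitutions need position >= 1", call. = FALSE)
    if (is.na(ref_base) || is.na(alt_base) || ref_base == alt_base)
      stop("substitution needs ref_base != alt_base", call. = FALSE)
  }
  if (kind == "upstream_substitution") {
    if (position >= 0) stop("upstream substitutions need a negative position", call. = FALSE)
    if (is.na(ref_base) || is.na(alt_base) || ref_base == alt_base)
      stop("upstream substitution needs ref_base != alt_base", call. = FALSE)
  }
  if (kind == "insertion" && (is.na(inserted_seq) || nchar(inserted_seq) == 0))
    stop("insertion needs a non-empty inserted_seq", call. = FALSE)
  structure(
    list(kind = kind, position = as.integer(position),
         ref_base = ref_base, alt_base = alt_base, inserted_seq = inserted_seq),
    class = "mutation_call"
  )
}

#' @export
print.mutation_call <- function(x, ...) {
  cat("<mutation_call>", format_mutation_notation(x), "\n")
  invisible(x)
}

#' Canonical allele identity string of a mutation call
#'
#' Identity is kind + position + bases, so the same nucleotide change found in
#' different clones maps to the same key.
#'
#' @param call A [mutation_call()] (or the string `"none"`).
#' @return A single character key, or `NA` for `"none"`.
#' @export
allele_key <- function(call) {
  if (identical(call, "none")) return(NA_character_)
  stopifnot(inherits(call, "mutation_call"))
  switch(call$kind,
    substitution = sprintf("sub:%d:%s>%s", call$position, call$ref_base, call$alt_base),
    upstream_substitution = sprintf("up:%d:%s>%s", call$position, call$ref_base, call$alt_base),
    insertion = sprintf("ins:%d:%s", call$position, call$inserted_seq)
  )
}

#' Tetrad record
#'
#' Phenotypes of the four spores of one dissected tetrad.
#'
#' @param spores Character vector of exactly four values among
#'   `"resistant"`, `"sensitive"`, `"dead"` (unknown/unscored spores count as
#'   dead).
#' @param cross Label of the cross the tetrad came from.
#' @return An object of class `tetrad_record`.
#' @export
tetrad_record <- function(spores, cross = "cross") {
  if (length(spores) != 4L) stop("a tetrad has exactly 4 spores", call. = FALSE)
  choices <- c("resistant", "sensitive", "dead")
  idx <- pmatch(tolower(spores), choices, duplicates.ok = TRUE)
  if (any(is.na(idx)))
    stop("spore phenotypes must be 'resistant', 'sensitive' or 'dead', got: ",
         paste(spores[is.na(idx)], collapse = ", "), call. = FALSE)
  structure(list(cross = as.character(cross), spores = choices[idx]),
            class = "tetrad_record")
}
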