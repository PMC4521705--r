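#' Codon index of a CDS nucleotide position
#'
#' 1-based codon arithmetic with the reading frame starting at the first base
#' of the start codon: positions 1-3 are codon 1, 4-6 codon 2, and so on.
#'
#' @param cds_position Positive integer CDS position(s).
#' @return Positive integer codon index (vectorized).
#' @examples
#' codon_index(2027)  # codon 676
#' codon_index(412)   # codon 138
#' @export
codon_index <- function(cds_position) {
  if (any(is.na(cds_position)) || any(cds_position < 1) ||
      any(cds_position != floor(cds_position)))
    stop("CDS positions must be positive integers", call. = FALSE)
  as.integer((cds_position - 1) %/% 3 + 1)
}

#' Classify a mutation and annotate its protein consequence
#'
#' Assigns each mutation a class:
#' \describe{
#'   \item{start_disruption}{substitution within codon 1 (positions 1-3).}
#'   \item{frameshift}{insertion whose length is not a multiple of 3;
#'     annotated with the first affected codon.}
#'   \item{in_frame_insertion}{insertion of a multiple of 3 bases.}
#'   \item{upstream}{substitution upstream of the start codon.}
#'   \item{missense/nonsense/synonymous}{coding substitutions, resolved by
#'     translating the mutated codon - this requires the CDS sequence.}
#'   \item{unknown}{coding substitution beyond codon 1 when no CDS is
#'     supplied (position-only classification cannot tell missense from
#'     nonsense).}
#' }
#'
#' @param call A [mutation_call()].
#' @param cds Optional CDS as a single character string (from the A of ATG,
#'   a multiple of 3 long). When supplied, substitutions are checked against
#'   it and translated with the standard nuclear genetic code.
#' @return A list with `call`, `codon_index` (NA for upstream), `mclass` and
#'   `aa_change` (e.g. `"A676V"`; NA without a CDS).
#' @examples
#' classify_mutation(parse_mutation_notation("+ 2(AA) at bp 658"))
#' classify_mutation(parse_mutation_notation("T6A"), cds = "ATGTGTTAA")
#' @export
classify_mutation <- function(call, cds = NULL) {
  stopifnot(inherits(call, "mutation_call"))
  if (call$kind == "upstream_substitution")
    return(list(call = call, codon_index = NA_integer_, mclass = "upstream",
                aa_change = NA_character_))
  ci <- codon_index(call$position)
  if (call$kind == "insertion") {
    mclass <- if (nchar(call$inserted_seq) %% 3 != 0) "frameshift" else "in_frame_insertion"
    return(list(call = call, codon_index = ci, mclass = mclass,
                aa_change = NA_character_))
  }
  # coding substitution
  if (is.null(cds)) {
    mclass <- if (call$position <= 3) "start_disruption" else "unknown"
    return(list(call = call, codon_index = ci, mclass = mclass,
                aa_change = NA_character_))
  }
  cds <- toupper(gsub("\\s", "", cds))
  if (call$position > nchar(cds))
    stop("CDS position ", call$position, " beyond CDS length ", nchar(cds),
         call. = FALSE)
  if (substr(cds, call$position, call$position) != call$ref_base)
    stop("reference base mismatch at CDS position ", call$position, ": CDS has ",
         substr(cds, call$position, call$position), ", call says ", call$ref_base,
         call. = FALSE)
  codon_start <- (ci - 1L) * 3L + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  mut_codon <- ref_codon
  substr(mut_codon, call$position - codon_start + 1L,
         call$position - codon_start + 1L) <- call$alt_base
  ref_aa <- .translate_codon(ref_codon)
  mut_aa <- .translate_codon(mut_codon)
  mclass <- if (call$position <= 3) "start_disruption"
    else if (mut_aa == "*") "nonsense"
    else if (mut_aa == ref_aa) "synonymous"
    else "missense"
  aa_change <- if (mut_aa == ref_aa) NA_character_
    else sprintf("%s%d%s", ref_aa, ci, if (mut_aa == "*") "*" else mut_aa)
  list(call = call, codon_index = ci, mclass = mclass, aa_change = aa_change)
}

.translate_codon <- function(codon) {
  if (requireNamespace("Biostrings", quietly = TRUE))
    return(unname(Biostrings::GENETIC_CODE[codon]))
  stop("translating codons requires the 'Biostrings' package", call. = FALSE)
}

#' Count distinct mutant alleles across sequenced clones
#'
#' Deduplicates mutation calls by allele identity (kind + position + bases):
#' the same nucleotide change observed in several clones counts once. Clones
#' without a mutation are skipped. Upstream (promoter) variants are excluded
#' from the count unless `include_upstream = TRUE`, so the default counts
#' distinct coding alleles.
#'
#' @param clones A `clone_table` data frame from [read_clone_table()].
#' @param include_upstream Count upstream variants too? (default `FALSE`).
#' @return A list with `count` and `alleles` (a character vector of distinct
#'   notations, in order of first appearance).
#' @examples
#' clones <- read_clone_table(saltadapt_example("table3_clone_mutations.tsv"))
#' distinct_alleles(clones)$count  # 21 distinct coding alleles
#' @export
distinct_alleles <- function(clones, include_upstream = FALSE) {
  calls <- lapply(clones$mutation, parse_mutation_notation)
  keep <- !vapply(calls, identical, TRUE, "none")
  if (!include_upstream)
    keep <- keep & !vapply(calls, function(cl)
      !identical(cl, "none") && cl$kind == "upstream_substitution", TRUE)
  calls <- calls[keep]
  keys <- vapply(calls, allele_key, "")
  first <- !duplicated(keys)
  list(count = sum(first),
       alleles = vapply(calls[first], format_mutation_notation, ""))
}

#' Prevalence of target-gene mutations by genotype and transfer
#'
#' Tabulates, for every (genotype, transfer) cell of a clone table, how many
#' sequenced clones there are and how many carry any mutation in the target
#' gene (upstream variants count as a mutation; `"none"` rows do not).
#'
#' @param clones A `clone_table` data frame from [read_clone_table()].
#' @return A data frame with columns `genotype`, `transfer`, `clones_total`,
#'   `clones_with_mutation`.
#' @export
prevalence <- function(clones) {
  has_mut <- !vapply(lapply(clones$mutation, parse_mutation_notation),
                     identical, TRUE, "none")
  agg <- stats::aggregate(
    cbind(clones_total = rep(1L, nrow(clones)), clones_with_mutation = has_mut),
    by = list(genotype = clones$genotype, transfer = clones$transfer),
    FUN = sum
  )
  agg <- agg[order(agg$genotype, agg$transfer), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Temporal succession of alleles within one evolving line
#'
#' Orders the mutations seen in clones of one line by transfer and flags
#' replacement events: a different allele appearing at a later transfer than
#' an earlier one (consistent with a second beneficial mutation sweeping
#' before the first fixed).
#'
#' @param clones A `clone_table` data frame from [read_clone_table()].
#' @param line_id Line identifier: genotype initial + clone letter, e.g.
#'   `"ID"` for clone D of the incompatible lines (clones of one line share
#'   the letter across transfers).
#' @return A list with `line_id`, `steps` (data frame of `transfer`,
#'   `allele`) and `replacement` (logical: did the allele change between
#'   transfers?).
#' @examples
#' clones <- read_clone_table(saltadapt_example("table3_clone_mutations.tsv"))
#' succession(clones, "ID")  # T2213C at transfer 10 replaced by G3T at 16
#' @export
succession <- function(clones, line_id) {
  m <- regmatches(line_id, regexec("^([CI])(.+)$", line_id))[[1]]
  if (length(m) != 3L)
    stop("'line_id' must be a genotype initial (C/I) followed by the clone ",
         "letter, e.g. 'ID'", call. = FALSE)
  genotype <- if (m[2] == "I") "incompatible" else "compatible"
  rows <- clones[clones$genotype == genotype & clones$clone == m[3], , drop = FALSE]
  if (nrow(rows) == 0) stop("no clones for line '", line_id, "'", call. = FALSE)
  rows <- rows[order(rows$transfer), , drop = FALSE]
  alleles <- vapply(lapply(rows$mutation, parse_mutation_notation),
                    function(cl) if (identical(cl, "none")) "none"
                                 else format_mutation_notation(cl), "")
  steps <- data.frame(transfer = rows$transfer, allele = alleles)
  observed <- unique(alleles[alleles != "none"])
  list(line_id = line_id, steps = steps,
       replacement = length(observed) > 1)
}

#' Homopolymer-run context of an indel
#'
#' MMR-deficient genomes acquire most of their indels in homopolymeric runs
#' (replication slippage). This reports whether an insertion/deletion event
#' sits in such a run: the inserted (or deleted) unit must be a single
#' repeated base and the flanking sequence must carry an adjacent run of at
#' least `min_run` of that base at the event position.
#'
#' @param indel A [mutation_call()] of kind `"insertion"`.
#' @param flanking Sequence context as a character string.
#' @param at 1-based index in `flanking` after which the insertion occurred
#'   (default: centre of the string).
#' @param min_run Minimum adjacent run length to call the event "in a run"
#'   (default 3).
#' @return A list with `in_run` (logical) and `run_length` (the maximal run
#'   of the inserted base adjacent to the event position; 0 when the inserted
#'   unit is not a single repeated base).
#' @examples
#' ins <- mutation_call("insertion", 4, inserted_seq = "A")
#' homopolymer_context(ins, "CCAAAACC", at = 4)
#' @export
homopolymer_context <- function(indel, flanking, at = NULL, min_run = 3) {
  stopifnot(inherits(indel, "mutation_call"), indel$kind == "insertion")
  flanking <- toupper(gsub("\\s", "", flanking))
  n <- nchar(flanking)
  if (is.null(at)) at <- n %/% 2
  if (at < 0 || at > n)
    stop("'at' must index into the flanking sequence (0..", n, ")", call. = FALSE)
  unit <- strsplit(toupper(indel$inserted_seq), "")[[1]]
  if (length(unique(unit)) != 1L)
    return(list(in_run = FALSE, run_length = 0L))
  b <- unit[1]
  bases <- strsplit(flanking, "")[[1]]
  # maximal run of b adjacent to the insertion point (left of `at` inclusive,
  # right of `at` exclusive-start)
  run_left <- 0L
  i <- at
  while (i >= 1 && bases[i] == b) { run_left <- run_left + 1L; i <- i - 1L }
  run_right <- 0L
  i <- at + 1L
  while (i <= n && bases[i] == b) { run_right <- run_right + 1L; i <- i + 1L }
  run_length <- run_left + run_right
  list(in_run = run_length >= min_run, run_length = as.integer(run_length))
}

#' Catalog summary of a clone mutation table
#'
#' One-call overview combining distinct-allele counting and per-cell
#' prevalence, the two headline numbers of an adaptive-mutation catalog.
#'
#' @param clones A `clone_table` data frame from [read_clone_table()].
#' @param include_upstream Passed to [distinct_alleles()].
#' @return A list with `distinct` (from [distinct_alleles()]) and
#'   `prevalence` (from [prevalence()]).
#' @export
catalog_summary <- function(clones, include_upstream = FALSE) {
  list(distinct = distinct_alleles(clones, include_upstream = include_upstream),
       prevalence = prevalence(clones))
}
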