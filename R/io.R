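#' Parse the compact mutation notation of clone sequencing tables
#'
#' Understands the three notations used in clone mutation tables:
#' \describe{
#'   \item{`"C2027T"`}{coding substitution: wild-type base, 1-based CDS
#'     position, mutant base.}
#'   \item{`"T-220A"`}{substitution upstream of the start codon; the position
#'     is the number of bases upstream, stored as a negative coordinate.}
#'   \item{`"+ 2(AA) at bp 658"`}{insertion of the bracketed bases at the
#'     given CDS position; the leading integer is the insertion length.}
#' }
#' `"none"`/`"None"` (also `"n/a"`) mean no mutation was found. A trailing
#' `"*"` (a table footnote marker) is ignored.
#'
#' @param text A single notation string.
#' @return A [mutation_call()], or the string `"none"`.
#' @examples
#' parse_mutation_notation("C2027T")
#' parse_mutation_notation("+ 2(AA) at bp 658")
#' parse_mutation_notation("T-220A")
#' @export
parse_mutation_notation <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("mutation notation must be a single non-empty string", call. = FALSE)
  raw <- trimws(sub("\\*+$", "", trimws(text)))
  if (tolower(raw) %in% c("none", "n/a", "na")) return("none")

  m <- regmatches(raw, regexec("^([ACGT])(\\d+)([ACGT])$", raw))[[1]]
  if (length(m) == 4L)
    return(mutation_call("substitution", as.integer(m[3]),
                         ref_base = m[2], alt_base = m[4]))

  m <- regmatches(raw, regexec("^([ACGT])-(\\d+)([ACGT])$", raw))[[1]]
  if (length(m) == 4L)
    return(mutation_call("upstream_substitution", -as.integer(m[3]),
                         ref_base = m[2], alt_base = m[4]))

  m <- regmatches(raw, regexec("^\\+\\s*(\\d+)\\(([ACGT]+)\\)\\s+at\\s+bp\\s+(\\d+)$", raw))[[1]]
  if (length(m) == 4L) {
    if (as.integer(m[2]) != nchar(m[3]))
      stop("insertion length ", m[2], " does not match inserted bases '", m[3],
           "' in: ", text, call. = FALSE)
    return(mutation_call("insertion", as.integer(m[4]), inserted_seq = m[3]))
  }

  stop("unrecognized mutation notation: '", text, "'", call. = FALSE)
}

#' Format a mutation call back into table notation
#'
#' Inverse of [parse_mutation_notation()] (round-trips exactly, modulo
#' footnote asterisks and case of `"none"`).
#'
#' @param call A [mutation_call()] or `"none"`.
#' @return A single string.
#' @export
format_mutation_notation <- function(call) {
  if (identical(call, "none")) return("none")
  stopifnot(inherits(call, "mutation_call"))
  switch(call$kind,
    substitution = sprintf("%s%d%s", call$ref_base, call$position, call$alt_base),
    upstream_substitution = sprintf("%s%d%s", call$ref_base, call$position, call$alt_base),
    insertion = sprintf("+ %d(%s) at bp %d", nchar(call$inserted_seq),
                        call$inserted_seq, call$position)
  )
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
saltadapt_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "saltadapt")))
  path <- system.file("extdata", file, package = "saltadapt")
  if (!nzchar(path)) stop("no packaged file called '", file, "'", call. = FALSE)
  path
}

.required_pool_columns <- c("chrom", "pos", "r_wt", "r_snp", "s_wt", "s_snp")

#' Read a pooled read-count table (TSV)
#'
#' The canonical interchange format for bulk-segregant pool counts: a
#' tab-separated file with a header naming at least the columns
#' `chrom, pos, r_wt, r_snp, s_wt, s_snp` (`ref_allele`, `alt_allele`,
#' `quality` and `line` are optional). Lines starting with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @return A [variant_pool_counts()] data frame.
#' @export
read_pool_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(.required_pool_columns, names(df))
  if (length(missing_cols) > 0)
    stop("pool-count table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0)
    return(variant_pool_counts(character(), integer(), character(), character(),
                               integer(), integer(), integer(), integer()))
  count_cols <- c("r_wt", "r_snp", "s_wt", "s_snp")
  bad <- which(apply(df[count_cols], 1L, function(r) any(is.na(r)) || any(r < 0)))
  if (length(bad) > 0)
    stop("negative or missing read counts in ", path, " at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  variant_pool_counts(
    chrom = df$chrom, pos = df$pos,
    ref_allele = if ("ref_allele" %in% names(df)) df$ref_allele else NA_character_,
    alt_allele = if ("alt_allele" %in% names(df)) df$alt_allele else NA_character_,
    r_wt = df$r_wt, r_snp = df$r_snp, s_wt = df$s_wt, s_snp = df$s_snp,
    quality = if ("quality" %in% names(df)) df$quality else NA_real_,
    line = if ("line" %in% names(df)) df$line else NA_character_
  )
}

#' Write a pooled read-count table (TSV)
#'
#' @param variants A [variant_pool_counts()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_counts_tsv <- function(variants, path) {
  utils::write.table(as.data.frame(variants), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pooled allele depths from a VCF
#'
#' Convenience adapter for variant callers that report per-sample allele
#' depths (`AD`): extracts ref/alt read counts for the two pool samples into
#' the canonical count-table form. Only biallelic SNV records with an `AD`
#' field in both samples are kept; skipped records are counted in the
#' `"skipped"` attribute of the result (with a warning).
#'
#' @param path Path to a VCF (4.x) file.
#' @param resistant_sample,sensitive_sample Sample names of the resistant and
#'   sensitive pools.
#' @return A [variant_pool_counts()] data frame with attribute `"skipped"`.
#' @export
read_pool_counts_vcf <- function(path, resistant_sample, sensitive_sample) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the 'vcfR' package", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(resistant_sample, sensitive_sample)) {
    if (!s %in% samples)
      stop("sample '", s, "' not in VCF; available samples: ",
           paste(samples, collapse = ", "), call. = FALSE)
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1, dimnames = list(NULL, names(ad)))

  multiallelic <- grepl(",", fix[, "ALT"], fixed = TRUE)
  r_ad <- ad[, resistant_sample]
  s_ad <- ad[, sensitive_sample]
  has_ad <- !is.na(r_ad) & !is.na(s_ad) &
    grepl("^\\d+,\\d+$", r_ad) & grepl("^\\d+,\\d+$", s_ad)
  keep <- !multiallelic & has_ad
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    warning(n_skipped, " VCF record(s) skipped (multiallelic or missing AD)",
            call. = FALSE)

  split2 <- function(x) {
    m <- do.call(rbind, strsplit(x, ",", fixed = TRUE))
    matrix(as.integer(m), ncol = 2)
  }
  r <- split2(r_ad[keep])
  s <- split2(s_ad[keep])
  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  out <- variant_pool_counts(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref_allele = fix[keep, "REF"], alt_allele = fix[keep, "ALT"],
    r_wt = r[, 1], r_snp = r[, 2], s_wt = s[, 1], s_snp = s[, 2],
    quality = qual
  )
  attr(out, "skipped") <- n_skipped
  out
}

#' Read a clone mutation table (TSV)
#'
#' Reads a table of sequenced evolved clones in the layout of published clone
#' tables: one row per clone with columns `line` (e.g. `"C10"`, `"I16"`),
#' `clone` (a letter), `method` (`"WGS"` or a Sanger description), `mutation`
#' (compact notation, see [parse_mutation_notation()]) and optional
#' `aa_change`. Genotype (`compatible`/`incompatible`) and transfer number are
#' derived from the `line` label.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `clone_table` with derived `genotype` and
#'   `transfer` columns; every `mutation` string is checked to parse.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("line", "clone", "method", "mutation")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop("clone table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"aa_change" %in% names(df)) df$aa_change <- NA_character_
  m <- regmatches(df$line, regexec("^([CI])(\\d+)$", df$line))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad) > 0)
    stop("unparseable line label(s) at row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(df$line[bad]), collapse = ", "), call. = FALSE)
  df$genotype <- ifelse(vapply(m, `[`, "", 2L) == "I", "incompatible", "compatible")
  df$transfer <- as.integer(vapply(m, `[`, "", 3L))
  df$method <- ifelse(grepl("^WGS$", trimws(df$method)), "WGS", "Sanger")
  for (i in seq_len(nrow(df))) parse_mutation_notation(df$mutation[i])  # validate
  class(df) <- c("clone_table", "data.frame")
  df
}

#' Read a tetrad phenotype table (TSV)
#'
#' Expects columns `cross`, `tetrad` and four spore phenotype columns
#' `spore1..spore4` with values `resistant`/`sensitive`/`dead` (abbreviations
#' allowed).
#'
#' @param path Path to the TSV file.
#' @return A list of [tetrad_record()] objects.
#' @export
read_tetrad_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("cross", paste0("spore", 1:4))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop("tetrad table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    tetrad_record(unlist(df[i, paste0("spore", 1:4)], use.names = FALSE),
                  cross = df$cross[i]))
}

#' Read a competition colony-count table (TSV)
#'
#' Expects columns `medium`, `p0`, `q0`, `pt`, `qt` and optional `t`
#' (generations, default 7).
#'
#' @param path Path to the TSV file.
#' @param t Default generations when the file has no `t` column.
#' @return A list of [competition_assay()] objects.
#' @export
read_competition_tsv <- function(path, t = 7) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("medium", "p0", "q0", "pt", "qt")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop("competition table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"t" %in% names(df)) df$t <- t
  lapply(seq_len(nrow(df)), function(i)
    competition_assay(df$p0[i], df$q0[i], df$pt[i], df$qt[i],
                      t = df$t[i], medium = df$medium[i]))
}

#' Read a coding sequence from a FASTA file
#'
#' @param path Path to a FASTA file; the first sequence is used.
#' @return The CDS as a single uppercase character string.
#' @export
read_cds_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA input requires the 'Biostrings' package", call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path, call. = FALSE)
  toupper(as.character(seqs[[1]]))
}
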