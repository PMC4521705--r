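test_that("codon arithmetic follows the reading frame from the start codon", {
  expect_equal(codon_index(1), 1L)
  expect_equal(codon_index(3), 1L)
  expect_equal(codon_index(4), 2L)
  expect_equal(codon_index(2027), 676L)
  expect_equal(codon_index(412), 138L)
  expect_equal(codon_index(459), 153L)
  expect_equal(codon_index(c(658, 2213)), c(220L, 738L))
  expect_error(codon_index(0), "positive")
})

test_that("codon indices reproduce every printed amino-acid number", {
  clones <- table3_fixture()
  # rows whose annotation prints an amino-acid position (e.g. A676V, C153stop,
  # 'frameshift, amino acid 220')
  aa_num <- suppressWarnings(as.integer(
    gsub("[^0-9]", "", clones$aa_change)))
  has_num <- !is.na(aa_num) & clones$mutation != "None" &
    tolower(clones$mutation) != "none"
  expect_gte(sum(has_num), 21L)
  for (i in which(has_num)) {
    call <- parse_mutation_notation(clones$mutation[i])
    expect_equal(classify_mutation(call)$codon_index, aa_num[i],
                 info = paste(clones$mutation[i], "->", clones$aa_change[i]))
  }
})

test_that("mutation classes follow position and insertion frame rules", {
  fs <- classify_mutation(parse_mutation_notation("+ 2(AA) at bp 658"))
  expect_equal(fs$mclass, "frameshift")
  expect_equal(fs$codon_index, 220L)

  start <- classify_mutation(parse_mutation_notation("T2G"))
  expect_equal(start$mclass, "start_disruption")

  up <- classify_mutation(parse_mutation_notation("T-220A"))
  expect_equal(up$mclass, "upstream")
  expect_true(is.na(up$codon_index))

  inframe <- classify_mutation(mutation_call("insertion", 10, inserted_seq = "AAA"))
  expect_equal(inframe$mclass, "in_frame_insertion")

  noseq <- classify_mutation(parse_mutation_notation("C2027T"))
  expect_equal(noseq$mclass, "unknown")
  expect_true(is.na(noseq$aa_change))
})

test_that("CDS-aware classification translates the mutated codon", {
  skip_if_not_installed("Biostrings")
  cds <- "ATGTGTTAA"  # Met-Cys-stop
  non <- classify_mutation(parse_mutation_notation("T6A"), cds = cds)
  expect_equal(non$mclass, "nonsense")     # TGT -> TGA at codon 2
  expect_equal(non$codon_index, 2L)
  expect_equal(non$aa_change, "C2*")

  mis <- classify_mutation(parse_mutation_notation("T4G"), cds = cds)
  expect_equal(mis$mclass, "missense")     # TGT -> GGT, Cys -> Gly
  expect_equal(mis$aa_change, "C2G")
  syn <- classify_mutation(mutation_call("substitution", 6, "T", "C"), cds = cds)
  expect_equal(syn$mclass, "synonymous")   # TGT -> TGC, still Cys

  expect_error(classify_mutation(parse_mutation_notation("T100A"), cds = cds),
               "beyond")
  expect_error(classify_mutation(parse_mutation_notation("A6T"), cds = cds),
               "mismatch")
})

test_that("distinct coding alleles count each nucleotide change once", {
  clones <- table3_fixture()
  res <- distinct_alleles(clones)
  expect_equal(res$count, 21L)
  # recurrent alleles appear once (A557G found in I10 F and I16 F)
  expect_equal(sum(res$alleles == "A557G"), 1L)
  expect_true("+ 2(AA) at bp 658" %in% res$alleles)
  expect_false(any(grepl("-220", res$alleles)))
  # the upstream promoter variant joins only on request
  expect_equal(distinct_alleles(clones, include_upstream = TRUE)$count, 22L)
  # invariant to clone order and row duplication
  shuffled <- clones[rev(seq_len(nrow(clones))), ]
  expect_equal(distinct_alleles(shuffled)$count, 21L)
  doubled <- rbind(clones, clones)
  expect_equal(distinct_alleles(doubled)$count, 21L)
  expect_equal(distinct_alleles(clones[0, ])$count, 0L)
})

test_that("prevalence reproduces the published per-cell clone counts", {
  prev <- prevalence(table3_fixture())
  cell <- function(g, t) prev[prev$genotype == g & prev$transfer == t, ]
  expect_equal(cell("incompatible", 10)[, c("clones_total", "clones_with_mutation")],
               data.frame(clones_total = 14L, clones_with_mutation = 12L),
               ignore_attr = TRUE)
  expect_equal(unlist(cell("incompatible", 16)[, 3:4], use.names = FALSE), c(8L, 7L))
  expect_equal(unlist(cell("compatible", 10)[, 3:4], use.names = FALSE), c(10L, 2L))
  expect_equal(unlist(cell("compatible", 16)[, 3:4], use.names = FALSE), c(6L, 6L))
  # the upstream variant counts as carrying a mutation (it is in the 6/6)
  clones <- table3_fixture()
  none_only <- clones
  none_only$mutation <- "none"
  prev0 <- prevalence(none_only)
  expect_true(all(prev0$clones_with_mutation == 0L))
})

test_that("allele succession orders by transfer and flags replacement", {
  clones <- table3_fixture()
  d <- succession(clones, "ID")
  expect_equal(d$steps$transfer, c(10L, 16L))
  expect_equal(d$steps$allele, c("T2213C", "G3T"))
  expect_true(d$replacement)

  b <- succession(clones, "IB")
  expect_equal(b$steps$allele, c("T412C", "T412C"))
  expect_false(b$replacement)

  single <- succession(clones, "CH")   # C16 H only
  expect_equal(nrow(single$steps), 1L)
  expect_false(single$replacement)
  expect_error(succession(clones, "IZ"), "no clones")
})

test_that("homopolymer context detects runs adjacent to the insertion", {
  ins_a <- mutation_call("insertion", 4, inserted_seq = "A")
  res <- homopolymer_context(ins_a, "CCAAAACC", at = 4)
  expect_true(res$in_run)
  expect_equal(res$run_length, 4L)

  ins_g <- mutation_call("insertion", 3, inserted_seq = "G")
  expect_false(homopolymer_context(ins_g, "ATATAT", at = 3)$in_run)

  # two-base insertion next to an AAA run; cross-check with a scan oracle
  ins_aa <- mutation_call("insertion", 3, inserted_seq = "AA")
  res2 <- homopolymer_context(ins_aa, "CGAAACG", at = 3)
  expect_true(res2$in_run)
  runs <- rle(strsplit("CGAAACG", "")[[1]])
  expect_equal(res2$run_length, max(runs$lengths[runs$values == "A"]))

  # a non-homopolymeric insertion unit is never "in a run"
  ins_at <- mutation_call("insertion", 3, inserted_seq = "AT")
  expect_false(homopolymer_context(ins_at, "CGAAACG", at = 3)$in_run)
})
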