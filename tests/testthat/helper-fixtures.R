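table2_fixture <- function() {
  read_pool_counts_tsv(saltadapt_example("table2_pool_counts.tsv"))
}

table3_fixture <- function() {
  read_clone_table(saltadapt_example("table3_clone_mutations.tsv"))
}

published_linked <- function() {
  df <- utils::read.delim(saltadapt_example("table2_pool_counts.tsv"),
                          comment.char = "#")
  df$linkage == "Yes"
}

# A small VCF with the two pool samples, one multiallelic record and one
# record without allele depths.
write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "res_pool", "sens_pool", sep = "\t"),
    paste("chrVII", "190010", ".", "A", "T", "200", "PASS", ".",
          "GT:AD", "0/1:1,58", "0/1:54,1", sep = "\t"),
    paste("chrVII", "190057", ".", "A", "G", "150", "PASS", ".",
          "GT:AD", "1/1:0,91", "0/0:50,0", sep = "\t"),
    paste("chrII", "48117", ".", "C", "T,G", "99", "PASS", ".",
          "GT:AD", "0/1:42,51,0", "0/1:29,28,0", sep = "\t"),
    paste("chrIV", "13937", ".", "G", "A", "80", "PASS", ".",
          "GT", "0/1", "0/1", sep = "\t")
  ), path)
  path
}

# Independent full-enumeration oracle for the two-sided Fisher p-value:
# linear-space probabilities, probability-mass criterion.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
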