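#!/usr/bin/env Rscript
# Tetrad segregation and dominance of evolved resistance.
#
# A resistance trait caused by a single nuclear locus segregates 2:2 among
# the spores of evolved-x-unevolved diploids. This script summarizes
# simulated tetrad sets with a realistic per-spore scoring error and shows
# the dominance classification used for heterozygous diploids.

suppressPackageStartupMessages(library(saltadapt))
dir.create("results", showWarnings = FALSE)

# four crosses of ~20 tetrads each, 3% per-spore mis-scoring
crosses <- lapply(1:4, function(k)
  sim_tetrads(20, error_rate = 0.03, seed = 60 + k,
              cross = paste0("cross", k)))
summaries <- do.call(rbind, lapply(crosses, function(tt) {
  s <- summarize_cross(tt)
  data.frame(cross = tt[[1]]$cross, t(s$counts),
             deviant = s$deviant_3to1_pooled,
             fraction_2to2 = s$fraction_2to2, check.names = FALSE)
}))
write.table(summaries, "results/tetrad_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Tetrad class counts per cross (20 tetrads, 3% scoring error):\n\n")
print(summaries, row.names = FALSE, digits = 3)
cat("\nThe vast majority of tetrads segregate 2:2, as expected for a\n")
cat("single causal locus; deviants arise at the scoring-error rate.\n\n")

# dominance of the evolved allele in heterozygous diploids
diploids <- c("sensitive", "sensitive", "intermediate", "resistant")
calls <- vapply(diploids, function(d) dominance_call("resistant", d), "")
cat("Dominance calls for four example evolved-x-unevolved diploids:\n")
print(data.frame(diploid_phenotype = diploids, call = unname(calls)),
      row.names = FALSE)
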