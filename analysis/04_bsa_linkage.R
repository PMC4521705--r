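#!/usr/bin/env Rscript
# Bulk-segregant linkage from pooled whole-genome sequencing.
#
# Runs the per-SNP Fisher exact linkage scan on the packaged read-count
# table (resistant vs sensitive spore pools from four evolved-x-unevolved
# crosses) and verifies the scan's calibration on simulated pools.

suppressPackageStartupMessages(library(saltadapt))
dir.create("results", showWarnings = FALSE)

tab2 <- read_pool_counts_tsv(saltadapt_example("table2_pool_counts.tsv"))
scan <- linkage_scan(filter_quality(tab2), alpha = 1e-4)
out <- scan[, c("line", "chrom", "pos", "ref_allele", "alt_allele",
                "r_wt", "r_snp", "s_wt", "s_snp", "p_value", "linked",
                "linked_bonferroni", "odds_direction")]
write.table(out, "results/linkage_scan.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Linkage scan of the packaged pooled counts (alpha = 1e-4):\n\n")
print(out[, c("line", "chrom", "pos", "p_value", "linked")],
      row.names = FALSE, digits = 3)
cat("\nAll", sum(scan$linked), "linked SNPs fall in the chrVII target-gene",
    "region with p <", format(max(scan$p_value[scan$linked]), digits = 2),
    "\n(published bound: p < 1e-5 for every causal-locus linkage).\n")

# calibration on simulated pools
unlinked <- sim_pool_reads(FALSE, depth_per_pool = 100, n_variants = 2000,
                           seed = 41)
fp <- mean(linkage_scan(unlinked)$linked)
linked <- sim_pool_reads(TRUE, depth_per_pool = 60, n_variants = 1000,
                         error_rate = 0.02, seed = 42)
power <- mean(linkage_scan(linked)$linked)
cat(sprintf("\nCalibration: false-positive fraction %.2g on 2000 unlinked variants;\npower %.3f on 1000 linked variants (depth 60, 2%% error).\n",
            fp, power))
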