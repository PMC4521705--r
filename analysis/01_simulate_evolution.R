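#!/usr/bin/env Rscript
# Serial-transfer evolution of paired mutator / non-mutator populations.
#
# Simulates the core experiment: two populations differing only in a 100-fold
# mutation-rate elevation are passaged through 16 daily transfers under
# stress, at the standard bottleneck (2e7 cells) and at a ten-fold reduced
# one (2e6). The mutation supply (rate x population size) determines when
# beneficial-allele carriers reach a majority.

suppressPackageStartupMessages(library(saltadapt))
dir.create("results", showWarnings = FALSE)

# one illustrative trajectory per bottleneck
traj_hi <- serial_transfer(sim_config(bottleneck = 2e7, seed = 1))
traj_lo <- serial_transfer(sim_config(bottleneck = 2e6, seed = 1))
traj_hi$bottleneck <- 2e7
traj_lo$bottleneck <- 2e6
write.table(rbind(traj_hi, traj_lo), "results/trajectories.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# 200 replicate seed pairs per bottleneck: when does each population adapt?
summarise <- function(bottleneck) {
  tt <- t(sapply(1:200, function(sd) {
    traj <- serial_transfer(sim_config(bottleneck = bottleneck, seed = sd))
    c(mutator = transfers_to_majority(traj, "mutator"),
      nonmutator = transfers_to_majority(traj, "nonmutator"))
  }))
  data.frame(bottleneck = bottleneck,
             median_t_mutator = median(tt[, "mutator"]),
             median_t_nonmutator = median(tt[, "nonmutator"]),
             frac_mutator_first = mean(tt[, "mutator"] < tt[, "nonmutator"]),
             median_lead = median(tt[, "nonmutator"] - tt[, "mutator"]))
}
supply <- rbind(summarise(2e7), summarise(2e6))
write.table(supply, "results/mutation_supply.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Mutation-supply experiment (200 seed pairs, 16-transfer horizon;\n")
cat("transfer 17 = did not adapt within the experiment):\n\n")
print(supply, row.names = FALSE)
cat("\nAt the 2e7 bottleneck the mutator typically holds a beneficial\n")
cat("majority near transfer", supply$median_t_mutator[1],
    "while the non-mutator does not adapt within the horizon;\n")
cat("cutting the supply ten-fold removes the mutator's lead entirely\n")
cat("(median lead", supply$median_lead[2], "transfers at 2e6 vs",
    supply$median_lead[1], "at 2e7).\n")
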