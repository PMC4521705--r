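#' Configuration for the serial-transfer evolution simulator
#'
#' Parameters of a genotype-class serial-transfer model of two competing
#' scenarios run side by side: a non-mutator population and a mutator whose
#' mutation rates are elevated `mutator_fold`-fold (the hallmark of an MMR
#' defect). Cells are classified by whether they carry a beneficial
#' (stress-resistance) allele and by their deleterious-load bin; mutation
#' supply per transfer is the product of the mutation rate and the number of
#' cells, so the bottleneck size controls how quickly beneficial alleles
#' arise.
#'
#' Default rates: `mu_beneficial` is the per-cell per-generation rate of
#' strongly beneficial stress-resistance mutations in the non-mutator
#' (a narrow mutational target), `mu_base` the rate of deleterious hits, and
#' `s_beneficial` the per-generation selective advantage of a resistance
#' allele under stress (large-effect alleles; resistant colonies visibly
#' outgrow sensitive ones). `s_deleterious` is the multiplicative cost per
#' deleterious hit; with the defaults, load effects stay small across a
#' 16-transfer experiment, matching the observation that mutator and
#' non-mutator fitness in permissive medium stay similar.
#'
#' @param bottleneck Cells transferred each cycle (default 2e7; the
#'   low-supply variant uses 2e6).
#' @param gens_per_transfer Generations completed per 24 h cycle (default
#'   6.6, typical of growth in rich medium with 1.2 M NaCl; ~8.5 in rich
#'   medium alone).
#' @param transfers Number of transfer cycles (default 16).
#' @param mu_base Deleterious mutation rate per cell per generation
#'   (non-mutator).
#' @param mutator_fold Fold elevation of all rates in the mutator
#'   (default 100).
#' @param mu_beneficial Beneficial-target mutation rate per cell per
#'   generation (non-mutator).
#' @param s_beneficial Selection coefficient of the beneficial allele under
#'   stress.
#' @param s_deleterious Multiplicative fitness cost per deleterious hit.
#' @param load_bins Number of deleterious-load bins beyond load 0.
#' @param seed Integer seed; the two populations get distinct derived
#'   sub-seeds.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(bottleneck = 2e7, gens_per_transfer = 6.6, transfers = 16,
                       mu_base = 1e-4, mutator_fold = 100,
                       mu_beneficial = 5e-11, s_beneficial = 0.35,
                       s_deleterious = 0.02, load_bins = 8, seed = 1) {
  stopifnot(bottleneck >= 1, gens_per_transfer > 0, transfers >= 1,
            mu_base >= 0, mutator_fold >= 1, mu_beneficial >= 0,
            s_beneficial >= 0, s_deleterious >= 0, s_deleterious < 1,
            load_bins >= 1)
  structure(list(bottleneck = bottleneck, gens_per_transfer = gens_per_transfer,
                 transfers = as.integer(transfers), mu_base = mu_base,
                 mutator_fold = mutator_fold, mu_beneficial = mu_beneficial,
                 s_beneficial = s_beneficial, s_deleterious = s_deleterious,
                 load_bins = as.integer(load_bins), seed = as.integer(seed)),
            class = "sim_config")
}

.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483587)
}

# Poisson draw that stays finite for very large means (normal approximation
# above the range where rpois is exact and fast).
.rpois_big <- function(n, lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e9
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- round(stats::rnorm(sum(big), lambda[big], sqrt(lambda[big])))
  pmax(out, 0)
}

# One population for one full serial-transfer experiment.
# counts: 2 x (load_bins + 1) matrix, row 1 non-carrier, row 2 carrier.
.run_population <- function(config, fold, seed) {
  set.seed(seed)
  L <- config$load_bins
  counts <- matrix(0, nrow = 2, ncol = L + 1)
  counts[1, 1] <- config$bottleneck
  mu_b <- config$mu_beneficial * fold
  mu_d <- config$mu_base * fold
  loads <- 0:L
  w_class <- rbind((1 - config$s_deleterious)^loads,
                   (1 + config$s_beneficial) * (1 - config$s_deleterious)^loads)
  g <- config$gens_per_transfer
  steps <- c(rep(1, floor(g)), if (g > floor(g)) g - floor(g))

  out <- data.frame(transfer = seq_len(config$transfers), generations = NA_real_,
                    carrier_freq = NA_real_, mean_load = NA_real_,
                    census_before = NA_real_, census_after = NA_real_)
  gens_done <- 0
  for (tr in seq_len(config$transfers)) {
    for (dt in steps) {
      before <- counts
      counts <- counts * (2 * w_class)^dt
      new_cells <- pmax(counts - before, 0)
      # beneficial mutations arise among newly made non-carrier cells
      if (mu_b > 0) {
        m <- pmin(.rpois_big(L + 1, mu_b * new_cells[1, ]), floor(counts[1, ]))
        counts[1, ] <- counts[1, ] - m
        counts[2, ] <- counts[2, ] + m
      }
      # deleterious hits push cells one load bin up (top bin absorbs)
      if (mu_d > 0) {
        d <- pmin(.rpois_big(2 * L, mu_d * new_cells[, 1:L]),
                  floor(counts[, 1:L]))
        d <- matrix(d, nrow = 2)
        counts[, 1:L] <- counts[, 1:L] - d
        counts[, 2:(L + 1)] <- counts[, 2:(L + 1)] + d
      }
    }
    gens_done <- gens_done + g
    total <- sum(counts)
    out$generations[tr] <- gens_done
    out$carrier_freq[tr] <- sum(counts[2, ]) / total
    out$mean_load[tr] <- sum(sweep(counts, 2, loads, "*")) / total
    out$census_before[tr] <- total
    # bottleneck: multinomial sample of class counts at the transfer size
    sampled <- stats::rmultinom(1, size = config$bottleneck,
                                prob = as.vector(counts / total))
    counts <- matrix(as.numeric(sampled), nrow = 2)
    out$census_after[tr] <- sum(counts)
  }
  out
}

#' Simulate paired mutator / non-mutator serial-transfer evolution
#'
#' Runs the genotype-class serial-transfer model for two populations with
#' identical parameters except a `mutator_fold` elevation of both the
#' beneficial and deleterious mutation rates in the mutator. Within each
#' transfer, growth of the genotype classes is deterministic exponential
#' (per-generation factor `2 * w`, with `w` combining the beneficial
#' advantage and the multiplicative load cost); stochasticity enters through
#' Poisson mutation counts on newly produced cells and through the
#' multinomial bottleneck that resamples the population down to the transfer
#' size. The populations use distinct sub-seeds derived from `config$seed`,
#' so they are independent but jointly reproducible.
#'
#' @param config A [sim_config()].
#' @return A data frame of class `transfer_trajectory`: one row per
#'   (population, transfer) with `generations` (cumulative), `carrier_freq`
#'   (beneficial-allele carrier frequency at the end of growth, before the
#'   bottleneck), `mean_load`, `census_before` and `census_after` (always the
#'   bottleneck size).
#' @examples
#' traj <- serial_transfer(sim_config(transfers = 4, seed = 42))
#' head(traj)
#' @export
serial_transfer <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  runs <- lapply(c(mutator = 1, nonmutator = 2), function(k) {
    fold <- if (k == 1) config$mutator_fold else 1
    .run_population(config, fold, .sub_seed(config$seed, k))
  })
  out <- rbind(cbind(population = "mutator", runs[[1]]),
               cbind(population = "nonmutator", runs[[2]]))
  class(out) <- c("transfer_trajectory", "data.frame")
  out
}

#' First transfer at which the beneficial allele reaches a majority
#'
#' Scans a trajectory for the first transfer where the carrier frequency
#' exceeds the threshold. When the threshold is never reached within the
#' simulated horizon, the value is right-censored at `max(transfer) + 1` -
#' the population "did not adapt within the experiment", which is how a
#' fixed-length serial-transfer design scores it.
#'
#' @param trajectory A `transfer_trajectory` from [serial_transfer()].
#' @param population `"mutator"` or `"nonmutator"`.
#' @param threshold Carrier-frequency threshold (default 0.5).
#' @return Integer transfer number (possibly the censoring value).
#' @export
transfers_to_majority <- function(trajectory, population, threshold = 0.5) {
  rows <- trajectory[trajectory$population == population, , drop = FALSE]
  if (nrow(rows) == 0) stop("no such population in trajectory: ", population,
                            call. = FALSE)
  hit <- which(rows$carrier_freq > threshold)
  if (length(hit) == 0) max(rows$transfer) + 1L else rows$transfer[min(hit)]
}

#' Simulate Luria-Delbruck fluctuation-assay mutant counts
#'
#' Generative model of a fluctuation assay: each culture grows from `n0`
#' cells by doubling for `gens` generations; during generation `g` the
#' `n0 * 2^(g-1)` newly produced cells each mutate with probability `mu`
#' (Poisson number of events), and each mutation founds a clone that doubles
#' deterministically to final size `2^(gens - g)`. Early ("jackpot") events
#' therefore produce very large mutant counts - the heavy tail that makes
#' the mean useless and motivates median-based estimation. Counts are
#' binomially thinned when only a fraction of each culture is plated.
#'
#' @param mu Mutation rate per cell per generation (small).
#' @param n0 Initial cells per culture (>= 1).
#' @param gens Generations of growth (integer; final population
#'   `n_t = n0 * 2^gens`).
#' @param cultures Number of parallel cultures.
#' @param plating_fraction Fraction of each culture plated, in (0, 1].
#' @param seed Optional integer seed.
#' @return Integer vector of mutant counts, one per culture, with attribute
#'   `"n_t"` (final cells per culture).
#' @examples
#' counts <- sim_fluctuation_counts(5e-7, n0 = 19, gens = 20,
#'                                  cultures = 24, seed = 1)
#' @export
sim_fluctuation_counts <- function(mu, n0, gens, cultures,
                                   plating_fraction = 1, seed = NULL) {
  stopifnot(mu >= 0, mu < 1, n0 >= 1, gens >= 1, cultures >= 1,
            plating_fraction > 0, plating_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  gens <- as.integer(gens)
  new_cells <- n0 * 2^(0:(gens - 1))          # cells made during generation g
  clone_size <- 2^(gens - seq_len(gens))      # final size of a gen-g clone
  events <- matrix(stats::rpois(gens * cultures, rep(mu * new_cells, cultures)),
                   nrow = gens)
  counts <- round(colSums(events * clone_size))
  if (plating_fraction < 1)
    counts <- stats::rbinom(cultures, size = counts, prob = plating_fraction)
  structure(as.integer(counts), n_t = n0 * 2^gens)
}

#' Simulate a marked competition assay with colony sampling
#'
#' Two populations start at a 1:1 ratio; after `t` generations of growth the
#' focal:reference ratio is `true_w^t : 1`. Both time points are observed by
#' plating a fixed number of colonies and scoring each as focal or reference
#' (binomial sampling), mirroring replica-plating of ~200 colonies onto
#' selective plates.
#'
#' @param true_w True per-generation relative fitness of the focal
#'   population.
#' @param t Generations of competition (default 7).
#' @param colonies_per_timepoint Colonies scored at each time point
#'   (default 200).
#' @param seed Optional integer seed.
#' @param medium Medium label for the resulting assay.
#' @return A [competition_assay()].
#' @export
sim_competition_counts <- function(true_w, t = 7, colonies_per_timepoint = 200,
                                   seed = NULL, medium = "YPD+1.2M NaCl") {
  stopifnot(true_w > 0, t > 0, colonies_per_timepoint >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- colonies_per_timepoint
  p0 <- stats::rbinom(1, n, 0.5)
  frac_t <- true_w^t / (1 + true_w^t)
  pt <- stats::rbinom(1, n, frac_t)
  competition_assay(p0, n - p0, pt, n - pt, t = t, medium = medium)
}

#' Simulate pooled read counts for linked or unlinked variants
#'
#' In a bulk-segregant cross, a variant at the causal locus segregates with
#' the phenotype: its alternate allele is at frequency `1 - error_rate` in
#' the resistant spore pool and `error_rate` in the sensitive pool (the
#' error rate absorbs phenotyping mistakes and pool contamination). An
#' unlinked variant sits at frequency 0.5 in both pools. Read counts are
#' binomial at the given per-pool depth.
#'
#' @param linked Logical: simulate causal-locus variants?
#' @param depth_per_pool Reads per pool per variant (>= 1).
#' @param n_variants Number of variants.
#' @param error_rate Allele-frequency error for linked variants, in [0, 0.5).
#' @param seed Optional integer seed.
#' @return A [variant_pool_counts()] data frame.
#' @export
sim_pool_reads <- function(linked, depth_per_pool, n_variants,
                           error_rate = 0, seed = NULL) {
  stopifnot(is.logical(linked), depth_per_pool >= 1, n_variants >= 1,
            error_rate >= 0, error_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  p_r <- if (linked) 1 - error_rate else 0.5
  p_s <- if (linked) error_rate else 0.5
  r_snp <- stats::rbinom(n_variants, depth_per_pool, p_r)
  s_snp <- stats::rbinom(n_variants, depth_per_pool, p_s)
  variant_pool_counts(
    chrom = "chrSim", pos = seq_len(n_variants),
    ref_allele = "A", alt_allele = "T",
    r_wt = depth_per_pool - r_snp, r_snp = r_snp,
    s_wt = depth_per_pool - s_snp, s_snp = s_snp
  )
}

#' Simulate tetrads under single-locus 2:2 segregation with scoring error
#'
#' Each tetrad carries two resistant and two sensitive spores in random
#' order; each spore is independently mis-scored (flipped) with probability
#' `error_rate`.
#'
#' @param n Number of tetrads (0 allowed).
#' @param error_rate Per-spore mis-scoring probability, in [0, 1).
#' @param seed Optional integer seed.
#' @param cross Cross label.
#' @return A list of [tetrad_record()] objects.
#' @export
sim_tetrads <- function(n, error_rate = 0, seed = NULL, cross = "simulated") {
  stopifnot(n >= 0, error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(list())
  lapply(seq_len(n), function(i) {
    spores <- sample(c("resistant", "resistant", "sensitive", "sensitive"))
    flip <- stats::runif(4) < error_rate
    spores[flip] <- ifelse(spores[flip] == "resistant", "sensitive", "resistant")
    tetrad_record(spores, cross = cross)
  })
}
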