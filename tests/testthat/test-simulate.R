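test_that("all generators reproduce exactly under a fixed seed", {
  cfg <- sim_config(transfers = 3, seed = 11)
  expect_identical(serial_transfer(cfg), serial_transfer(cfg))
  cfg2 <- sim_config(transfers = 3, seed = 12)
  expect_false(identical(serial_transfer(cfg), serial_transfer(cfg2)))

  expect_identical(sim_fluctuation_counts(5e-7, 19, 20, 24, seed = 5),
                   sim_fluctuation_counts(5e-7, 19, 20, 24, seed = 5))
  expect_identical(sim_competition_counts(1.1, seed = 5),
                   sim_competition_counts(1.1, seed = 5))
  expect_identical(sim_pool_reads(TRUE, 60, 5, 0.02, seed = 5),
                   sim_pool_reads(TRUE, 60, 5, 0.02, seed = 5))
  expect_identical(lapply(sim_tetrads(5, 0.1, seed = 5), `[[`, "spores"),
                   lapply(sim_tetrads(5, 0.1, seed = 5), `[[`, "spores"))
})

test_that("the bottleneck conserves the census exactly", {
  traj <- serial_transfer(sim_config(bottleneck = 1e5, transfers = 5, seed = 3))
  expect_true(all(traj$census_after == 1e5))
  expect_true(all(traj$census_before > traj$census_after))
  expect_true(all(traj$carrier_freq >= 0 & traj$carrier_freq <= 1))
  expect_equal(unique(traj$population), c("mutator", "nonmutator"))
  # generations accumulate by gens_per_transfer
  m <- traj[traj$population == "mutator", ]
  expect_equal(m$generations, 6.6 * (1:5))
})

test_that("no beneficial target means no carriers ever", {
  traj <- serial_transfer(sim_config(mu_beneficial = 0, transfers = 6,
                                     bottleneck = 1e5, seed = 8))
  expect_true(all(traj$carrier_freq == 0))
  expect_equal(transfers_to_majority(traj, "mutator"), 7L)  # censored
})

test_that("neutral carrier frequency tracks cumulative mutation pressure", {
  # independent recursion oracle: per growth step of dt generations the
  # carrier frequency gains mu * (1 - f) * (1 - 2^-dt)
  mu <- 1e-3
  gpt <- 6.6
  transfers <- 5
  f <- 0
  steps <- c(rep(1, 6), 0.6)
  for (tr in seq_len(transfers)) for (dt in steps)
    f <- f + mu * (1 - f) * (1 - 2^-dt)
  finals <- vapply(1:300, function(sd) {
    traj <- serial_transfer(sim_config(
      bottleneck = 1e5, transfers = transfers, mu_base = 0, mutator_fold = 1,
      mu_beneficial = mu, s_beneficial = 0, seed = sd))
    traj$carrier_freq[traj$population == "nonmutator" &
                        traj$transfer == transfers]
  }, 0)
  expect_lt(abs(mean(finals) - f) / f, 0.05)
})

test_that("the mutator reaches a beneficial majority first", {
  # moderate-advantage scenario (s = 0.1) with a mutation supply and horizon
  # under which sweeps complete
  wins <- vapply(1:60, function(sd) {
    traj <- serial_transfer(sim_config(
      bottleneck = 2e7, transfers = 25, mu_beneficial = 1e-6,
      s_beneficial = 0.1, seed = sd))
    transfers_to_majority(traj, "mutator") <
      transfers_to_majority(traj, "nonmutator")
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("fluctuation counts have Luria-Delbruck structure", {
  expect_true(all(sim_fluctuation_counts(0, 100, 10, 20, seed = 1) == 0))

  # internal expectation oracle: E[count] = mu * n0 * gens * 2^(gens-1)
  counts <- sim_fluctuation_counts(1e-5, n0 = 1000, gens = 10,
                                   cultures = 5000, seed = 21)
  expectation <- 1e-5 * 1000 * 10 * 2^9
  expect_lt(abs(mean(counts) - expectation) / expectation, 0.05)
  expect_equal(attr(counts, "n_t"), 1000 * 2^10)

  # jackpot property: heavy tail makes the variance dwarf the mean
  jp <- sim_fluctuation_counts(5e-7, n0 = 19, gens = 20, cultures = 1000,
                               seed = 22)
  expect_gt(var(jp), 10 * mean(jp))

  # plating fraction thins binomially
  full <- sim_fluctuation_counts(1e-5, 1000, 10, 2000, seed = 23)
  half <- sim_fluctuation_counts(1e-5, 1000, 10, 2000,
                                 plating_fraction = 0.5, seed = 23)
  expect_lt(mean(half), mean(full))
})

test_that("competition sampling is centred on the deterministic ratio", {
  set.seed(31)
  # huge colony numbers approach the deterministic limit w
  a <- sim_competition_counts(1, t = 7, colonies_per_timepoint = 2e5)
  expect_lt(abs(relative_fitness(a) - 1), 0.01)
  # true_w = 0.5: end-point focal fraction is 0.5^7 / (1 + 0.5^7)
  frac <- replicate(400, {
    x <- sim_competition_counts(0.5, t = 7, colonies_per_timepoint = 200)
    x$pt / (x$pt + x$qt)
  })
  expect_lt(abs(mean(frac) - 0.5^7 / (1 + 0.5^7)), 0.005)
})

test_that("pool read generation matches linked and unlinked expectations", {
  perfect <- sim_pool_reads(TRUE, 60, 5, error_rate = 0, seed = 41)
  expect_true(all(perfect$r_wt == 0 & perfect$r_snp == 60 &
                    perfect$s_wt == 60 & perfect$s_snp == 0))
  unl <- sim_pool_reads(FALSE, 1000, 50, seed = 42)
  expect_lt(abs(mean(unl$r_snp) / 1000 - 0.5), 0.02)
})

test_that("simulated tetrads segregate 2:2 without scoring error", {
  expect_length(sim_tetrads(0), 0L)
  clean <- sim_tetrads(50, error_rate = 0, seed = 51)
  expect_true(all(vapply(clean, classify_tetrad, "") == "2:2"))
})
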