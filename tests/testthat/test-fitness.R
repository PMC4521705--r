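test_that("generation accounting is log2 of the census ratio", {
  expect_equal(generations(1e7, 1e7), 0)
  expect_equal(generations(1e7, 2e7), 1)
  expect_equal(generations(2e7, 2e9), log2(100))
  expect_lt(generations(2e7, 1e7), 0)
  expect_error(generations(0, 1e7), "positive")
})

test_that("relative fitness matches the ratio-of-ratios definition", {
  expect_equal(relative_fitness(competition_assay(100, 100, 100, 100, t = 7)), 1)
  expect_equal(relative_fitness(competition_assay(100, 100, 200, 100, t = 1)), 2)
  # cross-check by simulating 7 generations of deterministic growth at a
  # per-generation ratio advantage of 1.46^(1/7)
  w_step <- 1.46^(1 / 7)
  ratio <- 1
  for (g in 1:7) ratio <- ratio * w_step
  expect_equal(relative_fitness(competition_assay(100, 100, 146, 100, t = 7)),
               w_step, tolerance = 1e-12)
  expect_equal(ratio, 1.46, tolerance = 1e-12)
})

test_that("relative fitness obeys reciprocity and scale invariance", {
  set.seed(7)
  for (i in 1:20) {
    cnt <- sample(1:500, 4, replace = TRUE)
    t <- runif(1, 1, 10)
    a <- competition_assay(cnt[1], cnt[2], cnt[3], cnt[4], t = t)
    swapped <- competition_assay(cnt[2], cnt[1], cnt[4], cnt[3], t = t)
    expect_equal(relative_fitness(swapped), 1 / relative_fitness(a),
                 tolerance = 1e-12)
    scaled <- competition_assay(3 * cnt[1], 3 * cnt[2], 3 * cnt[3], 3 * cnt[4], t = t)
    expect_equal(relative_fitness(scaled), relative_fitness(a), tolerance = 1e-12)
  }
})

test_that("zero counts error unless an explicit pseudocount is given", {
  a <- competition_assay(0, 200, 100, 100, t = 7)
  expect_error(relative_fitness(a), "pseudocount")
  expect_gt(relative_fitness(a, pseudocount = 0.5), 0)
})

test_that("fitness summaries report mean, SEM and replicate count", {
  mk <- function(pt) competition_assay(100, 100, pt, 100, t = 1, medium = "YPD")
  s <- summarize_fitness(list(mk(100), mk(100), mk(100)))
  expect_equal(s$mean_w, 1)
  expect_equal(s$sem_w, 0)
  expect_equal(s$n, 3L)
  s2 <- summarize_fitness(list(mk(90), mk(100), mk(110)))
  expect_equal(s2$mean_w, 1, tolerance = 1e-12)
  expect_equal(s2$sem_w, sd(c(0.9, 1, 1.1)) / sqrt(3), tolerance = 1e-12)
  expect_equal(summarize_fitness(list(mk(100)))$sem_w, 0)
  expect_error(summarize_fitness(list()), "at least one")
  expect_error(summarize_fitness(list(mk(100),
    competition_assay(1, 1, 1, 1, medium = "other"))), "media")
})

test_that("one-way ANOVA matches hand sums of squares and stats::aov", {
  res <- one_way_anova(c(1, 2, 3), c(2, 3, 4))
  # SS_between = 1.5, SS_within = 4, df = (1, 4) -> F = 1.5/(4/4) = 1.5
  expect_equal(res$F, 1.5)
  expect_equal(res$p, pf(1.5, 1, 4, lower.tail = FALSE))
  expect_false(res$degenerate)

  deg <- one_way_anova(c(1, 1, 1), c(1, 1, 1))
  expect_equal(deg$F, 0)
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)

  set.seed(11)
  a <- rnorm(9, 1.0, 0.05)
  b <- rnorm(7, 1.1, 0.05)
  res <- one_way_anova(a, b)
  ref <- summary(aov(y ~ g, data.frame(y = c(a, b),
                                       g = rep(c("a", "b"), c(9, 7)))))[[1]]
  expect_equal(res$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("ANOVA p agrees with a permutation oracle on normal data", {
  set.seed(23)
  a <- rnorm(8, 1.00, 0.04)
  b <- rnorm(8, 1.04, 0.04)
  res <- one_way_anova(a, b)
  x <- c(a, b)
  # F for two equal groups is monotone in (sum of group a - half the total)^2
  stat <- function(idx) (sum(x[idx]) - sum(x) / 2)^2
  obs <- stat(1:8)
  perm <- replicate(1e5, stat(sample.int(16, 8)))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(res$p - p_perm), 0.02)
})

test_that("signed-rank test enumerates exactly for small n", {
  # n = 6 strictly positive differences: W = 21, p = 2 / 2^6
  res <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$W, 21)
  expect_equal(res$p, 2 / 2^6)
  expect_equal(res$method, "exact")
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "nonzero")

  # agreement with the base-R exact implementation on tie-free data
  set.seed(3)
  for (i in 1:10) {
    a <- round(rnorm(10), 3)
    b <- round(rnorm(10), 3)
    res <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(res$W, unname(ref$statistic))
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation branches agree near the cutover", {
  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(15)
    b <- rnorm(15, 0.4)
    exact <- wilcoxon_signed_rank(a, b)    # n = 15: exact branch
    expect_equal(exact$method, "exact")
    approx <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
    expect_lt(abs(exact$p - approx$p.value), 0.02)
    # n = 16 uses the package's own normal approximation; also near exact
    a2 <- c(a, 0.5); b2 <- c(b, -0.5)
    expect_equal(wilcoxon_signed_rank(a2, b2)$method, "normal")
    expect_lt(abs(wilcoxon_signed_rank(a2, b2)$p -
                  wilcox.test(a2, b2, paired = TRUE, exact = FALSE,
                              correct = TRUE)$p.value), 1e-10)
  }
})

test_that("competition estimator recovers true fitness from colony sampling", {
  set.seed(101)
  for (true_w in c(0.9, 1.16)) {
    w_hat <- replicate(300, relative_fitness(
      sim_competition_counts(true_w, t = 7, colonies_per_timepoint = 200)))
    expect_lt(abs(mean(w_hat) - true_w), 0.015)
  }
})
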