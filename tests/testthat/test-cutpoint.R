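test_that("minprop admissibility and the no-cutpoint error", {
  cfg <- cutpoint_config(n_boot = 5)
  # constant scores: every split is one-sided
  expect_error(
    maxstat_cutpoint(rep(4, 10), 1:10, rep(1, 10), cfg, bootstrap = FALSE),
    "no admissible cutpoint")
  # any reported cutoff satisfies minprop on both sides
  set.seed(61)
  sc <- sample(0:12, 40, replace = TRUE)
  t <- rexp(40, 0.1); e <- rbinom(40, 1, 0.8)
  fit <- maxstat_cutpoint(sc, t, e, cfg, bootstrap = FALSE)
  tab <- fit$table[fit$table$cutoff == fit$best_cutoff, ]
  expect_gte(min(tab$n_low, tab$n_high), ceiling(0.25 * 40))
})

test_that("equivalent splits tie and break to the lowest candidate", {
  # scores {3,6} only: all three candidates induce the same partition
  sc <- rep(c(3, 6), each = 6)
  t <- c(1, 2, 3, 4, 5, 6, 30, 35, 40, 45, 50, 55)
  e <- rep(1, 12)
  fit <- maxstat_cutpoint(sc, t, e, cutpoint_config(n_boot = 5),
                          bootstrap = FALSE)
  st <- fit$table$statistic
  expect_equal(st[1], st[2], tolerance = 1e-10)
  expect_equal(st[2], st[3], tolerance = 1e-10)
  expect_equal(fit$best_cutoff, 3.5)
  # and each equals the first-principles oracle
  expect_equal(st[1], oracle_logrank(t, e, sc > 3.5), tolerance = 1e-10)
})

test_that("bootstrap stability is seeded, complete, and degenerate-safe", {
  set.seed(62)
  sc <- rep(c(3, 4, 6, 7), each = 8)
  t <- rexp(32, ifelse(sc >= 5, 0.02, 0.25)); e <- as.integer(t < 60)
  t <- pmin(t, 60)
  cfg <- cutpoint_config(n_boot = 40)
  f1 <- bootstrap_stability(sc, t, e, cfg, seed = 7)
  f2 <- bootstrap_stability(sc, t, e, cfg, seed = 7)
  expect_identical(f1, f2)
  expect_equal(sum(f1), 1)
  expect_true(all(f1 >= 0))
  # B = 1 is a single deterministic selection
  fb1 <- bootstrap_stability(sc, t, e, cutpoint_config(n_boot = 1),
                             seed = 3)
  expect_equal(sum(fb1), 1)
  expect_equal(sum(fb1 == 1), 1)
})

test_that("overwhelming separation pins the bootstrap on the true
           candidate; the null spreads it", {
  # two score groups with extreme survival separation
  sc <- rep(c(3, 6), each = 20)
  t <- c(seq(0.5, 10, length.out = 20), seq(50, 59, length.out = 20))
  e <- rep(1, 40)
  f <- bootstrap_stability(sc, t, e, cutpoint_config(n_boot = 200),
                           seed = 11)
  # all three candidates split identically here; ties go low
  expect_gte(f[["3.5"]], 0.95)
  # under independence no candidate should dominate
  set.seed(63)
  sc2 <- sample(0:12, 60, replace = TRUE)
  t2 <- rexp(60, 0.1); e2 <- rbinom(60, 1, 0.8)
  f2 <- bootstrap_stability(sc2, t2, e2, cutpoint_config(n_boot = 200),
                            seed = 12)
  expect_true(all(f2[c("3.5", "4.5", "5.5")] < 0.9))
})

test_that("whole-fit reproducibility under a fixed seed", {
  set.seed(64)
  sc <- sample(2:8, 30, replace = TRUE)
  t <- rexp(30, 0.08); e <- rbinom(30, 1, 0.7)
  cfg <- cutpoint_config(n_boot = 25)
  a <- maxstat_cutpoint(sc, t, e, cfg, seed = 99)
  b <- maxstat_cutpoint(sc, t, e, cfg, seed = 99)
  expect_identical(a$selection_frequency, b$selection_frequency)
  expect_identical(a$best_cutoff, b$best_cutoff)
})

test_that("stronger effects never make the true candidate less
           recoverable", {
  # selection frequency of the ground-truth midpoint is non-decreasing
  # in the effect size (grid of hazard ratios, common seeds)
  hrs <- c(1, 0.5, 0.2, 0.05)
  freq <- sapply(hrs, function(hr) {
    hit <- 0
    for (s in 1:20) {
      set.seed(1000 + s)
      sc <- rep(c(3, 4, 6, 7), each = 10)
      t0 <- rexp(40, ifelse(sc >= 5, 0.15 * hr, 0.15))
      e <- as.integer(t0 < 60); t <- pmin(t0, 60)
      fit <- tryCatch(
        maxstat_cutpoint(sc, t, e, cutpoint_config(n_boot = 1),
                         bootstrap = FALSE),
        error = function(err) NULL)
      if (!is.null(fit) && fit$best_cutoff == 4.5) hit <- hit + 1
    }
    hit / 20
  })
  expect_true(all(diff(freq) >= -0.1))  # monotone up to MC noise
  expect_gt(freq[4], freq[1])
})

test_that("config validation rejects malformed settings", {
  expect_error(cutpoint_config(candidates = c(4.5, 3.5)), "increasing")
  expect_error(cutpoint_config(minprop = 0.7), "minprop")
  expect_error(cutpoint_config(n_boot = 0), "n_boot")
})
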