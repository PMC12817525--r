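test_that("log-rank statistic matches the risk-set oracle on small data", {
  set.seed(51)
  # the 6-subject toy with complete separation
  t6 <- c(1, 2, 3, 4, 5, 6); e6 <- rep(1, 6)
  g6 <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(t6, e6, g6)
  expect_equal(lr$statistic, oracle_logrank(t6, e6, g6),
               tolerance = 1e-10)
  # random small datasets, including ties
  for (i in 1:30) {
    n <- sample(4:25, 1)
    d <- random_surv(n)
    d$time <- round(d$time)  # force ties
    if (sum(d$event) == 0) next
    lr <- logrank_test(d$time, d$event, d$group)
    expect_equal(lr$statistic, oracle_logrank(d$time, d$event, d$group),
                 tolerance = 1e-8)
  }
})

test_that("log-rank is symmetric and vanishes for identical groups", {
  d <- list(time = c(3, 5, 7, 9, 11), event = c(1, 0, 1, 1, 0))
  dup <- list(time = rep(d$time, 2), event = rep(d$event, 2),
              group = rep(c("A", "B"), each = 5))
  lr <- logrank_test(dup$time, dup$event, dup$group)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  set.seed(52)
  r <- random_surv(12)
  a <- logrank_test(r$time, r$event, r$group)
  b <- logrank_test(r$time, r$event, 1 - r$group)
  expect_equal(a$statistic, b$statistic)
  expect_error(logrank_test(r$time, r$event, rep("A", 12)),
               "two levels")
})

test_that("Kaplan-Meier matches hand computation and its limits", {
  # worked 5-subject set: 3, 5+, 7, 9, 11+ (+ = censored)
  km <- km_estimate(c(3, 5, 7, 9, 11), c(1, 0, 1, 1, 0))
  ev <- km$steps[km$steps$n.event > 0, ]
  expect_equal(ev$surv, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2),
               tolerance = 1e-12)
  # no censoring: curve equals 1 - empirical CDF
  t <- c(2, 4, 4, 7, 9)
  km2 <- km_estimate(t, rep(1, 5))
  ecdf_surv <- 1 - ecdf(t)(km2$steps$time)
  expect_equal(km2$steps$surv[km2$steps$n.event > 0],
               ecdf_surv[km2$steps$n.event > 0], tolerance = 1e-12)
  # all censored: flat at 1
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$steps$surv == 1))
  # probabilities non-increasing from 1
  set.seed(53)
  r <- random_surv(40)
  km4 <- km_estimate(r$time, r$event)
  expect_true(all(diff(c(1, km4$steps$surv)) <= 1e-12))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty|non-negative")
})

test_that("merging two identical groups leaves the KM curve unchanged", {
  set.seed(54)
  r <- random_surv(15)
  one <- km_estimate(r$time, r$event)
  two <- km_estimate(rep(r$time, 2), rep(r$event, 2))
  expect_equal(one$steps$surv[one$steps$n.event > 0],
               two$steps$surv[two$steps$n.event > 0], tolerance = 1e-12)
})

test_that("Cox binary fit: identities and parameter recovery", {
  set.seed(55)
  # label swap inverts the hazard ratio
  r <- random_surv(40)
  a <- cox_binary(r$time, r$event, r$group)
  b <- cox_binary(r$time, r$event, 1 - r$group)
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-6)
  # identical survival distributions: HR near 1 (same data in both arms)
  dup_t <- rep(r$time, 2); dup_e <- rep(r$event, 2)
  dup_g <- rep(c(0, 1), each = 40)
  expect_equal(cox_binary(dup_t, dup_e, dup_g)$hr, 1, tolerance = 1e-8)
  # score test at beta = 0 equals the log-rank statistic
  for (i in 1:10) {
    d <- random_surv(sample(10:20, 1))
    if (min(tapply(d$event, d$group, sum)) == 0) next
    # the score statistic at beta = 0 is well defined even when the
    # likelihood is monotone, so convergence warnings are irrelevant here
    sc <- suppressWarnings(
      survival::coxph(survival::Surv(d$time, d$event) ~ d$group,
                      ties = "breslow"))
    expect_equal(unname(sc$score),
                 logrank_test(d$time, d$event, d$group)$statistic,
                 tolerance = 1e-6)
  }
})

test_that("Cox flags monotone likelihood when a group has no events", {
  t <- c(1, 2, 3, 10, 12, 14); e <- c(1, 1, 1, 0, 0, 0)
  g <- rep(c("A", "B"), each = 3)
  fit <- cox_binary(t, e, g)
  expect_false(fit$estimable)
  expect_lte(abs(fit$coef), 10)
  expect_true(fit$small_events)
})

test_that("mean survival: arithmetic and RMST coincide without censoring", {
  ms <- mean_survival(c(10), c(1), c("A"), horizon = 60)
  expect_equal(ms$means$mean, c(10, 10))
  set.seed(56)
  t <- rexp(30, 0.1); e <- rep(1, 30)
  g <- rep(c("A", "B"), 15)
  ms2 <- mean_survival(t, e, g, horizon = max(t) + 1)
  for (lv in c("A", "B")) {
    v <- ms2$means[ms2$means$group == lv, ]
    expect_equal(v$mean[v$method == "arithmetic"],
                 v$mean[v$method == "RMST"], tolerance = 1e-8)
  }
  expect_equal(ms2$delta[["arithmetic"]], ms2$delta[["RMST"]],
               tolerance = 1e-8)
})

test_that("log-rank test is calibrated under the null at a fixed
           cutpoint", {
  # scores independent of survival; dichotomize at the usual 5+ cutoff
  # and count rejections at the 0.05 level over 2000 simulations
  rej <- 0; done <- 0
  for (s in 1:2000) {
    set.seed(90000 + s)
    n <- 200
    sc <- sample(0:12, n, replace = TRUE)
    t0 <- rexp(n, log(2) / 7)
    e <- as.integer(t0 < 60); tt <- pmin(t0, 60)
    g <- sc >= 5
    if (min(sum(g), sum(!g)) < 2) next
    done <- done + 1
    if (logrank_test(tt, e, g)$p.value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / done, 0.03)
  expect_lte(rej / done, 0.07)
})
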