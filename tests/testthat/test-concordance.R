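test_that("confusion tables count with the adverse positive class", {
  pred <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  truth <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  tab <- confusion_from_labels(pred, truth)
  expect_equal(unlist(tab[c("tp", "fp", "fn", "tn")]),
               c(tp = 2L, fp = 1L, fn = 1L, tn = 2L))
  # factor input with an explicit positive level
  tab2 <- confusion_from_labels(
    factor(ifelse(pred, "PD", "SD")), factor(ifelse(truth, "PD", "SD")),
    positive = "PD")
  expect_equal(unlist(tab2[1:4]), unlist(tab[1:4]))
  expect_error(confusion_from_labels(pred, truth[-1]), "equal length")
  expect_error(confusion_from_labels(c(pred, NA), c(truth, TRUE)),
               "missing")
  # all-agree input has empty discordant cells
  agree <- confusion_from_labels(truth, truth)
  expect_equal(agree$fp + agree$fn, 0L)
})

test_that("report metrics satisfy their defining identities", {
  set.seed(41)
  for (i in 1:10) {
    cells <- rmultinom(1, 30, c(0.3, 0.15, 0.15, 0.4))[, 1]
    if (cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
    tab <- confusion_counts(cells[1], cells[2], cells[3], cells[4])
    rep <- concordance_report(tab)
    m <- rep$metrics
    n <- sum(cells)
    expect_equal(m["accuracy", "estimate"], (tab$tp + tab$tn) / n)
    expect_equal(rep$balanced_accuracy,
                 (m["sensitivity", "estimate"] +
                    m["specificity", "estimate"]) / 2)
    # each CI brackets its estimate
    ok <- !is.na(m$estimate)
    expect_true(all(m$lower[ok] <= m$estimate[ok] + 1e-12))
    expect_true(all(m$upper[ok] >= m$estimate[ok] - 1e-12))
    expect_equal(rep$mcnemar_p, exact_mcnemar(tab$fn, tab$fp))
  }
})

test_that("paired correctness cross-tabulates and tests the off-diagonal", {
  c1 <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  c2 <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  pc <- paired_correctness_mcnemar(c1, c2)
  expect_equal(pc$both_correct, 1)
  expect_equal(pc$only_method1_correct, 3)
  expect_equal(pc$only_method2_correct, 1)
  expect_equal(pc$both_wrong, 1)
  expect_equal(pc$exact_mcnemar_p, exact_mcnemar(3, 1))
  # identical vectors give p = 1
  expect_equal(paired_correctness_mcnemar(c1, c1)$exact_mcnemar_p, 1)
})

test_that("rank correlations: limits, antisymmetry, and tie handling", {
  x <- 1:6; y <- c(2, 3, 5, 7, 11, 13)
  rc <- rank_correlations(x, y)
  expect_equal(rc$spearman_rho, 1)
  expect_equal(rc$kendall_tau_b, 1)
  rev_rc <- rank_correlations(rev(x), y)
  expect_equal(rev_rc$spearman_rho, -1)
  expect_equal(rev_rc$kendall_tau_b, -1)
  expect_error(rank_correlations(rep(1, 5), 1:5), "constant")
  # tau-b with ties matches the explicit tie-corrected formula
  xt <- c(1, 1, 2, 3, 3, 4); yt <- c(2, 1, 1, 3, 4, 4)
  conc <- 0; disc <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    s <- sign(xt[i] - xt[j]) * sign(yt[i] - yt[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- choose(6, 2)
  n1 <- sum(choose(table(xt), 2)); n2 <- sum(choose(table(yt), 2))
  tau_b <- (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
  expect_equal(rank_correlations(xt, yt)$kendall_tau_b, tau_b)
})

test_that("permutation p-values match exhaustive R enumeration with ties", {
  set.seed(43)
  cases <- list(
    list(x = c(1, 1, 2, 3, 3, 4), y = c(2, 1, 1, 3, 4, 4)),
    list(x = c(-2, 0, 0, 1, 3, -1), y = c(-1, 0, 1, 1, 2, 0)),
    list(x = rnorm(6), y = rnorm(6)))
  for (cs in cases) {
    got <- rank_correlations(cs$x, cs$y)
    want <- oracle_perm_pvalues(cs$x, cs$y)
    expect_equal(got$spearman_p, unname(want["spearman_p"]),
                 tolerance = 1e-10)
    expect_equal(got$kendall_p, unname(want["kendall_p"]),
                 tolerance = 1e-10)
  }
})

test_that("directional concordance reports agreement and 3x3 kappa", {
  d1 <- c("IMPROVED", "STABLE", "WORSENED", "WORSENED", "STABLE",
          "IMPROVED", "WORSENED", "STABLE")
  d2 <- c("IMPROVED", "STABLE", "WORSENED", "WORSENED", "WORSENED",
          "IMPROVED", "WORSENED", "IMPROVED")
  dc <- directional_concordance(d1, d2)
  expect_equal(dc$agreement, 6 / 8)
  expect_equal(dc$kappa, cohens_kappa(dc$table))
  all_agree <- directional_concordance(d1, d1)
  expect_equal(all_agree$agreement, 1)
  expect_equal(all_agree$kappa, 1)
  expect_error(directional_concordance(d1, c(d2[-1], "UP")), "invalid")
})
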