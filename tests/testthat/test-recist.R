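test_that("RECIST rules classify the canonical lesion courses", {
  expect_equal(as.character(classify_recist(100, 68, 68)), "PR")
  expect_equal(as.character(classify_recist(100, 50, 61)), "PD")
  # 20% growth but absolute rise below 5 mm blocks PD
  expect_equal(as.character(classify_recist(30, 20, 24)), "SD")
  # size-stable lesion is stable disease
  expect_equal(as.character(classify_recist(76, 76, 76)), "SD")
  # new lesions force PD regardless of size
  expect_equal(as.character(classify_recist(100, 60, 60,
                                            new_lesions = TRUE)), "PD")
  # vanished targets with small nodes is CR; with large nodes it is not
  expect_equal(as.character(
    classify_recist(100, 0, 0, target_lesions_vanished = TRUE)), "CR")
  expect_equal(as.character(
    classify_recist(100, 0, 0, target_lesions_vanished = TRUE,
                    node_short_axis = 12)), "PR")
  # PD precedence over PR: deep response then regrowth from nadir
  expect_equal(as.character(classify_recist(100, 20, 30)), "PD")
})

test_that("RECIST validation rejects impossible measurements", {
  expect_error(classify_recist(0, 0, 0), "undefined")
  expect_error(classify_recist(50, 60, 60), "nadir")
  expect_error(classify_recist(-1, 0, 0), ">= 0")
})

test_that("categories are mutually exclusive and scale-invariant up to
           the absolute PD clause", {
  set.seed(31)
  for (i in 1:40) {
    b <- runif(1, 30, 150)
    nd <- b * runif(1, 0.1, 1)
    cur <- nd * runif(1, 0.8, 1.8)
    cat1 <- classify_recist(b, nd, cur)
    expect_length(cat1, 1)
    expect_false(is.na(cat1))
    # common rescaling keeps the binarized call unless the 5 mm absolute
    # clause is in play on either scale
    f <- runif(1, 2, 4)
    rel_growth <- cur >= 1.2 * nd
    abs_edge <- rel_growth && (cur - nd < 5 || f * (cur - nd) < 5)
    if (!abs_edge) {
      expect_equal(as.character(binarize_recist(cat1)),
                   as.character(binarize_recist(
                     classify_recist(f * b, f * nd, f * cur))))
    }
  }
  # the absolute clause itself breaks scale invariance
  expect_equal(as.character(classify_recist(30, 20, 24)), "SD")
  expect_equal(as.character(classify_recist(60, 40, 48)), "PD")
})

test_that("binarization keeps only PD as nonresponse", {
  expect_equal(as.character(binarize_recist(c("CR", "PR", "SD", "PD"))),
               c("RESPONDER", "RESPONDER", "RESPONDER", "NONRESPONDER"))
  expect_error(binarize_recist("NE"), "invalid")
})

test_that("five-year DFS labels respect the 60-month benchmark", {
  expect_equal(as.character(label_5yr_dfs(3, TRUE)),
               "RECURRENCE_WITHIN_5Y")
  expect_equal(as.character(label_5yr_dfs(60, FALSE)), "DISEASE_FREE_5Y")
  expect_equal(as.character(label_5yr_dfs(24, FALSE)), "INDETERMINATE")
  # the benchmark is inclusive; an event at exactly 60 months is not a
  # recurrence within 5 years
  expect_equal(as.character(label_5yr_dfs(60, TRUE)), "DISEASE_FREE_5Y")
  expect_error(label_5yr_dfs(-1, TRUE), "non-negative")
  # never disease-free with an event before 60 months
  set.seed(32)
  t <- runif(50, 0, 120); e <- rbinom(50, 1, 0.5)
  lab <- label_5yr_dfs(t, e)
  expect_false(any(lab == "DISEASE_FREE_5Y" & e == 1 & t < 60))
})

test_that("ordinal coding and direction labels agree with sign logic", {
  expect_equal(recist_ordinal(c("CR", "PR", "SD", "PD")), 3:0)
  expect_equal(as.character(direction_class(c(-2, 0, 3))),
               c("WORSENED", "STABLE", "IMPROVED"))
  # concordant worsening: CIWS drop with SD -> PD
  d_ciws <- -2
  d_recist <- recist_ordinal("PD") - recist_ordinal("SD")
  expect_equal(as.character(direction_class(d_ciws)),
               as.character(direction_class(d_recist)))
  expect_error(direction_class(c(1, NA)), "missing pair")
})
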