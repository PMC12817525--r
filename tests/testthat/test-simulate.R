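test_that("default cohort has the study shape and is seed-deterministic", {
  co <- simulate_cohort(seed = 1)
  expect_equal(nrow(co), 31)
  expect_equal(sum(co$timepoint == "pre"), 18)
  expect_equal(sum(co$timepoint == "post"), 13)
  paired <- intersect(co$patient_id[co$timepoint == "pre"],
                      co$patient_id[co$timepoint == "post"])
  expect_length(paired, 8)
  expect_equal(length(unique(co$patient_id)), 23)
  expect_identical(simulate_cohort(seed = 1), co)
  expect_false(identical(simulate_cohort(seed = 2), co))
})

test_that("generated readouts respect their ranges and invariants", {
  co <- simulate_cohort(seed = 4)
  for (cl in paste0("cir_", tolower(PDO_DRUGS))) {
    expect_true(all(co[[cl]] >= 0 & co[[cl]] <= 100))
    expect_true(all(co[[cl]] >= co$cir_control))  # treated >= control
  }
  expect_true(all(co$edu_fraction >= 0 & co$edu_fraction <= 1))
  expect_true(all(co$nadir_sld_mm <= co$baseline_sld_mm + 1e-9))
  expect_true(all(co$dfs_months >= 0 & co$os_months >= co$dfs_months))
  expect_true(all(co$dfs_months <= 60 & co$os_months <= 60))
})

test_that("intended labels are recovered exactly by the classifiers", {
  # trajectory model self-consistency: drawn lesions classify to the
  # intended category, drawn culture features to the intended grade
  for (s in 1:5) {
    co <- simulate_cohort(seed = 100 + s)
    got_recist <- classify_recist(co$baseline_sld_mm, co$nadir_sld_mm,
                                  co$current_sld_mm, co$new_lesions == 1,
                                  co$vanished == 1)
    expect_equal(as.character(got_recist), co$intended_recist_nat)
    got_ofp <- grade_ofp(co$days_to_formation, co$cluster_diameter_um,
                         co$edu_fraction, co$growth_sustained == 1)
    expect_equal(as.character(got_ofp), co$intended_ofp)
  }
})

test_that("full sensitivity prevalence yields a sensitive-dominated
           cohort", {
  cfg <- cohort_config(n_patients = 31, n_pre = 31, n_post = 0,
                       n_paired = 0, prevalence = 1)
  calls <- unlist(lapply(1:50, function(s) {
    co <- simulate_cohort(cfg, seed = 200 + s)
    score_samples(cohort_assays(co))$call
  }))
  expect_gte(mean(calls == "S"), 0.9)
})

test_that("truth report echoes the configuration and detects tampering", {
  co <- simulate_cohort(seed = 6)
  tr <- truth_report(co)
  expect_equal(tr$true_cutoff, 4.5)
  expect_equal(tr$true_hr_dfs, 0.2)
  expect_equal(tr$n_samples, 31)
  expect_equal(tr$n_patients, 23)
  # analysis mode refuses
  an <- simulate_cohort(seed = 6, truth = FALSE)
  expect_false(any(c("latent_sensitive", "true_cutoff") %in% names(an)))
  expect_error(truth_report(an), "truth-mode")
  # tampering with an analysis column breaks the checksum
  tampered <- co
  tampered$dfs_months[1] <- tampered$dfs_months[1] + 1
  expect_error(truth_report(tampered), "checksum")
})

test_that("configured hazard ratio is echoed and the null config severs
           the link", {
  cfg <- cohort_config(hr_dfs = 0.4)
  expect_equal(truth_report(simulate_cohort(cfg, seed = 7))$true_hr_dfs,
               0.4)
  null_cfg <- cohort_config(null_survival = TRUE)
  expect_equal(truth_report(simulate_cohort(null_cfg,
                                            seed = 7))$true_hr_dfs, 1)
})

test_that("cohort shape validation rejects inconsistent configs", {
  expect_error(cohort_config(n_patients = 10, n_pre = 8, n_post = 5,
                             n_paired = 6), "n_paired")
  expect_error(cohort_config(n_patients = 20, n_pre = 18, n_post = 13,
                             n_paired = 8), "inconsistent")
})
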