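# End-to-end reproduction driver -----------------------------------------

#' Run the full PDO concordance and survival analysis
#'
#' Orchestrates every stage on one cohort table and emits the complete
#' statistics battery in the standard reporting order: (1) pre-NAT CIWS
#' predictions against the post-NAT radiological response, (2) post-NAT
#' CIWS predictions against the five-year outcome, (3) the NAT RECIST
#' response itself as a predictor of the five-year outcome, (4) the
#' paired-correctness comparison of (2) versus (3), (5) directional and
#' rank concordance of paired pre/post changes, and (6) cutpoint
#' selection plus Kaplan--Meier / log-rank / Cox summaries for CIWS- and
#' OFP-stratified survival. Patients censored before the five-year
#' benchmark are excluded from accuracy denominators and reported as
#' exclusions.
#'
#' @param cohort Cohort table from [simulate_cohort()] or
#'   [read_cohort()]; must contain the assay, lesion and survival
#'   columns.
#' @param cutpoint_boot Bootstrap resamples for the cutpoint stability
#'   assessment (default 1000).
#' @param seed Seed for the bootstrap stage (the only stochastic stage).
#' @return Object of class `pdo_analysis`; see the print method.
#' @export
run_reproduction <- function(cohort, cutpoint_boot = 1000, seed = NULL) {
  if (is.null(cohort) || nrow(cohort) == 0) {
    stop("empty cohort: nothing to analyse", call. = FALSE)
  }
  req <- c("patient_id", "timepoint", "cir_control",
           paste0("cir_", tolower(MAPI_REGIMEN)),
           "baseline_sld_mm", "nadir_sld_mm", "current_sld_mm",
           "new_lesions", "vanished",
           "dfs_months", "dfs_event", "os_months", "os_event")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  scored <- score_samples(cohort_assays(cohort))
  cohort$.key <- paste(cohort$patient_id, cohort$timepoint)
  scored$.key <- paste(scored$patient_id, scored$timepoint)
  cohort$ciws <- scored$ciws[match(cohort$.key, scored$.key)]
  cohort$ciws_sensitive <- cohort$ciws >= 5

  has_ofp <- all(c("days_to_formation", "cluster_diameter_um",
                   "edu_fraction", "growth_sustained") %in% names(cohort))
  if (has_ofp) {
    cohort$ofp_grade <- grade_ofp(cohort$days_to_formation,
                                  cohort$cluster_diameter_um,
                                  cohort$edu_fraction,
                                  cohort$growth_sustained == 1)
    cohort$growth_group <- group_ofp(cohort$ofp_grade)
  }

  # per-patient clinical labels
  pat <- cohort[!duplicated(cohort$patient_id),
                c("patient_id", "baseline_sld_mm", "nadir_sld_mm",
                  "current_sld_mm", "new_lesions", "vanished",
                  "dfs_months", "dfs_event", "os_months", "os_event")]
  pat$recist_nat <- classify_recist(pat$baseline_sld_mm, pat$nadir_sld_mm,
                                    pat$current_sld_mm,
                                    pat$new_lesions == 1,
                                    pat$vanished == 1)
  pat$nat_nonresponder <-
    binarize_recist(pat$recist_nat) == "NONRESPONDER"
  pat$dfs5y <- label_5yr_dfs(pat$dfs_months, pat$dfs_event)

  # latest sample per patient carries the prognostic CIWS class
  is_post <- cohort$timepoint == "post"
  latest <- cohort[order(cohort$patient_id, !is_post), ]
  latest <- latest[!duplicated(latest$patient_id), ]
  pat$ciws_latest <- latest$ciws[match(pat$patient_id, latest$patient_id)]
  pat$ciws_latest_sensitive <- pat$ciws_latest >= 5

  pre <- cohort[cohort$timepoint == "pre", ]
  pre_pat <- pat[match(pre$patient_id, pat$patient_id), ]
  cmp_pre <- concordance_report(confusion_from_labels(
    predicted = !pre$ciws_sensitive,          # resistant predicts PD
    truth = pre_pat$nat_nonresponder))

  post <- cohort[cohort$timepoint == "post", ]
  post_pat <- pat[match(post$patient_id, pat$patient_id), ]
  determinate <- post_pat$dfs5y != "INDETERMINATE"
  n_excluded <- sum(!determinate)
  adverse <- post_pat$dfs5y == "RECURRENCE_WITHIN_5Y"
  cmp_post <- concordance_report(confusion_from_labels(
    predicted = !post$ciws_sensitive[determinate],
    truth = adverse[determinate]))
  cmp_recist <- concordance_report(confusion_from_labels(
    predicted = post_pat$nat_nonresponder[determinate],
    truth = adverse[determinate]))
  paired_corr <- paired_correctness_mcnemar(
    correct1 = (!post$ciws_sensitive[determinate]) ==
      adverse[determinate],
    correct2 = post_pat$nat_nonresponder[determinate] ==
      adverse[determinate])

  # paired pre/post deltas
  paired_ids <- intersect(pre$patient_id, post$patient_id)
  delta_block <- NULL
  if (length(paired_ids) >= 3) {
    d_ciws <- post$ciws[match(paired_ids, post$patient_id)] -
      pre$ciws[match(paired_ids, pre$patient_id)]
    pp <- pat[match(paired_ids, pat$patient_id), ]
    at5y_cat <- ifelse(pp$dfs5y == "DISEASE_FREE_5Y", "CR",
                       ifelse(pp$dfs5y == "RECURRENCE_WITHIN_5Y", "PD",
                              NA))
    keep <- !is.na(at5y_cat)
    d_recist <- recist_ordinal(at5y_cat[keep]) -
      recist_ordinal(pp$recist_nat[keep])
    d_ciws <- d_ciws[keep]
    delta_block <- list(
      n_pairs = sum(keep),
      delta_ciws = d_ciws, delta_recist = d_recist,
      directions = directional_concordance(direction_class(d_ciws),
                                           direction_class(d_recist)),
      correlations = tryCatch(rank_correlations(d_ciws, d_recist),
                              error = function(e) NULL))
  }

  # cutpoint + survival stratifications at patient level
  cut_cfg <- cutpoint_config(n_boot = cutpoint_boot)
  cut_dfs <- tryCatch(
    maxstat_cutpoint(pat$ciws_latest, pat$dfs_months, pat$dfs_event,
                     cut_cfg, endpoint = "DFS", seed = seed),
    error = function(e) e)
  cut_os <- tryCatch(
    maxstat_cutpoint(pat$ciws_latest, pat$os_months, pat$os_event,
                     cut_cfg, endpoint = "OS",
                     seed = if (is.null(seed)) NULL else seed + 1L),
    error = function(e) e)

  strata <- list()
  grp <- factor(ifelse(pat$ciws_latest_sensitive, "SENSITIVE",
                       "RESISTANT"), levels = c("RESISTANT", "SENSITIVE"))
  if (nlevels(droplevels(grp)) == 2) {
    strata$ciws_dfs <- list(
      cox = cox_binary(pat$dfs_months, pat$dfs_event, grp),
      means = mean_survival(pat$dfs_months, pat$dfs_event, grp))
    strata$ciws_os <- list(
      cox = cox_binary(pat$os_months, pat$os_event, grp),
      means = mean_survival(pat$os_months, pat$os_event, grp))
  }
  if (has_ofp && nrow(post) > 0) {
    og <- droplevels(post$growth_group)
    if (nlevels(og) == 2) {
      strata$ofp_dfs <- list(
        cox = cox_binary(post_pat$dfs_months, post_pat$dfs_event,
                         post$growth_group),
        means = mean_survival(post_pat$dfs_months, post_pat$dfs_event,
                              post$growth_group))
      strata$ofp_os <- list(
        cox = cox_binary(post_pat$os_months, post_pat$os_event,
                         post$growth_group),
        means = mean_survival(post_pat$os_months, post_pat$os_event,
                              post$growth_group))
    }
  }

  structure(list(
    n_samples = nrow(cohort), n_patients = nrow(pat),
    n_pre = nrow(pre), n_post = nrow(post),
    n_indeterminate_excluded = n_excluded,
    scored = scored, patients = pat,
    pre_ciws_vs_nat = cmp_pre,
    post_ciws_vs_5y = cmp_post,
    recist_vs_5y = cmp_recist,
    paired_correctness = paired_corr,
    delta_concordance = delta_block,
    cutpoint_dfs = cut_dfs, cutpoint_os = cut_os,
    strata = strata),
    class = "pdo_analysis")
}

#' @export
print.pdo_analysis <- function(x, ...) {
  cat(sprintf("PDO chemosensitivity analysis: %d samples / %d patients",
              x$n_samples, x$n_patients),
      sprintf("(%d pre, %d post)\n", x$n_pre, x$n_post))
  if (x$n_indeterminate_excluded > 0) {
    cat(sprintf("  [%d patient(s) censored before 5 years excluded from %s",
                x$n_indeterminate_excluded, "accuracy denominators]\n"))
  }
  cat("\n-- PDO (pre-NAT CIWS) vs NAT-RECIST --\n")
  print(x$pre_ciws_vs_nat)
  cat("\n-- PDO (post-NAT CIWS) vs 5-year outcome --\n")
  print(x$post_ciws_vs_5y)
  cat("\n-- NAT-RECIST vs 5-year outcome --\n")
  print(x$recist_vs_5y)
  cat("\n-- Paired correctness (CIWS vs RECIST as predictors) --\n")
  print(x$paired_correctness)
  if (!is.null(x$delta_concordance)) {
    cat("\n-- Paired pre/post direction concordance --\n")
    d <- x$delta_concordance
    cat(sprintf("  agreement %.1f%% (%d/%d), kappa = %.2f\n",
                100 * d$directions$agreement,
                round(d$directions$agreement * d$n_pairs), d$n_pairs,
                d$directions$kappa))
    if (!is.null(d$correlations)) print(d$correlations)
  }
  for (nm in c("cutpoint_dfs", "cutpoint_os")) {
    if (inherits(x[[nm]], "maxstat_cutpoint")) {
      cat("\n")
      print(x[[nm]])
    }
  }
  labels <- c(ciws_dfs = "CIWS strata, DFS", ciws_os = "CIWS strata, OS",
              ofp_dfs = "OFP growth groups, DFS",
              ofp_os = "OFP growth groups, OS")
  for (nm in names(x$strata)) {
    cat(sprintf("\n-- %s --\n", labels[[nm]]))
    print(x$strata[[nm]]$cox)
    print(x$strata[[nm]]$means)
  }
  invisible(x)
}
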