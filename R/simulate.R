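# Seeded synthetic cohort generator --------------------------------------

#' Configuration of the synthetic PDO cohort generator
#'
#' Describes a cohort with the structure of a paired pre/post neoadjuvant
#' chemotherapy (NAT) organoid study: `n_patients` patients contributing
#' `n_pre` pre-NAT and `n_post` post-NAT samples, `n_paired` of them
#' paired (defaults 23/18/13/8; the counts must satisfy
#' `n_pre + n_post - n_paired = n_patients` and
#' `n_paired <= min(n_pre, n_post)`).
#'
#' Each patient carries a latent chemosensitivity class
#' (`prevalence` = probability of being sensitive). A per-sample drug
#' potency is drawn from a class-specific beta distribution
#' (`potency_sensitive`, `potency_resistant` shape pairs; defaults give
#' mean potencies 0.68 and 0.36) and per-drug SCIRs are drawn around it
#' as `100 * Beta(k * m, k * (1 - m))` with concentration
#' `drug_concentration` -- a bounded-scale noise model that respects
#' \[0, 100\] without clamping distortions. Control (spontaneous) death
#' is `100 * Beta(control_shape1, control_shape2)` (default mean 10%).
#' Sensitive patients flip their latent class to resistant in the post-NAT
#' sample with probability `resistance_acquisition`, emulating acquired
#' resistance under therapy pressure.
#'
#' Survival attaches to the *realized* CIWS class of the patient's latest
#' sample: resistant patients draw exponential DFS with median
#' `median_dfs_resistant` months, sensitive patients with hazard
#' multiplied by `hr_dfs` (the ground-truth hazard ratio); overall
#' survival adds an exponential post-progression time with mean
#' `post_progression_mean`. Both are administratively censored at
#' `censor_horizon` months, plus optional uniform early censoring at rate
#' `early_censor_rate` (default 0: a fully followed cohort). Setting
#' `hr_dfs = 1` with `null_survival = TRUE` severs the score-survival
#' link entirely (survival ignores class) for type-I-error studies.
#'
#' RECIST trajectories are drawn per patient to land in an intended
#' category: responders (pre-NAT sensitive) in CR/PR/SD with
#' probabilities `responder_recist_probs`, nonresponders in PD with
#' probability `nonresponder_pd_prob` (else SD). Lesion measurements are
#' then generated inside the category's defining region, so the intended
#' category is recovered exactly by [classify_recist()]. OFP grades are
#' drawn per timepoint (`ofp_probs_pre`, `ofp_probs_post`, in I/II/III
#' order; the post default reproduces a 7/2/4-of-13 marginal) with
#' culture features generated inside each grade's region of the
#' [grade_ofp()] decision tree.
#'
#' @param n_patients,n_pre,n_post,n_paired Cohort shape.
#' @param prevalence Latent sensitivity prevalence in \[0, 1\].
#' @param potency_sensitive,potency_resistant Beta shape pairs.
#' @param drug_concentration Beta concentration of per-drug SCIR noise.
#' @param control_shape1,control_shape2 Beta shapes of control CIR.
#' @param resistance_acquisition Probability a sensitive patient's
#'   post-NAT sample is resistant.
#' @param hr_dfs True sensitive-vs-resistant DFS hazard ratio.
#' @param median_dfs_resistant Months.
#' @param post_progression_mean Mean months from progression to death.
#' @param censor_horizon Administrative censoring time (months).
#' @param early_censor_rate Exponential rate of additional censoring.
#' @param null_survival If `TRUE`, survival is independent of class.
#' @param responder_recist_probs Probabilities of CR/PR/SD for intended
#'   responders.
#' @param nonresponder_pd_prob Probability an intended nonresponder is PD.
#' @param ofp_probs_pre,ofp_probs_post OFP grade probabilities (I, II,
#'   III).
#' @return Named list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 23, n_pre = 18, n_post = 13,
                          n_paired = 8,
                          prevalence = 0.6,
                          potency_sensitive = c(20.4, 9.6),
                          potency_resistant = c(14.4, 25.6),
                          drug_concentration = 35,
                          control_shape1 = 2, control_shape2 = 18,
                          resistance_acquisition = 0.25,
                          hr_dfs = 0.2,
                          median_dfs_resistant = 7,
                          post_progression_mean = 18,
                          censor_horizon = 60,
                          early_censor_rate = 0,
                          null_survival = FALSE,
                          responder_recist_probs = c(CR = 0.05, PR = 0.45,
                                                     SD = 0.5),
                          nonresponder_pd_prob = 0.85,
                          ofp_probs_pre = c(0.70, 0.20, 0.10),
                          ofp_probs_post = c(7, 2, 4) / 13) {
  if (n_paired > min(n_pre, n_post)) {
    stop("n_paired may not exceed min(n_pre, n_post)", call. = FALSE)
  }
  if (n_pre + n_post - n_paired != n_patients) {
    stop("inconsistent cohort shape: need n_pre + n_post - n_paired ",
         "= n_patients", call. = FALSE)
  }
  stopifnot(prevalence >= 0, prevalence <= 1, hr_dfs > 0,
            median_dfs_resistant > 0, censor_horizon > 0,
            resistance_acquisition >= 0, resistance_acquisition <= 1,
            early_censor_rate >= 0, drug_concentration > 0)
  structure(as.list(environment()), class = "cohort_config")
}

.tier_int <- function(scir) findInterval(scir, c(30, 60, 80))

# lesion measurements landing exactly in an intended RECIST category
.draw_lesions <- function(categories) {
  n <- length(categories)
  baseline <- runif(n, 40, 120)
  nadir <- baseline
  current <- baseline
  new_lesions <- rep(FALSE, n)
  vanished <- rep(FALSE, n)
  for (i in seq_len(n)) {
    switch(as.character(categories[i]),
      CR = {
        vanished[i] <- TRUE; nadir[i] <- 0; current[i] <- 0
      },
      PR = {
        current[i] <- baseline[i] * runif(1, 0.45, 0.68)
        nadir[i] <- current[i]
      },
      SD = {
        current[i] <- baseline[i] * runif(1, 0.75, 0.98)
        nadir[i] <- current[i] * runif(1, 0.97, 1)
      },
      PD = {
        if (runif(1) < 0.5) {
          new_lesions[i] <- TRUE
          nadir[i] <- baseline[i] * runif(1, 0.8, 1)
          current[i] <- nadir[i] * runif(1, 1, 1.15)
        } else {
          nadir[i] <- baseline[i] * runif(1, 0.85, 1)
          current[i] <- nadir[i] * runif(1, 1.25, 1.6)
        }
      })
  }
  data.frame(baseline_sld_mm = baseline, nadir_sld_mm = nadir,
             current_sld_mm = current, new_lesions = new_lesions,
             vanished = vanished, node_short_axis_mm = NA_real_)
}

# culture observations landing exactly in an intended OFP grade
.draw_ofp_features <- function(grades) {
  n <- length(grades)
  days <- numeric(n); diam <- numeric(n); edu <- numeric(n)
  sus <- logical(n); viable <- logical(n)
  for (i in seq_len(n)) {
    switch(as.character(grades[i]),
      I = {
        days[i] <- runif(1, 4, 14); diam[i] <- runif(1, 110, 220)
        edu[i] <- runif(1, 0.45, 0.80); sus[i] <- TRUE; viable[i] <- TRUE
      },
      II = {
        days[i] <- runif(1, 8, 21); diam[i] <- runif(1, 60, 95)
        edu[i] <- runif(1, 0.12, 0.35); sus[i] <- FALSE; viable[i] <- TRUE
      },
      III = {
        days[i] <- if (runif(1) < 0.7) NA_real_ else runif(1, 22, 27)
        diam[i] <- runif(1, 0, 25)
        edu[i] <- runif(1, 0, 0.03); sus[i] <- FALSE; viable[i] <- FALSE
      })
  }
  data.frame(days_to_formation = days, cluster_diameter_um = diam,
             edu_fraction = edu, viable_after_3wk = viable,
             growth_sustained = sus)
}

.truth_columns <- c("latent_sensitive", "true_cutoff", "true_hr_dfs",
                    "intended_recist_nat", "intended_ofp")

# order-insensitive numeric digest of the analysis columns; cheap
# tamper-evidence for truth-mode tables
.cohort_checksum <- function(cohort) {
  cols <- setdiff(names(cohort), .truth_columns)
  h <- 0
  for (cl in cols) {
    v <- cohort[[cl]]
    v <- if (is.numeric(v)) round(v, 6) else as.character(v)
    s <- paste(cl, paste(v, collapse = ","))
    raw <- utf8ToInt(s)
    h <- (h + sum(raw * (seq_along(raw) %% 97 + 1))) %% 2147483647
  }
  h
}

#' Generate a synthetic PDO cohort
#'
#' Draws a full cohort table under a [cohort_config()]: one row per
#' patient x timepoint carrying the drug-assay readouts (control and
#' per-drug treated CIR), organoid-culture observations, lesion
#' measurements, and patient-level survival follow-up. Deterministic for
#' a fixed seed. In truth mode the table additionally carries the hidden
#' ground-truth columns (latent class, intended labels, true cutoff and
#' hazard ratio) used by parameter-recovery tests; analysis mode strips
#' them.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @param truth Keep the ground-truth columns (`TRUE`) or emit the
#'   analysis-mode table (`FALSE`).
#' @return Data frame of class `pdo_cohort`; attribute `truth_mode`
#'   records the mode, and truth-mode tables carry a checksum enabling
#'   [truth_report()] to detect tampering.
#' @examples
#' head(simulate_cohort(seed = 1))
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL,
                            truth = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  np <- config$n_patients
  ids <- sprintf("OS%02d", seq_len(np))
  # patients 1..n_paired are paired, then pre-only, then post-only
  has_pre <- seq_len(np) <= config$n_pre
  has_post <- seq_len(np) <= config$n_paired | seq_len(np) > config$n_pre

  latent_pre <- rbinom(np, 1, config$prevalence) == 1
  latent_post <- latent_pre &
    !(latent_pre & runif(np) < config$resistance_acquisition)

  draw_potency <- function(sensitive) {
    shp <- if (sensitive) config$potency_sensitive else
      config$potency_resistant
    rbeta(1, shp[1], shp[2])
  }

  draw_sample <- function(pid, tp, m) {
    k <- config$drug_concentration
    scir <- 100 * rbeta(length(PDO_DRUGS), k * m, k * (1 - m))
    control <- 100 * rbeta(1, config$control_shape1, config$control_shape2)
    treated <- pmin(control + scir, 100)
    row <- data.frame(patient_id = pid, timepoint = tp,
                      cir_control = control)
    for (j in seq_along(PDO_DRUGS)) {
      row[[paste0("cir_", tolower(PDO_DRUGS[j]))]] <- treated[j]
    }
    row
  }

  # tumor potency persists within a patient unless the latent class flips
  # (acquired resistance under therapy pressure)
  rows <- list()
  for (i in seq_len(np)) {
    m_pre <- draw_potency(latent_pre[i])
    m_post <- if (latent_post[i] == latent_pre[i]) m_pre else
      draw_potency(latent_post[i])
    if (has_pre[i]) {
      rows[[length(rows) + 1]] <-
        cbind(draw_sample(ids[i], "pre", m_pre),
              latent_sensitive = latent_pre[i])
    }
    if (has_post[i]) {
      rows[[length(rows) + 1]] <-
        cbind(draw_sample(ids[i], "post", m_post),
              latent_sensitive = latent_post[i])
    }
  }
  cohort <- do.call(rbind, rows)

  # OFP grade per sample, features drawn inside the grade's region
  intended_ofp <- vapply(cohort$timepoint, function(tp) {
    p <- if (tp == "pre") config$ofp_probs_pre else config$ofp_probs_post
    sample(c("I", "II", "III"), 1, prob = p)
  }, character(1), USE.NAMES = FALSE)
  cohort <- cbind(cohort, .draw_ofp_features(intended_ofp),
                  intended_ofp = intended_ofp)

  # realized CIWS class of each sample, and of each patient's latest sample
  scir_cols <- paste0("cir_", tolower(MAPI_REGIMEN))
  scir_mat <- sapply(scir_cols, function(cl) {
    compute_scir(cohort[[cl]], cohort$cir_control)
  })
  ciws_vec <- rowSums(matrix(.tier_int(scir_mat), nrow = nrow(cohort)))
  is_latest <- cohort$timepoint == "post" |
    (cohort$timepoint == "pre" & !has_post[match(cohort$patient_id, ids)])
  latest_sensitive <- setNames(ciws_vec[is_latest] >= 5,
                               cohort$patient_id[is_latest])

  # RECIST trajectory per patient, driven by the pre-NAT latent class
  intended_cat <- character(np)
  for (i in seq_len(np)) {
    if (latent_pre[i]) {
      p <- config$responder_recist_probs
      intended_cat[i] <- sample(names(p), 1, prob = p)
    } else {
      intended_cat[i] <- if (runif(1) < config$nonresponder_pd_prob)
        "PD" else "SD"
    }
  }
  lesions <- .draw_lesions(intended_cat)
  lesions$patient_id <- ids
  cohort <- merge(cohort, cbind(lesions,
                                intended_recist_nat = intended_cat),
                  by = "patient_id", sort = FALSE)

  # survival per patient from the realized CIWS class of the latest sample
  lam0 <- log(2) / config$median_dfs_resistant
  cls <- latest_sensitive[ids]
  lam <- if (config$null_survival) rep(lam0, np) else
    ifelse(cls, lam0 * config$hr_dfs, lam0)
  dfs_t <- rexp(np, lam)
  os_t <- dfs_t + rexp(np, 1 / config$post_progression_mean)
  cens <- rep(config$censor_horizon, np)
  if (config$early_censor_rate > 0) {
    cens <- pmin(cens, rexp(np, config$early_censor_rate))
  }
  surv <- data.frame(patient_id = ids,
                     dfs_months = pmin(dfs_t, cens),
                     dfs_event = as.integer(dfs_t <= cens),
                     os_months = pmin(os_t, cens),
                     os_event = as.integer(os_t <= cens))
  cohort <- merge(cohort, surv, by = "patient_id", sort = FALSE)
  cohort$true_cutoff <- 4.5
  cohort$true_hr_dfs <- if (config$null_survival) 1 else config$hr_dfs
  cohort$latent_sensitive <- as.integer(cohort$latent_sensitive)

  # flags as 0/1 per the tabular I/O contract
  for (cl in intersect(.COHORT_FLAGS, names(cohort))) {
    cohort[[cl]] <- as.integer(cohort[[cl]])
  }

  ord <- order(cohort$patient_id,
               match(cohort$timepoint, c("pre", "post")))
  cohort <- cohort[ord, , drop = FALSE]
  rownames(cohort) <- NULL
  if (!truth) {
    cohort <- cohort[, setdiff(names(cohort), .truth_columns),
                     drop = FALSE]
    attr(cohort, "truth_mode") <- FALSE
  } else {
    attr(cohort, "truth_mode") <- TRUE
    attr(cohort, "truth_checksum") <- .cohort_checksum(cohort)
  }
  class(cohort) <- c("pdo_cohort", "data.frame")
  cohort
}

#' Ground-truth summary of a truth-mode cohort
#'
#' Extracts the generator's hidden ground truth for parameter-recovery
#' testing: per-sample latent class, the true score cutoff, the true DFS
#' hazard ratio, and the intended RECIST/OFP labels. Refuses
#' analysis-mode tables and tables whose analysis columns were modified
#' after generation (checksum mismatch).
#'
#' @param cohort Truth-mode table from [simulate_cohort()].
#' @return List with `true_cutoff`, `true_hr_dfs`, `latent` (per-sample
#'   data frame), `n_samples`, `n_patients`.
#' @export
truth_report <- function(cohort) {
  if (!isTRUE(attr(cohort, "truth_mode")) ||
      !all(.truth_columns %in% names(cohort))) {
    stop("truth_report requires a truth-mode cohort", call. = FALSE)
  }
  stored <- attr(cohort, "truth_checksum")
  if (!identical(.cohort_checksum(cohort), stored)) {
    stop("cohort checksum mismatch: table was modified after generation",
         call. = FALSE)
  }
  list(true_cutoff = cohort$true_cutoff[1],
       true_hr_dfs = cohort$true_hr_dfs[1],
       latent = cohort[, c("patient_id", "timepoint", "latent_sensitive",
                           "intended_recist_nat", "intended_ofp")],
       n_samples = nrow(cohort),
       n_patients = length(unique(cohort$patient_id)))
}

#' Long-format drug assays from a cohort table
#'
#' Reshapes the wide per-sample drug columns of a cohort into the long
#' assay format consumed by [score_samples()]: one row per patient x
#' timepoint x drug with `cir_treated` and `cir_control`.
#'
#' @param cohort A cohort table (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @return Long-format data frame.
#' @export
cohort_assays <- function(cohort) {
  cols <- paste0("cir_", tolower(PDO_DRUGS))
  miss <- setdiff(c(cols, "cir_control"), names(cohort))
  if (length(miss)) {
    stop("cohort is missing assay column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(PDO_DRUGS), function(j) {
    data.frame(patient_id = cohort$patient_id,
               timepoint = cohort$timepoint,
               drug_id = PDO_DRUGS[j],
               cir_treated = cohort[[cols[j]]],
               cir_control = cohort$cir_control,
               stringsAsFactors = FALSE)
  }))
  out[order(out$patient_id, out$timepoint), , drop = FALSE]
}
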