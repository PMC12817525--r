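# SCIR / efficacy tiers / CIWS -------------------------------------------

TIER_SYMBOLS <- c("-", "+", "++", "+++")

.check_pct <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad)) {
    stop(what, " must lie in [0, 100]; offending value(s): ",
         paste(format(x[bad][seq_len(min(3, sum(bad)))]), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Standardized cell inhibition rate
#'
#' The raw cell inhibition rate (CIR) of a drug is the percentage of dead
#' cells in drug-treated organoids; untreated organoids carry a background
#' of spontaneous death. The standardized rate subtracts that background,
#' `SCIR = CIR_drug - CIR_control`, and represents the kill fraction
#' attributable to the agent. Negative differences (control death exceeding
#' treated death) are clamped to 0, and the result is capped at 100.
#'
#' @param cir_treated Percentage of dead cells under drug, in \[0, 100\].
#' @param cir_control Percentage of dead cells in untreated controls, in
#'   \[0, 100\].
#' @return Numeric vector of SCIR percentages in \[0, 100\].
#' @examples
#' compute_scir(70, 10)  # 60
#' compute_scir(5, 20)   # clamped to 0
#' @export
compute_scir <- function(cir_treated, cir_control) {
  .check_pct(cir_treated, "cir_treated")
  .check_pct(cir_control, "cir_control")
  pmin(pmax(cir_treated - cir_control, 0), 100)
}

#' Efficacy tier of a standardized inhibition rate
#'
#' Maps SCIR percentages onto the four-level ordinal efficacy scale used
#' for osteosarcoma PDO screens: not effective (`-`, SCIR < 30),
#' possibly effective (`+`, 30 to < 60), likely effective (`++`, 60 to
#' < 80) and highly effective (`+++`, SCIR >= 80). Lower bounds are
#' inclusive, so 30, 60 and 80 fall in the upper tier and 100 maps to
#' `+++`.
#'
#' @param scir Numeric vector of SCIR percentages in \[0, 100\].
#' @return Ordered factor with levels `-` < `+` < `++` < `+++`.
#' @seealso [tier_value()] for the 0--3 numeric coding.
#' @examples
#' assign_tier(c(29.9, 30, 60, 80, 100))
#' @export
assign_tier <- function(scir) {
  .check_pct(scir, "scir")
  idx <- findInterval(scir, c(30, 60, 80)) + 1L
  factor(TIER_SYMBOLS[idx], levels = TIER_SYMBOLS, ordered = TRUE)
}

#' Numeric value of an efficacy tier
#'
#' The ordinal tiers carry fixed values `-` = 0, `+` = 1, `++` = 2,
#' `+++` = 3; these are the addends of the CIWS.
#'
#' @param tier Ordered factor from [assign_tier()], or a character vector
#'   of tier symbols.
#' @return Integer vector in 0..3.
#' @export
tier_value <- function(tier) {
  if (is.character(tier)) {
    tier <- factor(tier, levels = TIER_SYMBOLS, ordered = TRUE)
  }
  if (!is.factor(tier) || !identical(levels(tier), TIER_SYMBOLS)) {
    stop("tier must be a tier factor or one of: ",
         paste(TIER_SYMBOLS, collapse = " "), call. = FALSE)
  }
  if (anyNA(tier)) stop("invalid tier symbol", call. = FALSE)
  as.integer(tier) - 1L
}

#' Composite cell inhibition weighted score (CIWS)
#'
#' Sums the efficacy-tier values of the drugs in a regimen into a single
#' composite score. With the default four-drug MAPI regimen the score lies
#' in 0--12, and a sample is called `SENSITIVE` when the score reaches the
#' sensitivity cutoff (default 5, i.e. `CIWS >= 5+`), `RESISTANT`
#' otherwise. The input is a named profile over the drug panel: either
#' SCIR percentages (tiered internally via [assign_tier()]) or
#' pre-assigned tier symbols.
#'
#' @param profile Named vector keyed by drug id: numeric SCIR percentages,
#'   or character/factor tier symbols (`-`, `+`, `++`, `+++`).
#' @param regimen Drug ids to sum over; defaults to [MAPI_REGIMEN]
#'   (carboplatin excluded). Every regimen drug must be present in
#'   `profile`; missing assays raise an error rather than being imputed.
#' @param cutoff Minimum score called sensitive (default 5).
#' @return Object of class `ciws_score`: list with `score` (integer),
#'   `classification` (`"SENSITIVE"`/`"RESISTANT"`), `tiers` (ordered
#'   factor named by drug), `contributing_drugs`, `cutoff`.
#' @examples
#' compute_ciws(c(DOX = "+++", CDDP = "+", MTX = "+", IFO = "-"))
#' compute_ciws(c(DOX = 85, CDDP = 40, MTX = 35, IFO = 10, CBP = 70))
#' @export
compute_ciws <- function(profile, regimen = MAPI_REGIMEN, cutoff = 5L) {
  if (is.null(names(profile)) || any(!nzchar(names(profile)))) {
    stop("profile must be named by drug id", call. = FALSE)
  }
  regimen <- as.character(regimen)
  missing_drugs <- setdiff(regimen, names(profile))
  if (length(missing_drugs)) {
    stop("profile is missing regimen drug(s): ",
         paste(missing_drugs, collapse = ", "), call. = FALSE)
  }
  sel <- profile[regimen]
  tiers <- if (is.numeric(profile)) assign_tier(sel) else {
    f <- factor(as.character(sel), levels = TIER_SYMBOLS, ordered = TRUE)
    if (anyNA(f)) stop("invalid tier symbol in profile", call. = FALSE)
    f
  }
  names(tiers) <- regimen
  score <- sum(tier_value(tiers))
  structure(
    list(score = as.integer(score),
         classification = if (score >= cutoff) "SENSITIVE" else "RESISTANT",
         tiers = tiers,
         contributing_drugs = regimen,
         cutoff = as.integer(cutoff)),
    class = "ciws_score")
}

#' @export
print.ciws_score <- function(x, ...) {
  cat("CIWS =", format_ciws_label(x$score), "->", x$classification,
      sprintf("(cutoff >= %d+)\n", x$cutoff))
  cat("  tiers:", paste(names(x$tiers), as.character(x$tiers), sep = ":",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Change in CIWS between paired assessments
#'
#' For paired pre-/post-treatment organoid screens of the same patient,
#' the signed difference `post - pre` tracks acquired resistance (negative
#' shift) or gained sensitivity (positive shift). Both scores must have
#' been computed over the same regimen.
#'
#' @param pre,post `ciws_score` objects (or plain integer scores, in which
#'   case no regimen check is possible).
#' @return Signed integer difference.
#' @examples
#' pre  <- compute_ciws(c(DOX = "+++", CDDP = "+", MTX = "+", IFO = "-"))
#' post <- compute_ciws(c(DOX = "+",   CDDP = "+", MTX = "+", IFO = "-"))
#' delta_ciws(pre, post)  # -2
#' @export
delta_ciws <- function(pre, post) {
  get_score <- function(z) {
    if (inherits(z, "ciws_score")) z$score else as.integer(z)
  }
  if (inherits(pre, "ciws_score") && inherits(post, "ciws_score") &&
      !identical(sort(pre$contributing_drugs), sort(post$contributing_drugs))) {
    stop("pre and post CIWS were computed over different regimens",
         call. = FALSE)
  }
  get_score(post) - get_score(pre)
}

#' Score a long-format assay table sample by sample
#'
#' Takes per-drug assay rows (one row per patient x timepoint x drug) and
#' returns one row per sample with the per-drug tier symbols, the CIWS and
#' the sensitive/resistant call -- the same layout as a per-patient
#' screening report table.
#'
#' @param assays Data frame with columns `patient_id`, `timepoint`,
#'   `drug_id` and either `scir` or both `cir_treated` and `cir_control`.
#' @param regimen,cutoff Passed to [compute_ciws()].
#' @return Data frame with one row per sample: `patient_id`, `timepoint`,
#'   one tier-symbol column per panel drug present, `ciws`, `ciws_label`
#'   (e.g. `"5+"`), `call` (`"S"`/`"R"`).
#' @export
score_samples <- function(assays, regimen = MAPI_REGIMEN, cutoff = 5L) {
  req <- c("patient_id", "timepoint", "drug_id")
  miss <- setdiff(req, names(assays))
  if (length(miss)) {
    stop("assays is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"scir" %in% names(assays)) {
    if (!all(c("cir_treated", "cir_control") %in% names(assays))) {
      stop("assays needs either 'scir' or 'cir_treated' + 'cir_control'",
           call. = FALSE)
    }
    assays$scir <- compute_scir(assays$cir_treated, assays$cir_control)
  }
  key <- interaction(assays$patient_id, assays$timepoint, drop = TRUE)
  out <- lapply(split(assays, key), function(d) {
    profile <- setNames(d$scir, as.character(d$drug_id))
    cw <- compute_ciws(profile, regimen = regimen, cutoff = cutoff)
    tiers <- setNames(as.character(assign_tier(profile)), names(profile))
    row <- data.frame(patient_id = d$patient_id[1],
                      timepoint = d$timepoint[1],
                      stringsAsFactors = FALSE)
    for (dr in names(profile)) row[[paste0("tier_", dr)]] <- tiers[dr]
    row$ciws <- cw$score
    row$ciws_label <- format_ciws_label(cw$score)
    row$call <- if (cw$classification == "SENSITIVE") "S" else "R"
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$patient_id, out$timepoint), , drop = FALSE]
}

#' Parse and format the "5+" score notation
#'
#' Screening report tables write composite scores with a plus suffix
#' (`"5+"`); these helpers round-trip that notation to plain integers.
#'
#' @param x Character vector like `"5+"` (`parse_ciws_label`) or integer
#'   scores (`format_ciws_label`).
#' @return Integer vector, or character vector with `+` suffix.
#' @examples
#' parse_ciws_label(c("5+", "3", "12+"))
#' format_ciws_label(0:3)
#' @export
parse_ciws_label <- function(x) {
  x <- trimws(as.character(x))
  bad <- !grepl("^[0-9]+\\+?$", x) & !is.na(x)
  if (any(bad)) {
    stop("malformed CIWS label(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  as.integer(sub("\\+$", "", x))
}

#' @rdname parse_ciws_label
#' @export
format_ciws_label <- function(x) paste0(as.integer(x), "+")
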