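# RECIST 1.1 classification and outcome labels ---------------------------

RECIST_LEVELS <- c("CR", "PR", "SD", "PD")

#' RECIST 1.1 response category from lesion measurements
#'
#' Applies the RECIST 1.1 target-lesion rules to sum-of-longest-diameter
#' (SLD) measurements. Evaluation order is fixed: complete response (CR)
#' when all target lesions have vanished and any pathologic node has a
#' short axis under 10 mm; otherwise progressive disease (PD) when new
#' lesions appear or the SLD has grown at least 20\% from the nadir with
#' an absolute rise of at least 5 mm; otherwise partial response (PR)
#' when the SLD has dropped at least 30\% from baseline; otherwise stable
#' disease (SD). PD takes precedence over PR when growth from a deep
#' nadir coexists with a large drop from baseline. Ratios are compared
#' exactly, without rounding.
#'
#' @param baseline_sld,nadir_sld,current_sld SLD in millimetres; the nadir
#'   may not exceed baseline.
#' @param new_lesions Logical; appearance of any new lesion.
#' @param target_lesions_vanished Logical; disappearance of all target
#'   lesions.
#' @param node_short_axis Short axis of residual pathologic nodes in mm,
#'   or `NA` when none.
#' @return Factor with levels `CR`, `PR`, `SD`, `PD`.
#' @examples
#' classify_recist(100, 68, 68)              # PR (32% decrease)
#' classify_recist(100, 50, 61)              # PD (+22%, +11 mm)
#' classify_recist(100, 20, 24)              # SD (absolute rise < 5 mm)
#' classify_recist(76, 76, 76)               # SD (size-stable lesion)
#' @export
classify_recist <- function(baseline_sld, nadir_sld, current_sld,
                            new_lesions = FALSE,
                            target_lesions_vanished = FALSE,
                            node_short_axis = NA_real_) {
  n <- max(length(baseline_sld), length(nadir_sld), length(current_sld),
           length(new_lesions), length(target_lesions_vanished),
           length(node_short_axis))
  b <- rep_len(as.numeric(baseline_sld), n)
  nd <- rep_len(as.numeric(nadir_sld), n)
  cur <- rep_len(as.numeric(current_sld), n)
  nl <- rep_len(as.logical(new_lesions), n)
  van <- rep_len(as.logical(target_lesions_vanished), n)
  nodes <- rep_len(as.numeric(node_short_axis), n)
  if (any(c(b, nd, cur) < 0, na.rm = TRUE)) {
    stop("SLD measurements must be >= 0", call. = FALSE)
  }
  if (any(nd > b)) stop("nadir_sld may not exceed baseline_sld",
                        call. = FALSE)
  if (any(b == 0 & !van)) {
    stop("baseline_sld of 0 without vanished target lesions: ",
         "response ratio undefined", call. = FALSE)
  }
  cr <- van & (is.na(nodes) | nodes < 10)
  pd <- !cr & (nl | (cur >= 1.2 * nd & cur - nd >= 5))
  pr <- !cr & !pd & cur <= 0.7 * b
  cat_chr <- ifelse(cr, "CR", ifelse(pd, "PD", ifelse(pr, "PR", "SD")))
  factor(cat_chr, levels = RECIST_LEVELS)
}

#' Binarize a RECIST category into responder / nonresponder
#'
#' Responders are CR, PR or SD; only PD counts as nonresponse. This is the
#' dichotomization used for all accuracy comparisons, with nonresponse as
#' the positive class.
#'
#' @param category RECIST factor or character vector.
#' @return Factor with levels `RESPONDER`, `NONRESPONDER`.
#' @export
binarize_recist <- function(category) {
  g <- as.character(category)
  bad <- !g %in% RECIST_LEVELS & !is.na(g)
  if (any(bad)) stop("invalid RECIST category: ",
                     paste(unique(g[bad]), collapse = ", "), call. = FALSE)
  factor(ifelse(g == "PD", "NONRESPONDER", "RESPONDER"),
         levels = c("RESPONDER", "NONRESPONDER"))
}

#' Five-year disease-free-survival label
#'
#' Most osteosarcoma relapses occur within five years of surgery, so the
#' 60-month mark is used as the long-term benchmark: relapse (event)
#' before 60 months labels the patient `RECURRENCE_WITHIN_5Y`
#' (chemoresistant course); follow-up reaching 60 months with no earlier
#' event labels them `DISEASE_FREE_5Y` (the benchmark is inclusive);
#' censoring before 60 months is `INDETERMINATE` and is excluded from
#' accuracy denominators downstream.
#'
#' @param dfs_months Disease-free survival time in months (>= 0).
#' @param dfs_event Logical/0-1; relapse or progression observed.
#' @param benchmark Months defining long-term disease freedom (default 60).
#' @return Factor with levels `DISEASE_FREE_5Y`, `RECURRENCE_WITHIN_5Y`,
#'   `INDETERMINATE`.
#' @examples
#' label_5yr_dfs(c(3, 60, 24), c(TRUE, FALSE, FALSE))
#' @export
label_5yr_dfs <- function(dfs_months, dfs_event, benchmark = 60) {
  t <- as.numeric(dfs_months)
  e <- as.logical(dfs_event)
  if (any(is.na(t)) || any(t < 0)) {
    stop("dfs_months must be non-negative and non-missing", call. = FALSE)
  }
  lab <- ifelse(e & t < benchmark, "RECURRENCE_WITHIN_5Y",
                ifelse(t >= benchmark, "DISEASE_FREE_5Y", "INDETERMINATE"))
  factor(lab, levels = c("DISEASE_FREE_5Y", "RECURRENCE_WITHIN_5Y",
                         "INDETERMINATE"))
}

#' Ordinal coding of RECIST categories
#'
#' Codes CR = 3, PR = 2, SD = 1, PD = 0, so that a falling ordinal value
#' means clinical worsening. Paired differences of this coding share their
#' sign convention with paired CIWS differences: negative = worsened.
#'
#' @param category RECIST factor or character vector.
#' @return Integer vector in 0..3.
#' @export
recist_ordinal <- function(category) {
  g <- as.character(category)
  code <- c(CR = 3L, PR = 2L, SD = 1L, PD = 0L)
  bad <- !g %in% names(code) & !is.na(g)
  if (any(bad)) stop("invalid RECIST category: ",
                     paste(unique(g[bad]), collapse = ", "), call. = FALSE)
  unname(code[g])
}

#' Direction of a paired change
#'
#' Collapses a signed paired difference (change in CIWS, or change in the
#' RECIST ordinal coding) into the three-level direction label used for
#' paired concordance: positive = `IMPROVED`, zero = `STABLE`, negative =
#' `WORSENED`.
#'
#' @param delta Numeric vector of signed paired differences.
#' @return Factor with levels `IMPROVED`, `STABLE`, `WORSENED`.
#' @examples
#' direction_class(c(-2, 0, 3))
#' @export
direction_class <- function(delta) {
  if (anyNA(delta)) stop("missing pair member in paired delta",
                         call. = FALSE)
  lab <- ifelse(delta > 0, "IMPROVED", ifelse(delta < 0, "WORSENED",
                                              "STABLE"))
  factor(lab, levels = c("IMPROVED", "STABLE", "WORSENED"))
}
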