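# Worked-example fixtures -------------------------------------------------

#' Worked-example confusion counts
#'
#' The three published 2x2 prediction-vs-truth tables of a 23-patient
#' osteosarcoma PDO validation cohort, reconstructed from the reported
#' sensitivity/specificity/PPV/NPV fractions. Positive class = adverse
#' outcome. `pre_ciws_vs_nat`: pre-NAT CIWS predictions against the
#' post-NAT RECIST response over 18 samples. `post_ciws_vs_5y`: post-NAT
#' CIWS predictions against the 5-year outcome over 13 samples.
#' `recist_vs_5y`: the NAT RECIST response itself as predictor of the
#' 5-year outcome over the same 13 patients. These serve as the worked
#' example for [concordance_report()] and as a regression fixture for
#' the exact-statistics battery.
#'
#' @return Named list of three [confusion_counts()] tables.
#' @examples
#' concordance_report(pdo_example_counts()$pre_ciws_vs_nat)
#' @export
pdo_example_counts <- function() {
  list(pre_ciws_vs_nat = confusion_counts(tp = 4, fp = 2, fn = 1,
                                          tn = 11),
       post_ciws_vs_5y = confusion_counts(tp = 7, fp = 0, fn = 2,
                                          tn = 4),
       recist_vs_5y = confusion_counts(tp = 5, fp = 0, fn = 4, tn = 4))
}

#' Worked-example tier profiles of an acquired-resistance course
#'
#' Per-drug efficacy tiers of one patient's paired organoid screens: the
#' pre-treatment screen scores CIWS 5+ (sensitive: doxorubicin highly
#' effective, cisplatin and methotrexate possibly effective, ifosfamide
#' not effective), the post-treatment screen drops to 3+ (resistant) --
#' the signature shift of resistance acquired under therapy. Used as the
#' worked example for [compute_ciws()] and [delta_ciws()].
#'
#' @return List with `pre` and `post` named tier-symbol vectors over the
#'   MAPI drugs.
#' @examples
#' ex <- pdo_example_tiers()
#' delta_ciws(compute_ciws(ex$pre), compute_ciws(ex$post))  # -2
#' @export
pdo_example_tiers <- function() {
  list(pre = c(DOX = "+++", CDDP = "+", MTX = "+", IFO = "-"),
       post = c(DOX = "+", CDDP = "+", MTX = "+", IFO = "-"))
}
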