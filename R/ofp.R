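# Organoid formation potential (OFP) grading -----------------------------

#' Thresholds for OFP grading
#'
#' The published grade definitions are partly qualitative ("abundant",
#' "moderate", "few" EdU-positive nuclei); these defaults operationalize
#' them while staying tunable. `edu_high` (default 0.40) is the minimum
#' EdU-positive fraction for robust-forming cultures, `edu_low` (0.05) the
#' floor below which proliferation is considered absent, `diameter_min`
#' (30 um) the smallest cluster diameter counted as organoid growth,
#' `diameter_robust` (100 um) the diameter above which clusters count as
#' dense and highly viable, `formation_window` (21 days) the three-week
#' boundary (inclusive) for timely formation, and `observation_window`
#' (28 days) the total culture observation period.
#'
#' @param edu_high,edu_low EdU-positive fraction thresholds in \[0, 1\].
#' @param diameter_min,diameter_robust Cluster diameters in micrometres.
#' @param formation_window,observation_window Days.
#' @return Named list of thresholds.
#' @export
ofp_thresholds <- function(edu_high = 0.40, edu_low = 0.05,
                           diameter_min = 30, diameter_robust = 100,
                           formation_window = 21, observation_window = 28) {
  stopifnot(edu_low < edu_high, edu_low >= 0, edu_high <= 1,
            diameter_min < diameter_robust,
            formation_window <= observation_window)
  list(edu_high = edu_high, edu_low = edu_low,
       diameter_min = diameter_min, diameter_robust = diameter_robust,
       formation_window = formation_window,
       observation_window = observation_window)
}

#' Grade organoid formation potential
#'
#' Classifies a culture into the three-level OFP scale from formation
#' kinetics and proliferation features. Grade III (minimal/non-forming)
#' if no organoid appears within the three-week window, the EdU-positive
#' fraction is below `edu_low`, or the cluster diameter is below
#' `diameter_min` -- proliferation features dominate, so a large but
#' EdU-negative culture is still grade III. Grade I (robust-forming) if
#' formation occurs within the window, the diameter exceeds
#' `diameter_robust`, the EdU fraction reaches `edu_high`, and growth is
#' sustained. Everything else is grade II (intermediate).
#'
#' @param days_to_formation Days from seeding to first organoid emergence;
#'   `NA` means no formation within the observation window.
#' @param cluster_diameter Cluster diameter in micrometres.
#' @param edu_fraction EdU-positive fraction in \[0, 1\].
#' @param growth_sustained Logical; `TRUE` when expansion does not decline
#'   over the culture period.
#' @param viable_after_3wk Logical; retained for the record but not used
#'   by the decision tree (grade II covers viable, declining cultures).
#' @param thresholds List from [ofp_thresholds()].
#' @return Ordered factor with levels `III` < `II` < `I` (higher =
#'   greater formation potential).
#' @examples
#' grade_ofp(5, 120, 0.60, TRUE)    # I
#' grade_ofp(NA, 10, 0.01, FALSE)   # III
#' grade_ofp(14, 80, 0.30, FALSE)   # II
#' @export
grade_ofp <- function(days_to_formation, cluster_diameter, edu_fraction,
                      growth_sustained, viable_after_3wk = NULL,
                      thresholds = ofp_thresholds()) {
  n <- max(length(days_to_formation), length(cluster_diameter),
           length(edu_fraction), length(growth_sustained))
  days <- rep_len(days_to_formation, n)
  diam <- rep_len(cluster_diameter, n)
  edu <- rep_len(edu_fraction, n)
  sus <- rep_len(growth_sustained, n)
  missing_feats <- c(
    if (anyNA(diam)) "cluster_diameter",
    if (anyNA(edu)) "edu_fraction",
    if (anyNA(sus)) "growth_sustained")
  if (length(missing_feats)) {
    stop("missing required OFP feature(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  if (any(diam < 0)) stop("cluster_diameter must be >= 0", call. = FALSE)
  if (any(edu < 0 | edu > 1)) {
    stop("edu_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(days) & days > thresholds$observation_window)) {
    stop("days_to_formation exceeds the observation window", call. = FALSE)
  }
  formed_in_window <- !is.na(days) & days <= thresholds$formation_window
  is3 <- !formed_in_window | edu < thresholds$edu_low |
    diam < thresholds$diameter_min
  is1 <- !is3 & formed_in_window & diam > thresholds$diameter_robust &
    edu >= thresholds$edu_high & sus
  grade <- ifelse(is3, "III", ifelse(is1, "I", "II"))
  factor(grade, levels = c("III", "II", "I"), ordered = TRUE)
}

#' Collapse OFP grades into growth-potential groups
#'
#' For outcome stratification, robust-forming cultures (grade I) form the
#' high-growth-potential group and grades II/III the low-growth-potential
#' group; after chemotherapy, low residual formation potential indicates
#' diminished tumor viability.
#'
#' @param grade Factor from [grade_ofp()] (or character `"I"/"II"/"III"`).
#' @return Factor with levels `HIGH`, `LOW`.
#' @examples
#' group_ofp(c("I", "II", "III"))
#' @export
group_ofp <- function(grade) {
  g <- as.character(grade)
  bad <- !g %in% c("I", "II", "III") & !is.na(g)
  if (any(bad)) stop("invalid OFP grade: ", paste(unique(g[bad]),
                     collapse = ", "), call. = FALSE)
  factor(ifelse(g == "I", "HIGH", "LOW"), levels = c("HIGH", "LOW"))
}
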