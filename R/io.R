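# Tabular I/O ------------------------------------------------------------

.COHORT_NUMERIC <- c("cir_control", paste0("cir_", tolower(PDO_DRUGS)),
                     "cluster_diameter_um", "edu_fraction",
                     "baseline_sld_mm", "nadir_sld_mm", "current_sld_mm",
                     "dfs_months", "os_months")
.COHORT_FLAGS <- c("viable_after_3wk", "growth_sustained", "new_lesions",
                   "vanished", "dfs_event", "os_event")

#' Read and write cohort tables
#'
#' Cohort tables are UTF-8 CSV with a header row: one row per patient x
#' timepoint, months as decimals, flags as 0/1, percentages on the 0-100
#' scale. `read_cohort` validates the schema strictly -- required columns
#' must be present with the right type, negative survival times are
#' rejected with the offending row numbers, unknown columns produce a
#' warning -- and parses any `ciws` column written in `"5+"` notation.
#' `write_cohort` is the inverse; write-then-read round-trips the table.
#'
#' @param path File path.
#' @param required Column names that must be present (default: the
#'   identifier, assay and survival columns).
#' @return `read_cohort`: a validated data frame of class `pdo_cohort`.
#' @export
read_cohort <- function(path,
                        required = c("patient_id", "timepoint",
                                     "cir_control", "dfs_months",
                                     "dfs_event")) {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop("cohort file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  known <- unique(c("patient_id", "timepoint", .COHORT_NUMERIC,
                    .COHORT_FLAGS, "days_to_formation",
                    "node_short_axis_mm", "ciws", "ciws_label"))
  unknown <- setdiff(names(d), known)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  numeric_like <- c(.COHORT_NUMERIC, "days_to_formation",
                    "node_short_axis_mm")
  for (cl in intersect(numeric_like, names(d))) {
    if (is.logical(d[[cl]]) && all(is.na(d[[cl]]))) {
      d[[cl]] <- as.numeric(d[[cl]])  # empty column parsed as logical
    }
    if (!is.numeric(d[[cl]])) {
      stop("column '", cl, "' must be numeric", call. = FALSE)
    }
  }
  for (cl in intersect(c("dfs_months", "os_months"), names(d))) {
    bad <- which(!is.na(d[[cl]]) & d[[cl]] < 0)
    if (length(bad)) {
      stop("negative ", cl, " at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  for (cl in intersect(.COHORT_FLAGS, names(d))) {
    v <- d[[cl]]
    if (is.logical(v)) v <- as.integer(v)
    if (!all(v %in% c(0L, 1L, NA))) {
      stop("column '", cl, "' must be a 0/1 flag", call. = FALSE)
    }
    d[[cl]] <- as.integer(v)
  }
  if ("ciws" %in% names(d) && is.character(d$ciws)) {
    d$ciws <- parse_ciws_label(d$ciws)
  }
  class(d) <- c("pdo_cohort", "data.frame")
  attr(d, "truth_mode") <- FALSE
  d
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  d <- as.data.frame(cohort)
  d <- d[, setdiff(names(d), .truth_columns), drop = FALSE]
  write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a human-readable analysis report
#'
#' Serializes any of the package's printed summaries (a
#' [run_reproduction()] result, a [concordance_report()], a
#' [maxstat_cutpoint()], ...) into a plain-text report file via its print
#' method.
#'
#' @param report Object with a print method.
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  writeLines(capture.output(print(report)), path)
  invisible(path)
}
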