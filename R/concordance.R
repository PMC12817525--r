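# Prediction-vs-truth concordance battery --------------------------------

#' Build a 2x2 confusion table from binary labels
#'
#' Cross-tabulates predictions against ground truth with the *adverse*
#' outcome (nonresponse / PD / recurrence) as the positive class, the
#' convention used throughout PDO validation reports. Cells: `tp` both
#' positive, `fp` predicted positive only, `fn` predicted negative only,
#' `tn` both negative. In the paired-discordance notation, `b = fn` and
#' `c = fp`.
#'
#' @param predicted,truth Vectors of equal length: logical (`TRUE` =
#'   positive class), or factors/characters, in which case `positive`
#'   names the positive level.
#' @param positive The positive-class level when inputs are not logical.
#' @return Object of class `confusion_table`: named list `tp`, `fp`,
#'   `fn`, `tn` with `as.matrix` support.
#' @examples
#' confusion_counts(tp = 4, fp = 2, fn = 1, tn = 11)
#' @export
confusion_from_labels <- function(predicted, truth, positive = NULL) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (anyNA(predicted) || anyNA(truth)) {
    stop("missing labels are not allowed", call. = FALSE)
  }
  to_logical <- function(x) {
    if (is.logical(x)) return(x)
    if (is.null(positive)) {
      stop("supply 'positive' for non-logical labels", call. = FALSE)
    }
    as.character(x) == positive
  }
  p <- to_logical(predicted)
  t <- to_logical(truth)
  confusion_counts(tp = sum(p & t), fp = sum(p & !t),
                   fn = sum(!p & t), tn = sum(!p & !t))
}

#' @rdname confusion_from_labels
#' @param tp,fp,fn,tn Cell counts.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("empty confusion table", call. = FALSE)
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "confusion_table")
}

#' @export
as.matrix.confusion_table <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
         dimnames = list(predicted = c("positive", "negative"),
                         truth = c("positive", "negative")))
}

#' @export
print.confusion_table <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

#' Concordance report for a binary prediction
#'
#' Computes the full accuracy battery from a 2x2 confusion table:
#' accuracy, sensitivity, specificity, PPV, NPV and balanced accuracy,
#' each proportion with its exact Clopper--Pearson interval; an exact
#' binomial test of the accuracy against a null proportion (default 0.5,
#' one-sided upper tail); Cohen's kappa; and the exact McNemar test on
#' the discordant cells (`b = fn`, `c = fp`). Degenerate denominators
#' (e.g. no true positives in the cohort) yield `NA` for the affected
#' metric rather than an error.
#'
#' @param x A `confusion_table` (from [confusion_counts()] or
#'   [confusion_from_labels()]).
#' @param level Confidence level for the exact intervals.
#' @param p_null Null proportion for the exact binomial test on accuracy.
#' @param alternative Sidedness of that test; see [exact_binomial_p()].
#' @return Object of class `concordance_report`: list with `counts`, and
#'   a `metrics` data frame (metric, k, n, estimate, lower, upper), plus
#'   `accuracy_p`, `kappa`, `mcnemar_p`, `balanced_accuracy`.
#' @examples
#' concordance_report(confusion_counts(4, 2, 1, 11))
#' @export
concordance_report <- function(x, level = 0.95, p_null = 0.5,
                               alternative = "greater") {
  stopifnot(inherits(x, "confusion_table"))
  n <- x$tp + x$fp + x$fn + x$tn
  metric_row <- function(name, k, d) {
    if (d == 0) {
      return(data.frame(metric = name, k = NA_integer_, n = 0L,
                        estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_))
    }
    ci <- clopper_pearson_ci(k, d, level)
    data.frame(metric = name, k = as.integer(k), n = as.integer(d),
               estimate = k / d, lower = ci[["lower"]],
               upper = ci[["upper"]])
  }
  metrics <- rbind(
    metric_row("accuracy", x$tp + x$tn, n),
    metric_row("sensitivity", x$tp, x$tp + x$fn),
    metric_row("specificity", x$tn, x$tn + x$fp),
    metric_row("ppv", x$tp, x$tp + x$fp),
    metric_row("npv", x$tn, x$tn + x$fn))
  rownames(metrics) <- metrics$metric
  sens <- metrics["sensitivity", "estimate"]
  spec <- metrics["specificity", "estimate"]
  structure(
    list(counts = x,
         n = as.integer(n),
         metrics = metrics,
         balanced_accuracy = (sens + spec) / 2,
         accuracy_p = exact_binomial_p(x$tp + x$tn, n, p_null,
                                       alternative = alternative),
         kappa = cohens_kappa(as.matrix(x)),
         mcnemar_b = x$fn, mcnemar_c = x$fp,
         mcnemar_p = exact_mcnemar(x$fn, x$fp),
         level = level),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, digits = 1, ...) {
  pct <- function(p) ifelse(is.na(p), "NA",
                            formatC(100 * p, format = "f", digits = digits))
  m <- x$metrics
  cat(sprintf("Concordance over n = %d (positive class = adverse outcome)\n",
              x$n))
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %s%% (%d/%d; %d%% CI %s-%s)\n", m$metric[i],
                pct(m$estimate[i]), m$k[i], m$n[i],
                round(100 * x$level), pct(m$lower[i]), pct(m$upper[i])))
  }
  cat(sprintf("  %-12s %s%%\n", "balanced", pct(x$balanced_accuracy)))
  cat(sprintf("  exact binomial P = %.3f; Cohen's kappa = %.3f\n",
              x$accuracy_p, x$kappa))
  cat(sprintf("  exact McNemar P = %.3f (discordant b = %d, c = %d)\n",
              x$mcnemar_p, x$mcnemar_b, x$mcnemar_c))
  invisible(x)
}

#' @export
as.data.frame.concordance_report <- function(x, ...) {
  out <- x$metrics
  out$accuracy_p <- x$accuracy_p
  out$kappa <- x$kappa
  out$mcnemar_p <- x$mcnemar_p
  out$balanced_accuracy <- x$balanced_accuracy
  rownames(out) <- NULL
  out
}

#' Paired-correctness comparison of two prediction methods
#'
#' When two methods predict the same ground truth on the same patients,
#' their per-patient correctness indicators form a paired 2x2 table:
#' both correct, only method 1 correct, only method 2 correct, both
#' wrong. The exact McNemar test on the two "only" cells asks whether one
#' method is systematically more often correct.
#'
#' @param correct1,correct2 Logical vectors of per-subject correctness of
#'   the two methods, equal length.
#' @return Object of class `paired_correctness`: counts and
#'   `exact_mcnemar_p`.
#' @examples
#' paired_correctness_mcnemar(c(TRUE, TRUE, TRUE, FALSE),
#'                            c(TRUE, FALSE, FALSE, FALSE))
#' @export
paired_correctness_mcnemar <- function(correct1, correct2) {
  if (length(correct1) != length(correct2)) {
    stop("correctness vectors must have equal length", call. = FALSE)
  }
  c1 <- as.logical(correct1); c2 <- as.logical(correct2)
  if (anyNA(c1) || anyNA(c2)) stop("missing correctness flags",
                                   call. = FALSE)
  res <- list(both_correct = sum(c1 & c2),
              only_method1_correct = sum(c1 & !c2),
              only_method2_correct = sum(!c1 & c2),
              both_wrong = sum(!c1 & !c2))
  res$exact_mcnemar_p <- exact_mcnemar(res$only_method1_correct,
                                       res$only_method2_correct)
  structure(res, class = "paired_correctness")
}

#' @export
print.paired_correctness <- function(x, ...) {
  cat(sprintf(paste0("Paired correctness: both %d, only method1 %d, ",
                     "only method2 %d, neither %d\n"),
              x$both_correct, x$only_method1_correct,
              x$only_method2_correct, x$both_wrong))
  cat(sprintf("  exact McNemar P = %.4g\n", x$exact_mcnemar_p))
  invisible(x)
}

#' Tie-aware rank correlations for paired deltas
#'
#' Spearman's rho (average ranks for ties) and Kendall's tau-b (tie
#' corrected) between two paired series, e.g. per-patient changes in CIWS
#' versus changes in the RECIST ordinal coding. For n <= `exact_n` pairs
#' the p-values are exact, from exhaustive enumeration of all
#' permutations (two-sided); beyond that the usual asymptotic
#' approximations are used.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param exact_n Largest n for which exhaustive permutation p-values are
#'   computed (default 10; enumeration is factorial in n).
#' @return Object of class `rank_correlations`: `spearman_rho`,
#'   `spearman_p`, `kendall_tau_b`, `kendall_p`, `n`, `p_method`.
#' @examples
#' rank_correlations(c(-2, 0, 1, 3), c(-1, 0, 0, 2))
#' @export
rank_correlations <- function(x, y, exact_n = 10) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired deltas",
                                 call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("rank correlation undefined for a constant vector",
         call. = FALSE)
  }
  rho <- cor(x, y, method = "spearman")
  tau <- cor(x, y, method = "kendall")
  if (n <= exact_n) {
    p <- .perm_rank_pvalues(rank(x), rank(y), as.numeric(x),
                            as.numeric(y))
    sp_p <- p[["spearman_p"]]; kd_p <- p[["kendall_p"]]
    method <- "exact permutation"
  } else {
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    kd <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    sp_p <- sp$p.value; kd_p <- kd$p.value
    method <- "asymptotic"
  }
  structure(list(spearman_rho = rho, spearman_p = sp_p,
                 kendall_tau_b = tau, kendall_p = kd_p,
                 n = n, p_method = method),
            class = "rank_correlations")
}

#' @export
print.rank_correlations <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (P = %.3f); Kendall tau-b = %.3f (P = %.3f)\n",
              x$spearman_rho, x$spearman_p, x$kendall_tau_b, x$kendall_p))
  cat(sprintf("  n = %d pairs, %s p-values\n", x$n, x$p_method))
  invisible(x)
}

#' Three-level directional concordance
#'
#' Agreement between two improved/stable/worsened direction labellings of
#' the same paired series (e.g. CIWS direction vs RECIST direction):
#' raw agreement fraction plus unweighted 3x3 Cohen's kappa.
#'
#' @param dir1,dir2 Factors/characters with values in `IMPROVED`,
#'   `STABLE`, `WORSENED` (as produced by [direction_class()]).
#' @return List with `agreement`, `kappa`, `table` (3x3 counts), `n`.
#' @export
directional_concordance <- function(dir1, dir2) {
  lv <- c("IMPROVED", "STABLE", "WORSENED")
  f1 <- factor(as.character(dir1), levels = lv)
  f2 <- factor(as.character(dir2), levels = lv)
  if (length(f1) != length(f2)) stop("label vectors must have equal length",
                                     call. = FALSE)
  if (anyNA(f1) || anyNA(f2)) stop("invalid direction label", call. = FALSE)
  tab <- table(f1, f2)
  list(agreement = sum(diag(tab)) / sum(tab),
       kappa = cohens_kappa(tab),
       table = tab,
       n = length(f1))
}
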