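# Survival-optimal dichotomization over restricted midpoints -------------

#' Configuration for restricted-midpoint cutpoint selection
#'
#' Defaults mirror the selection procedure used to dichotomize the CIWS:
#' candidate cutoffs restricted to the ordinal midpoints 3.5, 4.5 and
#' 5.5, a minimum group proportion of 0.25 on each side of any admissible
#' split, and 1000 bootstrap resamples for stability assessment.
#'
#' @param candidates Strictly increasing numeric midpoints.
#' @param minprop Minimum fraction of subjects required on each side of a
#'   candidate split, in (0, 0.5\].
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @return Named list used by [maxstat_cutpoint()].
#' @export
cutpoint_config <- function(candidates = c(3.5, 4.5, 5.5),
                            minprop = 0.25, n_boot = 1000) {
  if (is.unsorted(candidates, strictly = TRUE)) {
    stop("candidates must be strictly increasing", call. = FALSE)
  }
  if (minprop <= 0 || minprop > 0.5) {
    stop("minprop must lie in (0, 0.5]", call. = FALSE)
  }
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  list(candidates = candidates, minprop = minprop,
       n_boot = as.integer(n_boot))
}

# per-candidate log-rank table; the selection core shared by the fit and
# the bootstrap
.candidate_table <- function(scores, time, event, candidates, minprop) {
  n <- length(scores)
  need <- ceiling(minprop * n)
  rows <- lapply(candidates, function(cand) {
    high <- scores > cand
    n_high <- sum(high); n_low <- n - n_high
    valid <- min(n_high, n_low) >= need
    if (valid) {
      lr <- logrank_test(time, event, high)
      data.frame(cutoff = cand, n_low = n_low, n_high = n_high,
                 valid = TRUE, statistic = lr$statistic,
                 p_unadjusted = lr$p.value)
    } else {
      data.frame(cutoff = cand, n_low = n_low, n_high = n_high,
                 valid = FALSE, statistic = NA_real_,
                 p_unadjusted = NA_real_)
    }
  })
  do.call(rbind, rows)
}

.select_best <- function(tab, tol = 1e-8) {
  ok <- tab$valid
  if (!any(ok)) return(NA_real_)
  stats <- tab$statistic[ok]
  cands <- tab$cutoff[ok]
  best <- max(stats)
  # ties broken to the lowest candidate (largest "high-score" group)
  cands[which(stats >= best - tol)[1]]
}

#' Survival-optimal cutpoint by maximally selected rank statistics
#'
#' Dichotomizes an ordinal score against a survival endpoint: each
#' candidate midpoint splits subjects into score <= c versus > c,
#' candidates leaving fewer than `ceiling(minprop * n)` subjects on
#' either side are inadmissible, and among admissible candidates the one
#' maximizing the two-group log-rank statistic is selected (ties broken
#' to the lowest candidate, which favors the larger sensitive group).
#' Per-candidate p-values are plain log-rank tail probabilities,
#' unadjusted for the selection. Stability is assessed by resampling
#' subjects with replacement and recording how often each candidate wins;
#' resamples in which a candidate loses admissibility simply skip it, and
#' resamples with no admissible candidate are tallied in the `none`
#' bucket.
#'
#' @param scores Ordinal score per subject (e.g. CIWS).
#' @param time,event Survival endpoint aligned with `scores`.
#' @param config List from [cutpoint_config()].
#' @param endpoint Label carried into the result (`"DFS"` or `"OS"`).
#' @param seed Integer seed making the bootstrap reproducible; `NULL`
#'   leaves the RNG state alone.
#' @param bootstrap Set `FALSE` to skip the stability assessment.
#' @return Object of class `maxstat_cutpoint`: `best_cutoff`, `table`
#'   (per-candidate statistics), `selection_frequency` (per candidate
#'   plus `none`), `endpoint`, `n`, `config`.
#' @examples
#' set.seed(7)
#' sc <- rep(c(3, 6), each = 15)
#' t <- rexp(30, ifelse(sc > 4.5, 0.02, 0.2))
#' maxstat_cutpoint(sc, pmin(t, 60), t < 60, seed = 1,
#'                  config = cutpoint_config(n_boot = 50))
#' @export
maxstat_cutpoint <- function(scores, time, event,
                             config = cutpoint_config(),
                             endpoint = c("DFS", "OS"), seed = NULL,
                             bootstrap = TRUE) {
  endpoint <- match.arg(endpoint)
  event <- .check_surv(time, event)
  if (length(scores) != length(time)) {
    stop("scores and survival records must be aligned", call. = FALSE)
  }
  if (length(scores) < 2) stop("need at least 2 subjects", call. = FALSE)
  tab <- .candidate_table(scores, time, event, config$candidates,
                          config$minprop)
  best <- .select_best(tab)
  if (is.na(best)) {
    stop("no admissible cutpoint: every candidate split violates minprop",
         call. = FALSE)
  }
  freq <- NULL
  if (bootstrap) {
    freq <- bootstrap_stability(scores, time, event, config, seed = seed)
  }
  structure(list(best_cutoff = best, table = tab,
                 selection_frequency = freq, endpoint = endpoint,
                 n = length(scores), config = config),
            class = "maxstat_cutpoint")
}

#' Bootstrap stability of the cutpoint selection
#'
#' Resamples subjects with replacement `config$n_boot` times, reruns the
#' restricted-candidate selection on each resample, and reports the
#' fraction of resamples in which each candidate was selected. The
#' `none` entry counts resamples where no candidate was admissible (or
#' the log-rank test was degenerate); frequencies therefore sum to 1.
#'
#' @inheritParams maxstat_cutpoint
#' @return Named numeric vector of selection fractions (candidates plus
#'   `none`).
#' @export
bootstrap_stability <- function(scores, time, event,
                                config = cutpoint_config(), seed = NULL) {
  event <- .check_surv(time, event)
  n <- length(scores)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  picks <- vapply(seq_len(config$n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      tab <- .candidate_table(scores[idx], time[idx], event[idx],
                              config$candidates, config$minprop)
      .select_best(tab)
    }, error = function(e) NA_real_)
    res
  }, numeric(1))
  labels <- c(as.character(config$candidates), "none")
  counts <- setNames(numeric(length(labels)), labels)
  for (p in picks) {
    key <- if (is.na(p)) "none" else as.character(p)
    counts[key] <- counts[key] + 1
  }
  counts / config$n_boot
}

#' @export
print.maxstat_cutpoint <- function(x, ...) {
  cat(sprintf("Survival-optimal cutpoint (%s, n = %d): %.1f\n",
              x$endpoint, x$n, x$best_cutoff))
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$selection_frequency)) {
    cat(sprintf("bootstrap selection frequency (B = %d):\n",
                x$config$n_boot))
    print(round(x$selection_frequency, 3))
  }
  cat("note: per-candidate p-values are unadjusted for selection\n")
  invisible(x)
}

#' @export
summary.maxstat_cutpoint <- function(object, ...) {
  object
}

#' @export
plot.maxstat_cutpoint <- function(x, ...) {
  tab <- x$table
  plot(tab$cutoff, tab$statistic, type = "b", pch = 19,
       xlab = "candidate cutoff", ylab = "log-rank chi-square", ...)
  graphics::abline(v = x$best_cutoff, lty = 2)
  invisible(x)
}
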