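# Exact small-sample statistics ------------------------------------------

.check_kn <- function(k, n) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n)) {
    stop("need integer counts with 0 <= k <= n and n >= 1", call. = FALSE)
  }
}

#' Exact (Clopper--Pearson) binomial confidence interval
#'
#' Beta-quantile interval for a binomial proportion: lower bound
#' `qbeta(alpha/2, k, n-k+1)` (0 when k = 0), upper bound
#' `qbeta(1-alpha/2, k+1, n-k)` (1 when k = n). Guarantees at least
#' nominal coverage at every true proportion, which matters at the cohort
#' sizes typical of organoid validation studies (n of 13--18).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` on the \[0, 1\] scale.
#' @examples
#' clopper_pearson_ci(15, 18)  # 0.586, 0.964
#' @export
clopper_pearson_ci <- function(k, n, level = 0.95) {
  .check_kn(k, n)
  stopifnot(level > 0, level < 1)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Exact binomial test p-value
#'
#' Tests an observed success count against a null proportion. The default
#' is the one-sided upper tail, `P(X >= k | n, p0)` -- the form under
#' which an accuracy of 15/18 against p0 = 0.5 gives p = 0.0038. The
#' two-sided option doubles the smaller tail and caps at 1.
#'
#' @param k,n Successes and trials.
#' @param p0 Null proportion (default 0.5).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return p-value.
#' @examples
#' exact_binomial_p(15, 18)  # 0.0038
#' exact_binomial_p(11, 13)  # 0.0112
#' @export
exact_binomial_p <- function(k, n, p0 = 0.5,
                             alternative = c("greater", "less",
                                             "two.sided")) {
  .check_kn(k, n)
  stopifnot(p0 >= 0, p0 <= 1)
  alternative <- match.arg(alternative)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  lower <- pbinom(k, n, p0)
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(lower, upper)))
}

#' Exact McNemar test on discordant pairs
#'
#' Two-sided exact binomial test of the discordant-pair counts of a paired
#' binary comparison: with `b + c` discordant pairs, under no systematic
#' bias `b ~ Binomial(b + c, 1/2)`; the p-value doubles the smaller tail,
#' `min(1, 2 min(P(X <= b), P(X >= b)))`, and equals 1 when there is no
#' discordance. Symmetric in `b` and `c`.
#'
#' @param b,c Discordant-pair counts (e.g. b = false negatives, c = false
#'   positives of a 2x2 prediction table).
#' @return p-value in (0, 1\].
#' @examples
#' exact_mcnemar(1, 2)  # 1.000
#' exact_mcnemar(2, 0)  # 0.50
#' @export
exact_mcnemar <- function(b, c) {
  if (length(b) != 1 || length(c) != 1 || is.na(b) || is.na(c) ||
      b < 0 || c < 0 || b != round(b) || c != round(c)) {
    stop("b and c must be single non-negative integers", call. = FALSE)
  }
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * min(pbinom(b, n, 0.5),
                 pbinom(b - 1, n, 0.5, lower.tail = FALSE)))
}

#' Cohen's kappa for a square agreement table
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)` with expected
#' agreement from the marginal products, for any k x k contingency table
#' of two raters/classifiers over the same categories (unweighted). When
#' the marginals force Pe = 1, kappa is 1 if observed agreement is also
#' perfect and undefined (error) otherwise.
#'
#' @param tab Square numeric matrix of cross-classified counts, rows =
#'   method 1, columns = method 2 over identical category order.
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohens_kappa(matrix(c(4, 2, 1, 11), 2, 2, byrow = TRUE))  # 0.609
#' @export
cohens_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("tab must be square", call. = FALSE)
  if (any(tab < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- sum(tab)
  if (n < 1) stop("empty table", call. = FALSE)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1 - sqrt(.Machine$double.eps)) {
    if (po >= 1 - sqrt(.Machine$double.eps)) return(1)
    stop("kappa undefined: chance agreement is 1 with imperfect ",
         "observed agreement", call. = FALSE)
  }
  (po - pe) / (1 - pe)
}
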