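# Independent first-principles oracles used across the suite. These stay
# deliberately naive: risk-set tables enumerated time by time, binomial
# tails summed term by term, permutations enumerated recursively.

# two-group log-rank chi-square from explicit risk-set tables
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  ev_times <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    OmE <- OmE + (d1 - d * n1 / n)
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  (OmE^2) / V
}

# product-limit estimator by hand
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out$surv[i] <- s
  }
  out
}

# binomial tail by explicit pmf summation
oracle_binom_tail_ge <- function(k, n, p) {
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}
oracle_binom_tail_le <- function(k, n, p) {
  sum(vapply(0:k, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}
oracle_mcnemar <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * min(oracle_binom_tail_le(b, n, 0.5),
                 oracle_binom_tail_ge(b, n, 0.5)))
}

# all permutations of 1..n (recursive; fine for n <= 7)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

oracle_perm_pvalues <- function(x, y) {
  n <- length(x)
  perms <- oracle_perms(n)
  rho_obs <- cor(x, y, method = "spearman")
  tau_obs <- cor(x, y, method = "kendall")
  rho_all <- apply(perms, 1, function(p) cor(x[p], y, method = "spearman"))
  tau_all <- apply(perms, 1, function(p) cor(x[p], y, method = "kendall"))
  c(spearman_p = mean(abs(rho_all) >= abs(rho_obs) - 1e-12),
    kendall_p = mean(abs(tau_all) >= abs(tau_obs) - 1e-12))
}

# small random survival dataset for property loops
random_surv <- function(n, two_groups = TRUE) {
  list(time = round(rexp(n, 0.1), 2) + 0.1,
       event = rbinom(n, 1, 0.75),
       group = if (two_groups) {
         g <- rep_len(c(0, 1), n)
         sample(g)
       })
}
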