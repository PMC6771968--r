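# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# term-by-term sample estimators of DN1/DN2/DS1/DS2 and indirect EV
oracle_binary <- function(p, p_bar) {
  s1 <- s2 <- n_less <- 0
  t1 <- t2 <- n_greater <- 0
  inacc <- 0
  for (pi in p) {
    if (pi < p_bar) {
      k <- (p_bar - pi) / p_bar
      s1 <- s1 + k^2; s2 <- s2 + k; n_less <- n_less + 1
    } else if (pi > p_bar) {
      k <- (pi - p_bar) / (1 - p_bar)
      t1 <- t1 + k^2; t2 <- t2 + k; n_greater <- n_greater + 1
    }
    inacc <- inacc + pi * (1 - pi)
  }
  list(dn1 = if (n_less) sqrt(s1 / n_less) else 0,
       dn2 = if (n_less) s2 / n_less else 0,
       ds1 = if (n_greater) sqrt(t1 / n_greater) else 0,
       ds2 = if (n_greater) t2 / n_greater else 0,
       ev = 1 - (inacc / length(p)) / (p_bar * (1 - p_bar)),
       n_less = n_less, n_greater = n_greater)
}

# textbook product-limit estimate, evaluated at the distinct event times
oracle_km <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  S <- 1
  out <- numeric(length(ut))
  for (j in seq_along(ut)) {
    at_risk <- sum(time >= ut[j])
    d <- sum(time == ut[j] & status == 1)
    S <- S * (1 - d / at_risk)
    out[j] <- 1 - S
  }
  list(event_times = ut, F = out)
}

# double-loop mean absolute predictive inaccuracy ratio
# S_cond: n x m matrix of per-subject conditional survival at event times
oracle_sh_ev <- function(time, status, event_times, S_unc, S_cond, G_inv, d) {
  m <- length(event_times)
  n <- length(time)
  contrib <- function(ti, si, S, j) {
    tj <- event_times[j]
    if (ti > tj) return(1 - S[j])
    if (si == 1) return(S[j])
    # censored at ti <= tj: split by the chance of still being alive at tj
    Si <- 1
    for (k in seq_len(m)) if (event_times[k] <= ti) Si <- S[k]
    (S[j] / Si) * (1 - S[j]) + (1 - S[j] / Si) * S[j]
  }
  M <- Mx <- numeric(m)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      M[j] <- M[j] + contrib(time[i], status[i], S_unc, j) / n
      Mx[j] <- Mx[j] + contrib(time[i], status[i], S_cond[i, ], j) / n
    }
  }
  w <- G_inv * d
  1 - sum(w * Mx) / sum(w * M)
}

# random calibrated probability vector (baseline = mean by construction)
random_probs <- function(n) stats::rbeta(n, 0.8, 1.6)

# random nondegenerate 2x2 count table
random_table <- function() {
  repeat {
    cnt <- stats::rmultinom(1, 60, stats::runif(4, 0.05, 1))[, 1]
    ok <- all(c(cnt[1] + cnt[2], cnt[3] + cnt[4],
                cnt[1] + cnt[3], cnt[2] + cnt[4]) > 0)
    if (ok) return(two_by_two(cnt[1], cnt[2], cnt[3], cnt[4]))
  }
}

# absolute-tolerance expectation (printed reference values carry absolute
# rounding, so relative comparison is the wrong scale for them)
expect_within <- function(actual, expected, tol, label = "value") {
  testthat::expect_true(
    all(abs(actual - expected) <= tol),
    info = sprintf("%s: got %s, want %s +- %g", label,
                   paste(signif(actual, 6), collapse = ", "),
                   paste(expected, collapse = ", "), tol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
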