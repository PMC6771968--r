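test_that("km_cdf matches textbook product-limit arithmetic", {
  expect_equal(km_cdf(c(1, 2, 3), c(1, 1, 1))$F, c(1, 2, 3) / 3)
  # censoring at 2 inflates the final step: S(3) = (2/3) * (1 - 1/1) = 0
  km <- km_cdf(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$event_times, c(1, 3))
  expect_equal(km$F, c(1 / 3, 1))
  set.seed(51)
  for (rep in 1:5) {
    tm <- rexp(40); st <- rbinom(40, 1, 0.7)
    if (sum(st) == 0) next
    got <- km_cdf(tm, st)
    want <- oracle_km(tm, st)
    expect_equal(got$event_times, want$event_times)
    expect_equal(got$F, want$F, tolerance = 1e-12)
  }
  # large-sample consistency against the true exponential CDF
  tm <- rexp(10000)
  km <- km_cdf(tm, rep(1, 10000))
  expect_lt(max(abs(km$F - pexp(km$event_times))), 0.02)
  expect_error(km_cdf(c(1, 2), c(0, 0)), "no events")
  expect_error(km_cdf(c(-1, 2), c(1, 1)), "positive")
})

test_that("reverse-KM weights use left limits and equal 1 without censoring", {
  w <- censoring_weights(c(1, 2, 3), c(1, 1, 1), eval_times = c(1, 2, 3))
  expect_equal(w$weights, c(1, 1, 1))
  # censoring at 2 halves G before t = 3
  w <- censoring_weights(c(1, 2, 3), c(1, 0, 1), eval_times = c(1, 3))
  expect_equal(w$G, c(1, 1 / 2))
  expect_equal(w$weights, c(1, 2))
  # a censoring tied to an event time must not affect that time's weight
  w <- censoring_weights(c(1, 2, 2, 3), c(1, 1, 0, 1), eval_times = c(2, 3))
  expect_equal(w$weights[1], 1)
  expect_true(all(w$weights >= 1) && all(is.finite(w$weights)))
})

test_that("per-time measures reduce to the dichotomous kernels", {
  at <- dn_ds_at_time(0.4, c(0.2, 0.6))
  expect_equal(at$dn1, 0.5)
  expect_equal(at$dn2, 0.5)
  expect_equal(at$ds1, 1 / 3)
  expect_equal(at$ds2, 1 / 3)
  expect_equal(c(at$n_less, at$n_greater), c(1, 1))
  # profile counts weight the kernels like repeated subjects
  expect_equal(dn_ds_at_time(0.4, c(0.2, 0.6), counts = c(30, 70)),
               dn_ds_at_time(0.4, c(rep(0.2, 30), rep(0.6, 70))))
  none <- dn_ds_at_time(0.5, rep(0.5, 4))
  expect_equal(unlist(none), c(dn1 = 0, dn2 = 0, ds1 = 0, ds2 = 0,
                               n_less = 0, n_greater = 0))
  expect_error(dn_ds_at_time(1, c(0.2, 0.6)), "degenerate time")
  # the population two-group kernels at a fixed time
  hr <- 10; alpha <- 0.5; t <- 1
  Fh <- pexp(t, 1); Fp <- pexp(t, 1 / hr)
  Fm <- alpha * Fh + (1 - alpha) * Fp
  at <- dn_ds_at_time(Fm, c(Fp, Fh), counts = c(1 - alpha, alpha))
  expect_equal(at$dn1, (Fm - Fp) / Fm)
  expect_equal(at$ds1, (Fh - Fm) / (1 - Fm))
})

test_that("conditional curves equal to the unconditional one give zero measures", {
  d <- gen_exp_survival(200, hr = 5, alpha = 0.5, seed = 52)
  km <- km_cdf(d$time, d$status)
  cur <- survival_curves(d$time, d$status,
                         matrix(km$F, 1, byrow = TRUE),
                         profile = rep(1L, nrow(d)))
  m <- dn_ds(cur)
  expect_equal(unlist(m[c("dn1", "dn2", "ds1", "ds2")]),
               c(dn1 = 0, dn2 = 0, ds1 = 0, ds2 = 0))
  expect_equal(as.numeric(sh_ev(cur)), 0)
})

test_that("estimates are bit-invariant under monotone time transformation", {
  d <- gen_exp_survival(400, hr = 8, alpha = 0.4,
                        censoring = "administrative", tau = 5, seed = 53)
  m1 <- dn_ds(cox_curves(d$time, d$status, d$group, method = "km"))
  m2 <- dn_ds(cox_curves(d$time^3, d$status, d$group, method = "km"))
  for (k in c("dn1", "dn2", "ds1", "ds2", "ev", "alpha"))
    expect_identical(m1[[k]], m2[[k]], label = k)
})

test_that("both variants coincide for a dichotomous factor", {
  d <- gen_exp_survival(500, hr = 6, alpha = 0.3,
                        censoring = "type1", tau = 4, seed = 54)
  m <- dn_ds(cox_curves(d$time, d$status, d$group, method = "km"))
  expect_equal(m$dn1, m$dn2, tolerance = 1e-12)
  expect_equal(m$ds1, m$ds2, tolerance = 1e-12)
  tt <- attr(m, "times")
  expect_true(all(c("time", "d", "weight", "dn1_t", "ds1_t",
                    "n_less", "n_greater") %in% names(tt)))
})

test_that("explained variation matches a double-loop inaccuracy oracle", {
  set.seed(55)
  for (rep in 1:3) {
    d <- gen_exp_survival(60, hr = 6, alpha = 0.5,
                          censoring = "administrative", tau = 6)
    cur <- cox_curves(d$time, d$status, d$group, method = "km")
    js <- seq_along(cur$event_times)
    S_cond <- 1 - cur$F_cond[cur$profile, , drop = FALSE]
    want <- oracle_sh_ev(d$time, d$status, cur$event_times,
                         1 - cur$F_uncond, S_cond, cur$G_inv, cur$d)
    expect_equal(as.numeric(sh_ev(cur)), max(want, 0), tolerance = 1e-10)
  }
})

test_that("Cox and stratified-KM conditional curves agree for one factor", {
  d <- gen_exp_survival(5000, hr = 6, alpha = 0.5,
                        censoring = "administrative", tau = 8, seed = 56)
  mk <- dn_ds(cox_curves(d$time, d$status, d$group, method = "km"))
  mc <- dn_ds(cox_curves(d$time, d$status, d$group, method = "cox"))
  expect_equal(mk$dn1, mc$dn1, tolerance = 0.02)
  expect_equal(mk$ds1, mc$ds1, tolerance = 0.02)
  expect_equal(mk$ev, mc$ev, tolerance = 0.02)
})

test_that("a permuted covariate yields near-null measures", {
  d <- gen_exp_survival(2000, hr = 8, alpha = 0.5, seed = 57)
  set.seed(58)
  m <- dn_ds(cox_curves(d$time, d$status, sample(d$group), method = "km"))
  expect_lt(m$dn1, 0.1)
  expect_lt(m$ds1, 0.1)
})

test_that("zero-coefficient conditional curves reproduce the trivial case", {
  d <- gen_exp_survival(150, hr = 4, alpha = 0.5, seed = 59)
  km <- km_cdf(d$time, d$status)
  cur <- survival_curves(d$time, d$status,
                         rbind(km$F, km$F), profile = d$group + 1L)
  m <- dn_ds(cur)
  expect_equal(m$dn1 + m$ds1, 0)
})

test_that("the curve container validates its invariants", {
  d <- gen_exp_survival(50, hr = 4, alpha = 0.5, seed = 60)
  km <- km_cdf(d$time, d$status)
  bad <- matrix(rev(km$F), 1)
  expect_error(survival_curves(d$time, d$status, bad,
                               profile = rep(1L, 50)), "nondecreasing")
  expect_error(survival_curves(d$time, d$status,
                               matrix(km$F, 1), profile = rep(5L, 50)),
               "profile")
  expect_error(dn_ds(cox_curves(d$time, d$status, d$group, method = "km"),
                     tau = min(d$time) / 2), "estimation impossible")
})
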