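test_that("sample estimators agree with a term-by-term oracle", {
  set.seed(101)
  for (rep in 1:10) {
    p <- runif(50)
    got <- dn_ds(p, p_bar = 0.5)
    want <- oracle_binary(p, 0.5)
    for (k in c("dn1", "dn2", "ds1", "ds2", "ev", "n_less", "n_greater"))
      expect_equal(got[[k]], want[[k]], tolerance = 1e-12, label = k)
  }
})

test_that("two-group smoking probabilities reproduce the cohort measures", {
  probs <- c(rep(36 / 8156, 8156), rep(177 / 4508, 4508))
  m <- dn_ds(probs, p_bar = 213 / 12664)
  expect_within(m$dn1, 0.738, tol = 5e-4)
  expect_equal(m$dn2, m$dn1, tolerance = 1e-12)
  expect_within(m$ds1, 0.023, tol = 5e-4)
  expect_within(m$ev, 0.017, tol = 5e-4)
  expect_equal(m$alpha, 4508 / 12664)
})

test_that("noninformative predictions give zero measures and empty sets", {
  m <- dn_ds(rep(0.3, 20), p_bar = 0.3)
  expect_equal(unlist(m[c("dn1", "dn2", "ds1", "ds2", "ev")]),
               c(dn1 = 0, dn2 = 0, ds1 = 0, ds2 = 0, ev = 0))
  expect_equal(m$n_less, 0)
  expect_equal(m$n_greater, 0)
  # one-sided input: the empty informative side stays 0
  one_sided <- dn_ds(c(0.1, 0.2), p_bar = 0.5)
  expect_gt(one_sided$dn1, 0)
  expect_equal(one_sided$ds1, 0)
})

test_that("invalid baselines and probabilities are rejected", {
  expect_error(dn_ds(c(0.2, 0.4), p_bar = 0), "invalid baseline")
  expect_error(dn_ds(c(0.2, 0.4), p_bar = 1), "invalid baseline")
  expect_error(dn_ds(c(-0.1, 0.4), p_bar = 0.5), "invalid probability")
  expect_error(dn_ds(c(0.2, 1.4), p_bar = 0.5), "invalid probability")
  expect_error(dn_ds(numeric(0)), "at least one subject")
  expect_error(dn_ds(c(0.2, 0.4), outcomes = c(1, 0, 1)), "same length")
})

test_that("baseline defaults to the outcome mean, else the prediction mean", {
  p <- c(0.1, 0.2, 0.6)
  y <- c(0, 1, 1)
  expect_equal(dn_ds(p, outcomes = y)$p_bar, mean(y))
  expect_equal(dn_ds(p)$p_bar, mean(p))
})

test_that("indirect and squared-deviation EV coincide exactly when calibrated", {
  set.seed(7)
  p <- random_probs(200)
  pb <- mean(p)
  expect_equal(dn_ds(p, p_bar = pb, ev = "indirect")$ev,
               dn_ds(p, p_bar = pb, ev = "deviation")$ev, tolerance = 1e-12)
})

test_that("EV decomposition matches the printed scenario and the identity", {
  expect_within(ev_decomposition(0.346, 0.346, alpha = 0.1, p_bar = 0.1),
                0.120, tol = 5e-4)
  expect_equal(ev_decomposition(0, 0, 0.3, 0.4), 0)
  expect_error(ev_decomposition(0.5, 0.5, 0.5, 1), "invalid baseline")
  # exact identity with the squared-deviation EV under calibration
  set.seed(11)
  for (rep in 1:5) {
    p <- random_probs(150)
    m <- dn_ds(p, p_bar = mean(p), ev = "deviation")
    expect_equal(ev_decomposition(m$dn1, m$ds1, m$alpha, m$p_bar), m$ev,
                 tolerance = 1e-12)
  }
})

test_that("partial measures vanish for identical models and track the true factor", {
  set.seed(21)
  m <- dn_ds(random_probs(100), p_bar = 0.4)
  expect_equal(unname(partial_measures(m, m)), rep(0, 5))

  # x1 is the sole true predictor; x2 is pure noise
  b0 <- solve_intercept(log(10), 0.5)
  d <- gen_logistic_normal(6000, b0, log(10), seed = 22)
  d$x2 <- rnorm(nrow(d))
  full <- dn_ds(logistic_probs("y", c("x", "x2"))(d))
  red_noise <- dn_ds(logistic_probs("y", "x2")(d))
  marg_true <- dn_ds(logistic_probs("y", "x")(d))
  # adding pure noise to the true model changes little
  delta <- suppressWarnings(partial_measures(full, marg_true))
  expect_lt(max(abs(delta)), 0.05)
  # partial EV of the true factor over noise approaches its marginal EV
  part <- partial_measures(full, red_noise)
  expect_equal(part[["ev"]], marg_true$ev, tolerance = 0.05)
  expect_warning(partial_measures(red_noise, full), "negative partial")
})

test_that("Jensen bounds and ranges hold on randomized inputs", {
  set.seed(31)
  for (rep in 1:25) {
    p <- random_probs(40)
    m <- dn_ds(p, p_bar = runif(1, 0.1, 0.9))
    v <- unlist(m[c("dn1", "dn2", "ds1", "ds2")])
    expect_true(all(v >= 0 & v <= 1))
    expect_lte(m$dn2, m$dn1 + 1e-12)
    expect_gte(m$dn2, m$dn1^2 - 1e-12)
    expect_lte(m$ds2, m$ds1 + 1e-12)
    expect_gte(m$ds2, m$ds1^2 - 1e-12)
  }
})
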