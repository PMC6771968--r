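#' Joint cell probabilities of a 2x2 scenario
#'
#' Solves the joint distribution of a dichotomous factor and a dichotomous
#' outcome from its three-parameter description: unconditional event
#' probability `p_d`, probability `alpha` of the *harmful* level, and odds
#' ratio.  The harmful level is `X = 1` when `odds_ratio > 1` and `X = 0`
#' when `odds_ratio < 1`; the exposed-diseased cell solves a quadratic with a
#' unique admissible root.  `odds_ratio` of `Inf` or `0` yields the exact
#' structural-zero table.
#'
#' @param p_d unconditional event probability, in `(0, 1)`.
#' @param alpha probability of the harmful level, in `(0, 1)`.
#' @param odds_ratio odds ratio for the event, in `[0, Inf]`.
#' @return A [two_by_two()] table whose cells are probabilities summing to 1.
#' @examples
#' scenario_cells(0.1, 0.1, 10)
#' @export
scenario_cells <- function(p_d, alpha, odds_ratio) {
  stopifnot(p_d > 0, p_d < 1, alpha > 0, alpha < 1, odds_ratio >= 0)
  flip <- odds_ratio < 1
  or <- if (flip) 1 / odds_ratio else odds_ratio
  # with harmful level X = 1: margins c + d = p_d, b + d = alpha
  if (is.infinite(or)) {
    d <- min(p_d, alpha)   # structural zero in c (alpha >= p_d) or b
  } else if (or == 1) {
    d <- p_d * alpha
  } else {
    A <- 1 - or
    B <- (1 - p_d - alpha) + or * (p_d + alpha)
    C <- -or * p_d * alpha
    disc <- B^2 - 4 * A * C
    if (disc < 0) stop("infeasible scenario: no admissible joint distribution")
    roots <- (-B + c(1, -1) * sqrt(disc)) / (2 * A)
    ok <- roots >= -1e-12 & roots <= min(p_d, alpha) + 1e-12
    if (!any(ok)) stop("infeasible scenario: no admissible joint distribution")
    d <- min(max(roots[ok][1], 0), min(p_d, alpha))
  }
  cells <- c(a = 1 - p_d - alpha + d, b = alpha - d, c = p_d - d, d = d)
  if (any(cells < -1e-12))
    stop("infeasible scenario: no admissible joint distribution")
  cells <- pmax(cells, 0)
  if (flip) cells <- cells[c("b", "a", "d", "c")]
  two_by_two(cells[[1]], cells[[2]], cells[[3]], cells[[4]])
}

#' Population DN, DS and EV for a 2x2 scenario
#'
#' Inserts the population cell probabilities from [scenario_cells()] into the
#' dichotomous closed forms, so that `EV = DN * DS` holds exactly and the
#' measures are invariant under `odds_ratio -> 1 / odds_ratio`.
#'
#' @inheritParams scenario_cells
#' @return A `"necsuff"` object (see [dn_ds()]) computed on probabilities;
#'   its `n_less` / `n_greater` components are the marginal probabilities of
#'   the protective and harmful level.
#' @examples
#' pop_2x2(0.5, 0.5, 100)
#' @export
pop_2x2 <- function(p_d, alpha, odds_ratio) {
  dn_ds(scenario_cells(p_d, alpha, odds_ratio))
}

#' Intercept calibrating a logistic-normal scenario
#'
#' For `X ~ N(0, 1)` and `P(D | X) = plogis(beta0 + beta1 X)`, finds the
#' intercept such that the marginal event probability
#' `E_X P(D | X)` equals `p_d`, by bracketed root-finding on the Gaussian
#' integral.
#'
#' @param beta1 slope (log odds ratio per SD of X).
#' @param p_d target marginal event probability, in `(0, 1)`.
#' @param tol root-finding tolerance.
#' @return The intercept `beta0`.
#' @export
solve_intercept <- function(beta1, p_d, tol = 1e-10) {
  stopifnot(p_d > 0, p_d < 1, is.finite(beta1))
  marg <- function(b0)
    stats::integrate(function(x) stats::plogis(b0 + beta1 * x) * stats::dnorm(x),
                     -Inf, Inf, rel.tol = 1e-12)$value - p_d
  lo <- stats::qlogis(p_d) - abs(beta1) * 40 - 1
  hi <- stats::qlogis(p_d) + abs(beta1) * 40 + 1
  stats::uniroot(marg, c(lo, hi), tol = tol)$root
}

#' Population DN, DS and EV for a logistic-normal scenario
#'
#' Standard-normal factor `X`, logistic conditional event probability with
#' slope `beta1` (log odds ratio per SD) and intercept solved so the marginal
#' event probability equals `p_d`.  The threshold `x*` where
#' `P(D | x) = P(D)` splits the factor range into protective and harmful
#' sides; the conditional expectations defining the measures are evaluated by
#' adaptive quadrature of the kernels against the truncated normal density,
#' EV by the squared-deviation form (the model is calibrated by
#' construction, so the indirect form coincides).
#'
#' @param p_d marginal event probability, in `(0, 1)`.
#' @param beta1 slope; alternatively give `or_per_sd = exp(beta1)`.
#' @param or_per_sd odds ratio per standard deviation of X (used when
#'   `beta1` is missing).
#' @return A list with `dn1`, `dn2`, `ds1`, `ds2`, `ev`, `alpha`, `beta0`,
#'   `x_star` and `degenerate` (`TRUE` when `beta1 = 0`, where every measure
#'   is 0).
#' @examples
#' pop_logistic_normal(0.9, or_per_sd = 100)
#' @export
pop_logistic_normal <- function(p_d, beta1 = log(or_per_sd), or_per_sd = NULL) {
  stopifnot(is.finite(beta1))
  if (beta1 == 0)
    return(list(dn1 = 0, dn2 = 0, ds1 = 0, ds2 = 0, ev = 0, alpha = 0,
                beta0 = stats::qlogis(p_d), x_star = NA_real_,
                degenerate = TRUE))
  b0 <- solve_intercept(beta1, p_d)
  x_star <- (stats::qlogis(p_d) - b0) / beta1
  p <- function(x) stats::plogis(b0 + beta1 * x)
  # harmful side: where p(x) > p_d, ie, the side x_star faces along sign(beta1)
  up <- beta1 > 0
  mass_less <- if (up) stats::pnorm(x_star) else stats::pnorm(x_star, lower.tail = FALSE)
  alpha <- 1 - mass_less
  q <- function(f, lower, upper)
    stats::integrate(function(x) f(x) * stats::dnorm(x), lower, upper,
                     rel.tol = 1e-10, abs.tol = 1e-10)$value
  lim_less <- if (up) c(-Inf, x_star) else c(x_star, Inf)
  lim_more <- if (up) c(x_star, Inf) else c(-Inf, x_star)
  kn <- function(x) (p_d - p(x)) / p_d
  ks <- function(x) (p(x) - p_d) / (1 - p_d)
  list(
    dn1 = sqrt(q(function(x) kn(x)^2, lim_less[1], lim_less[2]) / mass_less),
    dn2 = q(kn, lim_less[1], lim_less[2]) / mass_less,
    ds1 = sqrt(q(function(x) ks(x)^2, lim_more[1], lim_more[2]) / alpha),
    ds2 = q(ks, lim_more[1], lim_more[2]) / alpha,
    ev = q(function(x) (p(x) - p_d)^2, -Inf, Inf) / (p_d * (1 - p_d)),
    alpha = alpha, beta0 = b0, x_star = x_star, degenerate = FALSE)
}

#' Population DN, DS and EV for a two-group exponential survival scenario
#'
#' Survival times are exponential with hazard 1 at the harmful factor level
#' (probability `alpha`) and hazard `1 / hr` at the protective level, so that
#' the printed censoring fractions of the follow-up designs are reproduced.
#' The time-averaged measures integrate the per-time kernels against the
#' marginal event density up to the horizon `tau` by adaptive quadrature:
#' `DN1(tau)` averages `(F(t) - F(t | protective)) / F(t)` and `DS1(tau)`
#' `(F(t | harmful) - F(t)) / (1 - F(t))` (for a dichotomous factor both
#' variants coincide).  EV is the population inaccuracy ratio
#' `1 - int E_X[F(t|X)(1 - F(t|X))] f dt / int F(t)(1 - F(t)) f dt`.
#'
#' Censoring affects only the reported censoring fraction, not the measures:
#' `"type1"` (all subjects followed exactly `tau`) censors `P(T > tau)`;
#' `"administrative"` (uniform entry over `(0, tau)`, analysis at `tau`)
#' censors `E[min(T, tau)] / tau`, which equals the average survival over the
#' follow-up window.  Population measures under either design equal the
#' uncensored values truncated at the same `tau`.
#'
#' @param hr hazard ratio of the harmful versus the protective level,
#'   `>= 1` (a value below 1 is re-oriented by swapping the levels).
#' @param alpha probability of the harmful level, in `(0, 1)`.
#' @param tau follow-up horizon, positive (may be `Inf`).
#' @param censoring one of `"none"`, `"type1"`, `"administrative"`.
#' @return A list with `dn1`, `dn2`, `ds1`, `ds2`, `ev`, `pct_censored`,
#'   `tau` and `censoring`.
#' @examples
#' pop_survival(10, 0.5, tau = 4.90, censoring = "type1")
#' @export
pop_survival <- function(hr, alpha, tau = Inf,
                         censoring = c("none", "type1", "administrative")) {
  censoring <- match.arg(censoring)
  stopifnot(alpha > 0, alpha < 1, hr > 0)
  if (!is.numeric(tau) || tau <= 0) stop("invalid horizon: tau must be positive")
  if (censoring != "none" && !is.finite(tau))
    stop("invalid horizon: censored designs need a finite tau")
  if (hr < 1) { hr <- 1 / hr; alpha <- 1 - alpha }
  Sh <- function(t) exp(-t)          # harmful level, hazard 1
  Sp <- function(t) exp(-t / hr)     # protective level, hazard 1/hr
  Sm <- function(t) alpha * Sh(t) + (1 - alpha) * Sp(t)
  f <- function(t) alpha * exp(-t) + (1 - alpha) * exp(-t / hr) / hr
  # kernels written in survival scale to stay finite in the far tail
  dn_t <- function(t) {
    gap <- -Sp(t) * expm1(-t * (1 - 1 / hr))            # Sp - Sh
    Fm <- -(alpha * expm1(-t) + (1 - alpha) * expm1(-t / hr))
    alpha * gap / Fm
  }
  ds_t <- function(t) {
    r <- exp(-t * (1 - 1 / hr))      # Sh / Sp, bounded in (0, 1]
    (1 - alpha) * (1 - r) / (alpha * r + 1 - alpha)
  }
  q <- function(g) stats::integrate(function(t) g(t) * f(t), 0, tau,
                                    rel.tol = 1e-10, abs.tol = 1e-8)$value
  den <- q(function(t) 1)
  if (hr == 1) {
    dn <- ds <- ev <- 0
  } else {
    dn <- q(dn_t) / den
    ds <- q(ds_t) / den
    num <- q(function(t) alpha * Sh(t) * (1 - Sh(t)) +
               (1 - alpha) * Sp(t) * (1 - Sp(t)))
    dlt <- q(function(t) Sm(t) * (1 - Sm(t)))
    ev <- 1 - num / dlt
  }
  pct <- switch(censoring,
    none = 0,
    type1 = 100 * Sm(tau),
    administrative = 100 *
      stats::integrate(Sm, 0, tau, rel.tol = 1e-10)$value / tau)
  list(dn1 = dn, dn2 = dn, ds1 = ds, ds2 = ds, ev = ev,
       pct_censored = pct, tau = tau, censoring = censoring)
}
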