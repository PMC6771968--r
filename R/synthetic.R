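#' Simulated binary data from a logistic-normal model
#'
#' Draws a standard-normal prognostic factor and a Bernoulli outcome with
#' logistic conditional probability `plogis(beta0 + beta1 * x)` — the design
#' used throughout the package's simulation studies for a continuous factor.
#'
#' @param n sample size.
#' @param beta0 intercept (see [solve_intercept()] to calibrate a marginal
#'   event probability).
#' @param beta1 slope (log odds ratio per SD of X).
#' @param seed optional integer seed; identical seeds give identical tables.
#' @return A data frame with columns `x`, `y` (0/1) and `prob` (the true
#'   conditional event probability).
#' @examples
#' head(gen_logistic_normal(5, beta0 = 0, beta1 = log(10), seed = 1))
#' @export
gen_logistic_normal <- function(n, beta0, beta1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  prob <- stats::plogis(beta0 + beta1 * x)
  data.frame(x = x, y = stats::rbinom(n, 1, prob), prob = prob)
}

#' Simulated 2x2 table from a scenario
#'
#' Multinomial draw of `n` subjects from the joint cell probabilities of a
#' 2x2 scenario (see [scenario_cells()]).
#'
#' @inheritParams scenario_cells
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return A [two_by_two()] table of counts.
#' @export
gen_2x2 <- function(n, p_d, alpha, odds_ratio, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- scenario_cells(p_d, alpha, odds_ratio)
  repeat {
    cnt <- stats::rmultinom(1, n, c(cells$a, cells$b, cells$c, cells$d))[, 1]
    # redraw the (rare) degenerate tables whose margins vanish
    if (all(c(cnt[1] + cnt[2], cnt[3] + cnt[4],
              cnt[1] + cnt[3], cnt[2] + cnt[4]) > 0)) break
  }
  two_by_two(cnt[1], cnt[2], cnt[3], cnt[4])
}

#' Simulated two-group exponential survival data
#'
#' Subjects belong to the harmful factor level (`group = 1`, hazard 1) with
#' probability `alpha` and to the protective level (`group = 0`, hazard
#' `1 / hr`) otherwise.  Censoring is either absent, type I (all subjects
#' followed exactly `tau` time units), or administrative (uniform follow-up
#' over `(0, tau)`, as from constant accrual with analysis at `tau`).
#'
#' @param n sample size.
#' @param hr hazard ratio of harmful versus protective level.
#' @param alpha probability of the harmful level.
#' @param censoring `"none"`, `"type1"` or `"administrative"`.
#' @param tau follow-up horizon; required for the censored modes.
#' @param seed optional integer seed.
#' @return A data frame with columns `time`, `status` (1 = event) and
#'   `group` (1 = harmful level).
#' @examples
#' summary(gen_exp_survival(1000, hr = 10, alpha = 0.5,
#'                          censoring = "administrative", tau = 4.9, seed = 2))
#' @export
gen_exp_survival <- function(n, hr, alpha,
                             censoring = c("none", "type1", "administrative"),
                             tau = NULL, seed = NULL) {
  censoring <- match.arg(censoring)
  if (censoring != "none" && (is.null(tau) || tau <= 0))
    stop("a positive 'tau' is required for censored modes")
  if (!is.null(seed)) set.seed(seed)
  group <- stats::rbinom(n, 1, alpha)
  t_event <- stats::rexp(n, rate = ifelse(group == 1, 1, 1 / hr))
  cens <- switch(censoring,
    none = rep(Inf, n),
    type1 = rep(tau, n),
    administrative = stats::runif(n, 0, tau))
  data.frame(time = pmin(t_event, cens),
             status = as.integer(t_event <= cens),
             group = group)
}

#' Simulation study of estimator bias, coverage and interval width
#'
#' Runs the full generate / fit / estimate loop (optionally with a bootstrap
#' interval per replicate), compares against the matching population values
#' and summarizes the result: quartiles of bias (sample minus population
#' value), empirical coverage of the population value and mean interval
#' width.  Fully seeded: per-replicate seeds are drawn once from the base
#' seed so any single replicate can be regenerated.
#'
#' @param family `"logistic_normal"`, `"two_by_two"` or `"exp_survival"`.
#' @param params named list of scenario parameters: `beta0`/`beta1` for
#'   `logistic_normal`; `p_d`/`alpha`/`odds_ratio` for `two_by_two`;
#'   `hr`/`alpha` plus optional `censoring`/`tau` for `exp_survival`.
#' @param n per-replicate sample size.
#' @param n_sim number of simulated samples (the package's studies default
#'   to 250; coverage studies use more).
#' @param seed base integer seed.
#' @param bootstrap if `TRUE`, a bootstrap interval is built per replicate.
#' @param B,method,level bootstrap settings (see [boot_dn_ds()]).
#' @param tau analysis horizon for the survival family (defaults to
#'   `params$tau` or the per-sample maximum).
#' @return A list with `estimates` (one row per replicate and measure),
#'   `summary` (per measure: population value, median and quartiles of bias,
#'   and — when `bootstrap` — coverage and mean width) and `population`.
#' @examples
#' simulation_study("two_by_two", list(p_d = 0.5, alpha = 0.5, odds_ratio = 10),
#'                  n = 200, n_sim = 10, seed = 42)$summary
#' @export
simulation_study <- function(family = c("logistic_normal", "two_by_two",
                                        "exp_survival"),
                             params, n, n_sim = 250, seed = 1,
                             bootstrap = FALSE, B = 200, method = "bca",
                             level = 0.95, tau = NULL) {
  family <- match.arg(family)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_sim)
  keys <- c("dn1", "dn2", "ds1", "ds2", "ev")

  pop <- switch(family,
    logistic_normal = {
      if (params$beta1 == 0) {
        setNames(rep(0, 5), keys)
      } else {
        pd <- stats::integrate(function(x)
          stats::plogis(params$beta0 + params$beta1 * x) * stats::dnorm(x),
          -Inf, Inf, rel.tol = 1e-10)$value
        unlist(pop_logistic_normal(pd, beta1 = params$beta1)[keys])
      }
    },
    two_by_two = unlist(dn_ds(scenario_cells(params$p_d, params$alpha,
                                             params$odds_ratio))[keys]),
    exp_survival = {
      ptau <- if (!is.null(tau)) tau else
        if (!is.null(params$tau)) params$tau else Inf
      unlist(pop_survival(params$hr, params$alpha, tau = ptau)[keys])
    })

  one <- function(s) {
    est <- switch(family,
      logistic_normal = {
        d <- gen_logistic_normal(n, params$beta0, params$beta1, seed = s)
        if (bootstrap)
          boot_dn_ds(d, logistic_probs("y", "x"), B = B, method = method,
                     level = level, seed = s + 1L)
        else dn_ds(logistic_probs("y", "x")(d))
      },
      two_by_two = dn_ds(gen_2x2(n, params$p_d, params$alpha,
                                 params$odds_ratio, seed = s)),
      exp_survival = {
        d <- gen_exp_survival(n, params$hr, params$alpha,
                              censoring = params$censoring %||% "none",
                              tau = params$tau, seed = s)
        dn_ds(cox_curves(d$time, d$status, d$group, method = "km"),
              tau = tau %||% params$tau %||% NULL)
      })
    est
  }
  fits <- lapply(rep_seeds, function(s)
    tryCatch(one(s), error = function(e) NULL))
  failed <- vapply(fits, is.null, logical(1))
  fits <- fits[!failed]
  if (length(fits) == 0L) stop("all replicates failed")

  grab <- function(f, k) if (inherits(f, "necsuff_boot")) f$table[k, "point"]
                         else f[[k]]
  est <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(replicate = i, measure = keys,
               estimate = vapply(keys, grab, numeric(1), f = f),
               lower = if (inherits(f, "necsuff_boot")) f$table[keys, "lower"]
                       else NA_real_,
               upper = if (inherits(f, "necsuff_boot")) f$table[keys, "upper"]
                       else NA_real_,
               row.names = NULL)
  }))
  summ <- do.call(rbind, lapply(keys, function(k) {
    e <- est[est$measure == k, ]
    bias <- e$estimate - pop[[k]]
    out <- data.frame(measure = k, population = pop[[k]],
                      bias_q1 = unname(stats::quantile(bias, 0.25)),
                      bias_median = stats::median(bias),
                      bias_q3 = unname(stats::quantile(bias, 0.75)))
    if (bootstrap) {
      out$coverage <- mean(e$lower <= pop[[k]] & pop[[k]] <= e$upper)
      out$mean_width <- mean(e$upper - e$lower)
    }
    out
  }))
  list(estimates = est, summary = summ, population = pop,
       n_failed = sum(failed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
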