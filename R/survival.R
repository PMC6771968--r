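#' Kaplan-Meier cumulative incidence at the distinct event times
#'
#' Product-limit estimate of the unconditional cumulative incidence
#' `F(t) = 1 - S(t)`, evaluated (right-continuously) at each distinct event
#' time.  Thin wrapper around [survival::survfit()].
#'
#' @param time positive observation times.
#' @param status event indicators, 1 = event, 0 = censored.
#' @return A list with `event_times` (strictly increasing distinct event
#'   times), `d` (event counts per time) and `F` (cumulative incidence).
#' @examples
#' km_cdf(c(1, 2, 3), c(1, 0, 1))
#' @export
km_cdf <- function(time, status) {
  check_surv_input(time, status)
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  keep <- sf$n.event > 0
  list(event_times = sf$time[keep], d = sf$n.event[keep],
       F = 1 - sf$surv[keep])
}

check_surv_input <- function(time, status) {
  if (length(time) != length(status)) stop("'time' and 'status' lengths differ")
  if (anyNA(time) || anyNA(status)) stop("missing values in survival input")
  if (any(time <= 0) || any(!is.finite(time)))
    stop("all observation times must be positive and finite")
  if (!all(status %in% c(0, 1))) stop("'status' must be coded 0/1 (1 = event)")
  if (sum(status) == 0) stop("no events: estimation is impossible")
  invisible(TRUE)
}

#' Reverse Kaplan-Meier censoring weights
#'
#' Product-limit estimate of the censoring ("potential follow-up")
#' distribution `G(t)`, obtained by reversing the meaning of the event
#' indicator, and its reciprocal evaluated as the left limit `1 / G(t-)` at
#' each requested event time.  Evaluating the left limit means the weight at
#' an event time never conditions on censorings tied to that time, which
#' keeps every weight positive, finite and at least 1.  The reciprocals
#' de-attenuate late event times when averaging over the observed events.
#'
#' @inheritParams km_cdf
#' @param eval_times times (usually the distinct event times) at which the
#'   weights are required.
#' @return A list with `G` (the censoring-survival left limits `G(t-)`) and
#'   `weights` (`1 / G(t-)`), both in the order of `eval_times`.
#' @examples
#' censoring_weights(c(1, 2, 3), c(1, 0, 1), eval_times = c(1, 3))
#' @export
censoring_weights <- function(time, status, eval_times) {
  check_surv_input(time, status)
  sf <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  jump <- sf$n.event > 0
  jt <- sf$time[jump]
  js <- sf$surv[jump]
  # guard against G hitting 0 (only possible beyond the last usable weight)
  pos <- js > 0
  if (!all(pos) && any(pos)) js[!pos] <- min(js[pos])
  if (!any(pos)) js[] <- 1
  idx <- findInterval(eval_times, jt, left.open = TRUE)  # jumps strictly < t
  G <- c(1, js)[idx + 1L]
  list(G = G, weights = 1 / G)
}

#' Conditional and unconditional incidence curves for DN/DS estimation
#'
#' Container binding everything the survival estimators need: the distinct
#' event times with their event counts, the unconditional cumulative
#' incidence, a matrix of conditional cumulative incidences and the reverse
#' Kaplan-Meier weights.  The conditional matrix is model-agnostic: any
#' estimator that produces `F(t | x)` at the event times can feed it (Cox,
#' stratified Kaplan-Meier, parametric models, external predictions).
#'
#' Rows of `F_cond` are covariate *profiles*.  With one row per subject,
#' `profile` is `1:n`; identical profiles (eg, the levels of a dichotomous
#' factor) may be collapsed to one row each, with `profile` mapping subjects
#' to rows — the estimators weight each row by its subject count, which keeps
#' large two-group problems cheap.
#'
#' @param time,status the per-subject observation times and event indicators
#'   the curves were estimated from.
#' @param event_times strictly increasing distinct event times.
#' @param d event counts per event time (default from the data).
#' @param F_uncond unconditional cumulative incidence at `event_times`
#'   (default: Kaplan-Meier via [km_cdf()]).
#' @param F_cond numeric matrix of conditional cumulative incidences, one row
#'   per profile, one column per event time; rows must be nondecreasing with
#'   values in `[0, 1]`.
#' @param profile integer vector mapping each subject to a row of `F_cond`
#'   (default `1:n`, requiring `nrow(F_cond) == n`).
#' @param G_inv reverse-KM weights `1 / G(t-)` at `event_times` (default via
#'   [censoring_weights()]).
#' @return An object of class `"survival_curves"`.
#' @seealso [cox_curves()] to build one from a model fit, [dn_ds()] and
#'   [sh_ev()] to consume it.
#' @export
survival_curves <- function(time, status, F_cond, event_times = NULL,
                            d = NULL, F_uncond = NULL, profile = NULL,
                            G_inv = NULL) {
  check_surv_input(time, status)
  n <- length(time)
  km <- km_cdf(time, status)
  if (is.null(event_times)) event_times <- km$event_times
  if (is.null(d)) d <- km$d[match(event_times, km$event_times)]
  if (is.null(F_uncond)) F_uncond <- km$F[match(event_times, km$event_times)]
  m <- length(event_times)
  if (is.unsorted(event_times, strictly = TRUE))
    stop("'event_times' must be strictly increasing")
  if (anyNA(d) || any(d < 1)) stop("each event time needs at least one event")
  if (length(F_uncond) != m || any(F_uncond < 0 | F_uncond > 1) ||
      is.unsorted(F_uncond))
    stop("'F_uncond' must be nondecreasing in [0, 1], one value per event time")
  F_cond <- as.matrix(F_cond)
  if (ncol(F_cond) != m)
    stop("'F_cond' needs one column per event time")
  if (any(F_cond < 0 | F_cond > 1) ||
      any(apply(F_cond, 1L, is.unsorted)))
    stop("each row of 'F_cond' must be nondecreasing with values in [0, 1]")
  if (is.null(profile)) {
    if (nrow(F_cond) != n)
      stop("'F_cond' needs one row per subject unless 'profile' is given")
    profile <- seq_len(n)
  }
  profile <- as.integer(profile)
  if (length(profile) != n || any(profile < 1L) || any(profile > nrow(F_cond)))
    stop("'profile' must map every subject to a row of 'F_cond'")
  if (is.null(G_inv))
    G_inv <- censoring_weights(time, status, event_times)$weights
  if (length(G_inv) != m || any(G_inv < 1))
    stop("'G_inv' must provide one weight >= 1 per event time")
  structure(list(time = time, status = status, event_times = event_times,
                 d = d, F_uncond = F_uncond, F_cond = F_cond,
                 profile = profile,
                 counts = tabulate(profile, nbins = nrow(F_cond)),
                 G_inv = G_inv, n = n),
            class = "survival_curves")
}

#' @export
print.survival_curves <- function(x, ...) {
  cat(sprintf(paste0("survival_curves: %d subjects, %d distinct event times,",
                     " %d conditional profiles\n"),
              x$n, length(x$event_times), nrow(x$F_cond)))
  cat(sprintf("  follow-up %g to %g, %d events, max weight %.3f\n",
              min(x$time), max(x$time), sum(x$status), max(x$G_inv)))
  invisible(x)
}

#' Conditional incidence curves from a Cox model or stratified Kaplan-Meier
#'
#' Builds a [survival_curves()] object from data and a covariate
#' specification.  `method = "cox"` fits a proportional-hazards model via
#' [survival::coxph()] and derives per-profile survival from the Breslow
#' baseline cumulative hazard, `S(t | x) = exp(-H0(t) exp(x'beta))`;
#' `method = "km"` uses stratified product-limit curves and requires a single
#' discrete covariate.  Identical covariate rows are collapsed to one profile.
#'
#' @inheritParams km_cdf
#' @param x covariate vector, matrix or data frame (one row per subject).
#' @param method `"cox"` or `"km"` (stratified Kaplan-Meier).
#' @return A [survival_curves()] object.
#' @examples
#' d <- gen_exp_survival(300, hr = 4, alpha = 0.5, seed = 7)
#' dn_ds(cox_curves(d$time, d$status, d$group, method = "km"))
#' @export
cox_curves <- function(time, status, x, method = c("cox", "km")) {
  method <- match.arg(method)
  check_surv_input(time, status)
  km <- km_cdf(time, status)
  et <- km$event_times
  if (method == "km") {
    g <- as.factor(if (is.data.frame(x)) x[[1]] else x)
    if (length(g) != length(time)) stop("covariate length mismatch")
    lev <- levels(g)
    F_cond <- t(vapply(lev, function(l) {
      sel <- g == l
      if (!any(status[sel] == 1)) return(numeric(length(et)))
      sub <- km_cdf(time[sel], status[sel])
      c(0, sub$F)[findInterval(et, sub$event_times) + 1L]
    }, numeric(length(et))))
    profile <- as.integer(g)
  } else {
    X <- stats::model.matrix(~., data = as.data.frame(x))[, -1, drop = FALSE]
    if (nrow(X) != length(time)) stop("covariate length mismatch")
    fit <- survival::coxph(survival::Surv(time, status) ~ X)
    if (any(is.na(stats::coef(fit))))
      stop("proportional-hazards fit failed to converge")
    bh <- survival::basehaz(fit, centered = FALSE)
    H0 <- c(0, bh$hazard)[findInterval(et, bh$time) + 1L]
    uX <- unique(X)
    profile <- match(apply(X, 1, paste, collapse = "\r"),
                     apply(uX, 1, paste, collapse = "\r"))
    risk <- exp(as.vector(uX %*% stats::coef(fit)))
    F_cond <- 1 - exp(-outer(risk, H0))
    F_cond[F_cond < 0] <- 0; F_cond[F_cond > 1] <- 1
  }
  survival_curves(time, status, F_cond, event_times = et, d = km$d,
                  F_uncond = km$F, profile = profile)
}

#' Degrees of necessity and sufficiency at a single time point
#'
#' At a fixed time the survival problem reduces to the dichotomous one:
#' subjects whose conditional cumulative incidence lies strictly below the
#' unconditional value `F_t` form the protective set (necessity kernel
#' `(F_t - F(t|x)) / F_t`), those strictly above the harmful set
#' (sufficiency kernel `(F(t|x) - F_t) / (1 - F_t)`).  Variant 1 is the root
#' mean square of the kernel, variant 2 the mean; empty sets yield 0.
#'
#' @param F_t unconditional cumulative incidence at the time, in `(0, 1)`.
#' @param F_cond_t conditional cumulative incidences at the same time, one
#'   per profile.
#' @param counts subject counts per profile (default 1 each).
#' @return A list with `dn1`, `dn2`, `ds1`, `ds2`, `n_less`, `n_greater`.
#' @examples
#' dn_ds_at_time(0.4, c(0.2, 0.6))
#' @export
dn_ds_at_time <- function(F_t, F_cond_t, counts = rep(1, length(F_cond_t))) {
  if (F_t <= 0 || F_t >= 1)
    stop("degenerate time: unconditional incidence must be strictly in (0, 1)")
  less <- F_cond_t < F_t
  greater <- F_cond_t > F_t
  n_less <- sum(counts[less]); n_greater <- sum(counts[greater])
  kn <- (F_t - F_cond_t[less]) / F_t
  ks <- (F_cond_t[greater] - F_t) / (1 - F_t)
  wl <- counts[less]; wg <- counts[greater]
  list(
    dn1 = if (n_less > 0) sqrt(sum(wl * kn^2) / n_less) else 0,
    dn2 = if (n_less > 0) sum(wl * kn) / n_less else 0,
    ds1 = if (n_greater > 0) sqrt(sum(wg * ks^2) / n_greater) else 0,
    ds2 = if (n_greater > 0) sum(wg * ks) / n_greater else 0,
    n_less = n_less, n_greater = n_greater)
}

#' @describeIn dn_ds Weighted averages of the per-event-time measures over
#'   the distinct event times up to `tau`, with reverse-KM weights
#'   `d_j / G(t_j-)` compensating the attenuation of late event times by
#'   earlier censoring.  Event times whose informative set is empty are, by
#'   default, dropped from numerator and denominator of the affected measure
#'   (separate renormalization for DN and DS; `drop_empty = FALSE` keeps them
#'   as zeros instead).  `alpha` is the weighted average proportion of
#'   subjects with conditional incidence above the unconditional one.  The
#'   result additionally carries `tau`, `m_used` and a per-time diagnostic
#'   table in attribute `"times"` (columns `time`, `d`, `weight`, `dn1_t`,
#'   `ds1_t`, `n_less`, `n_greater`).  All estimates are invariant under
#'   strictly monotone transformations of the time scale.
#' @param tau time horizon: only event times `<= tau` enter (default: the
#'   largest observation time).  No extrapolation beyond `tau` is attempted.
#' @param drop_empty how event times with an empty informative set are
#'   handled (see above).
#' @export
dn_ds.survival_curves <- function(x, tau = NULL, drop_empty = TRUE, ...) {
  if (is.null(tau)) tau <- max(x$time)
  usable <- x$event_times <= tau & x$F_uncond > 0 & x$F_uncond < 1
  edge <- x$event_times <= tau & !usable   # F = 1 at the last event time(s)
  if (!any(x$event_times <= tau))
    stop("estimation impossible: no event times at or before tau")
  js <- which(usable)
  if (length(js) == 0L)
    stop("estimation impossible: no usable event times before tau")
  m <- length(js)
  per <- matrix(0, m, 6,
                dimnames = list(NULL, c("dn1", "dn2", "ds1", "ds2",
                                        "n_less", "n_greater")))
  for (k in seq_len(m)) {
    j <- js[k]
    at <- dn_ds_at_time(x$F_uncond[j], x$F_cond[, j], x$counts)
    per[k, ] <- unlist(at)
  }
  w <- x$G_inv[js] * x$d[js]
  wavg <- function(v, inform) {
    use <- if (drop_empty) inform > 0 else rep(TRUE, m)
    if (!any(use)) return(0)
    sum(w[use] * v[use]) / sum(w[use])
  }
  out <- list(
    dn1 = wavg(per[, "dn1"], per[, "n_less"]),
    dn2 = wavg(per[, "dn2"], per[, "n_less"]),
    ds1 = wavg(per[, "ds1"], per[, "n_greater"]),
    ds2 = wavg(per[, "ds2"], per[, "n_greater"]),
    ev = NA_real_,
    alpha = sum(w * per[, "n_greater"] / x$n) / sum(w),
    n_less = max(per[, "n_less"]), n_greater = max(per[, "n_greater"]),
    p_bar = NA_real_, n = x$n, tau = tau,
    m_used = m, m_dropped_degenerate = sum(edge))
  out$ev <- sh_ev(x, tau = tau)
  attr(out, "times") <- data.frame(
    time = x$event_times[js], d = x$d[js], weight = x$G_inv[js],
    dn1_t = per[, "dn1"], ds1_t = per[, "ds1"],
    n_less = per[, "n_less"], n_greater = per[, "n_greater"])
  class(out) <- "necsuff"
  out
}

#' Convenience wrapper: DN/DS/EV for survival data in one call
#'
#' Fits conditional curves with [cox_curves()] and evaluates the weighted
#' estimators with [dn_ds()].
#'
#' @inheritParams cox_curves
#' @inheritParams dn_ds.survival_curves
#' @return A `"necsuff"` object (see [dn_ds()]).
#' @export
dn_ds_surv <- function(time, status, x, method = c("cox", "km"), tau = NULL,
                       drop_empty = TRUE) {
  dn_ds(cox_curves(time, status, x, method = match.arg(method)),
        tau = tau, drop_empty = drop_empty)
}

#' Schemper-Henderson explained variation for survival
#'
#' The explained variation of a survival model is the relative reduction of
#' mean absolute predictive inaccuracy when conditional survival curves
#' replace the unconditional one.  At an event time `t` a subject still under
#' observation beyond `t` contributes `1 - S(t)`; a subject known to have
#' died by `t` contributes `S(t)`; a subject censored at `t_i <= t`
#' contributes its expected inaccuracy
#' `(S(t)/S(t_i)) (1 - S(t)) + (1 - S(t)/S(t_i)) S(t)`, splitting the
#' probability of being alive at `t` given survival to `t_i`.  The mean over
#' subjects gives the inaccuracy `M(t)` (conditional version `Mx(t)` with
#' `S(t | x_i)` throughout), and
#' `EV = 1 - sum_j w_j Mx(t_j) / sum_j w_j M(t_j)` with the reverse-KM
#' weights `w_j = d_j / G(t_j-)` over the distinct event times up to `tau`.
#' A negative value (possible in small samples) is clipped to 0 with
#' attribute `"clipped"` set.
#'
#' @param curves a [survival_curves()] object.
#' @param tau time horizon (default: the largest observation time).
#' @return The explained variation, a single number in `[0, 1]`.
#' @examples
#' d <- gen_exp_survival(400, hr = 6, alpha = 0.5, seed = 11)
#' sh_ev(cox_curves(d$time, d$status, d$group, method = "km"))
#' @export
sh_ev <- function(curves, tau = NULL) {
  stopifnot(inherits(curves, "survival_curves"))
  if (is.null(tau)) tau <- max(curves$time)
  js <- which(curves$event_times <= tau)
  if (length(js) == 0L)
    stop("estimation impossible: no event times at or before tau")
  et <- curves$event_times[js]
  n <- curves$n
  w <- curves$G_inv[js] * curves$d[js]

  # n * M(t_j) for the subjects in 'sel', against survival curve S (over js)
  inaccuracy <- function(sel, S) {
    tt <- curves$time[sel]; ss <- curves$status[sel]
    # S at each subject's own (censoring) time, step right-continuous
    Si <- c(1, S)[findInterval(tt, et) + 1L]
    Si[Si <= 0] <- min(S[S > 0], 1)
    ot <- order(tt)
    tt_s <- tt[ot]; ss_s <- ss[ot]; inv_s <- (1 / Si)[ot]
    # cumulative tallies at each event time: subjects with tt <= t_j
    pos <- findInterval(et, tt_s)
    cdead <- cumsum(ss_s)
    ccens <- cumsum(1 - ss_s)
    cinv <- cumsum((1 - ss_s) * inv_s)
    ndead <- c(0, cdead)[pos + 1L]
    ncens <- c(0, ccens)[pos + 1L]
    sinv <- c(0, cinv)[pos + 1L]
    nalive <- length(tt) - ndead - ncens
    nalive * (1 - S) + ndead * S + ncens * S + (1 - 2 * S) * S * sinv
  }

  S_unc <- 1 - curves$F_uncond[js]
  M <- inaccuracy(rep(TRUE, n), S_unc)
  Mx <- numeric(length(js))
  for (k in seq_len(nrow(curves$F_cond))) {
    sel <- curves$profile == k
    if (!any(sel)) next
    Mx <- Mx + inaccuracy(sel, 1 - curves$F_cond[k, js])
  }
  ev <- 1 - sum(w * Mx) / sum(w * M)
  if (ev < 0) {
    ev <- structure(0, clipped = TRUE)
  }
  ev
}
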