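#' Degrees of necessity and sufficiency
#'
#' `dn_ds()` computes the degree of necessity (DN), the degree of sufficiency
#' (DS) and the explained variation (EV) of a prognostic factor for a
#' dichotomous or survival outcome.  A factor level is *protective* where the
#' conditional event probability falls below the unconditional one and
#' *harmful* where it lies above; DN averages the normalized reduction of the
#' event probability over the protective range, DS the normalized increase
#' over the harmful range.  Both come in two variants: variant 1 is the root
#' mean square of the kernel, variant 2 its plain mean, so that
#' `dn1^2 <= dn2 <= dn1` always holds (and likewise for DS).
#'
#' For the default method the input is a vector of conditional event
#' probabilities, one per subject, typically fitted values of a logistic
#' regression model, although any calibrated prediction tool may be used.
#' With baseline probability `p_bar`, subjects with `probs < p_bar` form the
#' protective (informative) set for DN, subjects with `probs > p_bar` the
#' harmful set for DS; ties contribute to neither.  An empty informative set
#' yields a measure of 0.
#'
#' EV is the relative reduction in predictive inaccuracy when the conditional
#' prediction replaces the unconditional one.  The default (`ev = "indirect"`)
#' is the plug-in `1 - mean(p(1-p)) / (p_bar (1 - p_bar))`; `ev = "deviation"`
#' uses the squared-deviation form `mean((p - p_bar)^2) / (p_bar (1 - p_bar))`.
#' The two coincide exactly when the predictions are calibrated
#' (`mean(probs) == p_bar`).
#'
#' @param x conditional event probabilities in `[0, 1]` (default method), a
#'   [two_by_two()] table, or a [survival_curves()] object.
#' @param ... passed to methods.
#' @return An object of class `"necsuff"`: a list with components `dn1`,
#'   `dn2`, `ds1`, `ds2`, `ev`, `alpha` (estimated probability of a harmful
#'   level), `n_less`, `n_greater`, `p_bar` and `n`.  Method-specific extras
#'   are documented with the methods.
#' @seealso [two_by_two()], [dn_ds_surv()], [boot_dn_ds()], [ev_decomposition()]
#' @examples
#' ## a perfectly calibrated two-group prediction
#' p <- c(rep(0.05, 70), rep(0.40, 30))
#' dn_ds(p)
#' @export
dn_ds <- function(x, ...) UseMethod("dn_ds")

#' @rdname dn_ds
#' @param p_bar baseline (unconditional) event probability, strictly inside
#'   `(0, 1)`.  Defaults to `mean(outcomes)` when outcomes are supplied,
#'   otherwise to `mean(x)`.
#' @param outcomes optional 0/1 outcome indicators of the same length as `x`,
#'   used only to set the default `p_bar`.
#' @param ev estimator of explained variation, `"indirect"` or `"deviation"`.
#' @param tol absolute tolerance for classifying `probs` against `p_bar`;
#'   values within `tol` of `p_bar` are treated as noninformative ties.
#' @export
dn_ds.default <- function(x, p_bar = NULL, outcomes = NULL,
                          ev = c("indirect", "deviation"), tol = 0, ...) {
  ev <- match.arg(ev)
  probs <- as.numeric(x)
  n <- length(probs)
  if (n < 1L) stop("at least one subject is required")
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stop("invalid probability: all conditional probabilities must lie in [0, 1]")
  if (!is.null(outcomes)) {
    if (length(outcomes) != n)
      stop("'outcomes' must have the same length as the probability vector")
    if (!all(outcomes %in% c(0, 1))) stop("'outcomes' must be coded 0/1")
  }
  if (is.null(p_bar))
    p_bar <- if (!is.null(outcomes)) mean(outcomes) else mean(probs)
  if (!is.numeric(p_bar) || length(p_bar) != 1L || is.na(p_bar) ||
      p_bar <= 0 || p_bar >= 1)
    stop("invalid baseline: 'p_bar' must lie strictly inside (0, 1)")

  less <- probs < p_bar - tol
  greater <- probs > p_bar + tol
  kn <- (p_bar - probs[less]) / p_bar          # necessity kernel
  ks <- (probs[greater] - p_bar) / (1 - p_bar) # sufficiency kernel
  out <- list(
    dn1 = if (any(less)) sqrt(mean(kn^2)) else 0,
    dn2 = if (any(less)) mean(kn) else 0,
    ds1 = if (any(greater)) sqrt(mean(ks^2)) else 0,
    ds2 = if (any(greater)) mean(ks) else 0,
    ev = switch(ev,
      indirect = 1 - mean(probs * (1 - probs)) / (p_bar * (1 - p_bar)),
      deviation = mean((probs - p_bar)^2) / (p_bar * (1 - p_bar))),
    ev_mode = ev,
    alpha = sum(greater) / n,
    n_less = sum(less),
    n_greater = sum(greater),
    p_bar = p_bar,
    n = n)
  class(out) <- "necsuff"
  out
}

#' @export
print.necsuff <- function(x, digits = 3, ...) {
  cat("Degrees of necessity and sufficiency\n")
  if (!is.null(x$protective_level))
    cat("  protective level: X =", x$protective_level, "\n")
  m <- c(DN1 = x$dn1, DN2 = x$dn2, DS1 = x$ds1, DS2 = x$ds2, EV = x$ev)
  print(round(m, digits))
  cat(sprintf("baseline P(D) = %.*f, alpha = %.*f, n< = %d, n> = %d, n = %d\n",
              digits, x$p_bar, digits, x$alpha,
              as.integer(x$n_less), as.integer(x$n_greater), as.integer(x$n)))
  invisible(x)
}

#' Explained variation from its necessity/sufficiency decomposition
#'
#' EV decomposes exactly into the variant-1 measures when predictions are
#' calibrated:
#' `EV = (1 - alpha) * odds(D) * DN1^2 + alpha * odds(not D) * DS1^2`,
#' with `odds(D) = p_bar / (1 - p_bar)`.  The weights show that for rare
#' outcomes EV is driven almost entirely by sufficiency, and for common
#' outcomes by necessity.
#'
#' @param dn1,ds1 variant-1 degrees of necessity and sufficiency in `[0, 1]`.
#' @param alpha probability of a harmful factor level, in `[0, 1]`.
#' @param p_bar unconditional event probability, strictly inside `(0, 1)`.
#' @return The explained variation implied by the decomposition.
#' @examples
#' ev_decomposition(dn1 = 0.346, ds1 = 0.346, alpha = 0.1, p_bar = 0.1)
#' @export
ev_decomposition <- function(dn1, ds1, alpha, p_bar) {
  if (any(p_bar <= 0) || any(p_bar >= 1))
    stop("invalid baseline: 'p_bar' must lie strictly inside (0, 1)")
  stopifnot(dn1 >= 0, dn1 <= 1, ds1 >= 0, ds1 <= 1, alpha >= 0, alpha <= 1)
  (1 - alpha) * (p_bar / (1 - p_bar)) * dn1^2 +
    alpha * ((1 - p_bar) / p_bar) * ds1^2
}

#' Partial degrees of necessity and sufficiency
#'
#' The partial DN (DS, EV) of a set of added covariates is the difference
#' between the measures of a full and a nested reduced model fitted to the
#' same subjects, quantifying the gain attributable to the added covariates.
#' Partial measures can be negative in finite samples; they are returned
#' unchanged with a warning since no truncation is defined for them.
#'
#' @param full,reduced `"necsuff"` objects from nested models on the same
#'   subjects and outcome.
#' @return A named numeric vector with components `dn1`, `dn2`, `ds1`, `ds2`
#'   and `ev` (full minus reduced).
#' @export
partial_measures <- function(full, reduced) {
  stopifnot(inherits(full, "necsuff"), inherits(reduced, "necsuff"))
  if (!is.null(full$n) && !is.null(reduced$n) && full$n != reduced$n)
    warning("full and reduced estimates are based on different sample sizes")
  keys <- c("dn1", "dn2", "ds1", "ds2", "ev")
  out <- vapply(keys, function(k) full[[k]] - reduced[[k]], numeric(1))
  if (any(out < 0))
    warning("negative partial measure(s): ",
            paste(keys[out < 0], collapse = ", "))
  out
}
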