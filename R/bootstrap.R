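#' Bootstrap confidence intervals for DN, DS and EV
#'
#' Percentile or bias-corrected-and-accelerated (BCa) bootstrap intervals for
#' all five measures.  Replicates resample whole observation rows with
#' replacement and rerun the full model-fitting procedure on each replicate,
#' so the intervals reflect model-fitting variability, not just plug-in
#' noise.
#'
#' Within each replicate a *direction-consistency* rule is applied: the
#' protective/harmful partition of the subjects is frozen from the original
#' sample, and whenever the replicate's mean predicted probability over the
#' original harmful range falls below its mean over the original protective
#' range, the replicate's DN and DS (and, since the rule fires jointly, EV)
#' are set to zero.  This prevents the meaning of protective and harmful
#' from silently flipping between the original sample and a replicate.
#' Subjects tied at the baseline belong to neither range and never flip.
#'
#' For survival fits the same rule operates on the incidence scale: a
#' replicate is truncated when its reverse-KM-weighted average conditional
#' incidence over the original harmful subject set falls below that over the
#' protective set.
#'
#' @param data data frame of observations, one row per subject.
#' @param fit model-fitting procedure applied to every replicate.  Either a
#'   function `data -> probs` (a vector of conditional event probabilities,
#'   optionally with attribute `"p_bar"`), eg [logistic_probs()], or a
#'   function `data -> [survival_curves()]` for survival outcomes.
#' @param B number of bootstrap replicates (at least 100).
#' @param method `"bca"` or `"percentile"`.
#' @param level nominal two-sided coverage, eg 0.95.
#' @param seed optional integer seed; identical seed and inputs give
#'   identical intervals.
#' @param tau horizon passed to the survival estimator, if applicable.
#' @param max_fail abort when more than this fraction of replicates fails to
#'   fit; failed replicates below the limit are redrawn and counted.
#' @return An object of class `"necsuff_boot"`: a list with `table` (one row
#'   per measure: `point`, `lower`, `upper`), `point` (the original-sample
#'   `"necsuff"` fit), `method`, `B`, `level`, `n_truncated`, `n_refit` and
#'   `seed`.
#' @examples
#' d <- gen_logistic_normal(150, beta0 = 0, beta1 = log(5), seed = 3)
#' boot_dn_ds(d, logistic_probs("y", "x"), B = 200, seed = 4)
#' @export
boot_dn_ds <- function(data, fit, B = 1000,
                       method = c("bca", "percentile"), level = 0.95,
                       seed = NULL, tau = NULL, max_fail = 0.05) {
  method <- match.arg(method)
  stopifnot(B >= 100, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  keys <- c("dn1", "dn2", "ds1", "ds2", "ev")

  measures_of <- function(obj, orig_partition = NULL, orig_index = NULL) {
    if (inherits(obj, "survival_curves")) {
      est <- dn_ds(obj, tau = tau)
    } else {
      pb <- attr(obj, "p_bar")
      est <- dn_ds(as.numeric(obj), p_bar = pb)
    }
    est
  }
  # per-subject summary used by the truncation rule
  risk_summary <- function(obj) {
    if (inherits(obj, "survival_curves")) {
      w <- obj$G_inv * obj$d
      as.vector((obj$F_cond %*% w / sum(w)))[obj$profile]
    } else as.numeric(obj)
  }

  fit0 <- fit(data)
  est0 <- measures_of(fit0)
  r0 <- risk_summary(fit0)
  base0 <- if (inherits(fit0, "survival_curves")) {
    w <- fit0$G_inv * fit0$d
    sum(fit0$F_uncond * w) / sum(w)
  } else est0$p_bar
  harmful0 <- which(r0 > base0)
  protective0 <- which(r0 < base0)

  reps <- matrix(NA_real_, B, 5, dimnames = list(NULL, keys))
  n_trunc <- 0L; n_refit <- 0L; fail_budget <- ceiling(max_fail * B)
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(fit(data[idx, , drop = FALSE]), error = function(e) NULL)
    if (is.null(fb)) {
      n_refit <- n_refit + 1L
      if (n_refit > fail_budget)
        stop("estimator failure in more than ", 100 * max_fail,
             "% of bootstrap replicates")
      next
    }
    eb <- measures_of(fb)
    vals <- unlist(eb[keys])
    rb <- risk_summary(fb)
    in_harm <- idx %in% harmful0
    in_prot <- idx %in% protective0
    if (any(in_harm) && any(in_prot) &&
        mean(rb[in_harm]) < mean(rb[in_prot])) {
      vals[] <- 0
      n_trunc <- n_trunc + 1L
    }
    reps[b, ] <- vals
    b <- b + 1L
  }

  a_low <- (1 - level) / 2
  accel <- if (method == "bca") {
    # one leave-one-out pass serves the acceleration of all five measures
    jack <- vapply(seq_len(n), function(i) {
      ji <- tryCatch(
        unlist(measures_of(fit(data[-i, , drop = FALSE]))[keys]),
        error = function(e) rep(NA_real_, 5))
      ji
    }, numeric(5))
    apply(jack, 1L, function(th) {
      th <- th[is.finite(th)]
      dev <- mean(th) - th
      s2 <- sum(dev^2)
      if (s2 == 0) 0 else sum(dev^3) / (6 * s2^1.5)
    })
  } else rep(0, 5)
  names(accel) <- keys
  ci <- vapply(keys, function(k) {
    th <- reps[, k]; t0 <- est0[[k]]
    if (method == "bca") {
      acc <- accel[[k]]
      p0 <- mean(th < t0) + mean(th == t0) / 2
      if (p0 > 0 && p0 < 1 && is.finite(acc)) {
        z0 <- stats::qnorm(p0)
        za <- stats::qnorm(c(a_low, 1 - a_low))
        adj <- stats::pnorm(z0 + (z0 + za) / (1 - acc * (z0 + za)))
        return(stats::quantile(th, adj, names = FALSE, type = 6))
      }
    }
    stats::quantile(th, c(a_low, 1 - a_low), names = FALSE, type = 6)
  }, numeric(2))

  tab <- cbind(point = unlist(est0[keys]),
               lower = pmin(pmax(ci[1, ], 0), 1),
               upper = pmin(pmax(ci[2, ], 0), 1))
  out <- list(table = tab, point = est0, method = method, B = B,
              level = level, n_truncated = n_trunc, n_refit = n_refit,
              seed = seed)
  class(out) <- "necsuff_boot"
  out
}

#' @export
print.necsuff_boot <- function(x, digits = 3, ...) {
  cat(sprintf("%s bootstrap intervals (B = %d, level = %.2f)\n",
              toupper(x$method), x$B, x$level))
  print(round(x$table, digits))
  cat(sprintf("%d of %d replicates truncated to 0 by the direction rule\n",
              x$n_truncated, x$B))
  invisible(x)
}

#' Jackknife acceleration constant for BCa intervals
#'
#' Leave-one-out estimates of a statistic yield the acceleration
#' `a = sum((mean(th) - th)^3) / (6 * sum((mean(th) - th)^2)^{3/2})`, the
#' standard skewness-based constant of the BCa construction.  Returns 0 when
#' the jackknife variance is 0 (a constant statistic).
#'
#' @inheritParams boot_dn_ds
#' @param stat function mapping the fitted object (the return value of
#'   `fit`) to a single number.
#' @return The acceleration constant.
#' @export
jackknife_acceleration <- function(data, fit, stat, tau = NULL) {
  n <- nrow(data)
  if (n < 3) stop("insufficient data: the jackknife needs at least 3 rows")
  th <- vapply(seq_len(n), function(i) {
    stat(fit(data[-i, , drop = FALSE]))
  }, numeric(1))
  dev <- mean(th) - th
  s2 <- sum(dev^2)
  if (s2 == 0) return(0)
  sum(dev^3) / (6 * s2^1.5)
}

#' Fast logistic-regression probability estimator for the bootstrap
#'
#' Returns a fitting function suitable for [boot_dn_ds()]: given a data
#' frame it fits a logistic regression of `y_col` on `x_cols` (via
#' [stats::glm.fit()] on the prebuilt design matrix, avoiding per-replicate
#' formula overhead) and returns the fitted conditional event probabilities,
#' with the outcome mean attached as attribute `"p_bar"`.
#'
#' @param y_col name of the 0/1 outcome column.
#' @param x_cols names of the covariate columns.
#' @return A function `data -> probs`.
#' @export
logistic_probs <- function(y_col, x_cols) {
  force(y_col); force(x_cols)
  function(data) {
    X <- cbind(1, as.matrix(data[x_cols]))
    y <- data[[y_col]]
    f <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    if (!f$converged) stop("logistic fit did not converge")
    structure(f$fitted.values, p_bar = mean(y))
  }
}
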