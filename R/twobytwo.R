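#' A 2x2 exposure-by-outcome table
#'
#' Container for the dichotomous-factor / dichotomous-outcome setting.  The
#' layout follows the usual epidemiological convention: `a` and `b` count the
#' non-events at the unexposed (`X = 0`) and exposed (`X = 1`) level, `c` and
#' `d` the events.  Cells may be counts or probabilities (summing to 1), so
#' the same closed forms serve sample estimates and population values.
#'
#' @param a,b,c,d nonnegative cell values: `a` = unexposed non-event, `b` =
#'   exposed non-event, `c` = unexposed event, `d` = exposed event.  A single
#'   2x2 matrix (rows = outcome no/yes, columns = X 0/1) may be passed as `a`.
#' @return An object of class `"two_by_two"` with components `a`, `b`, `c`,
#'   `d` and `n = a + b + c + d`.
#' @examples
#' two_by_two(8120, 4331, 36, 177)
#' @export
two_by_two <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    m <- a; a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  }
  if (is.null(b) || is.null(c) || is.null(d))
    stop("all four cells a, b, c, d are required")
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0))
    stop("cell values must be nonnegative numbers")
  n <- sum(cells)
  if (n <= 0) stop("the table must contain at least one observation")
  for (mar in list(c("event margin (c + d)", c + d),
                   c("non-event margin (a + b)", a + b),
                   c("unexposed margin (a + c)", a + c),
                   c("exposed margin (b + d)", b + d)))
    if (as.numeric(mar[[2]]) == 0)
      stop("degenerate table: ", mar[[1]], " is zero")
  structure(list(a = a, b = b, c = c, d = d, n = n), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$c, x$a, x$d, x$b), 2, 2,
              dimnames = list(outcome = c("D", "not D"), X = c("0", "1")))
  cat("2 x 2 exposure-by-outcome table (n =", format(x$n), ")\n")
  print(m)
  invisible(x)
}

#' @describeIn dn_ds Closed forms for a single dichotomous factor.  With
#'   `det = a*d - b*c > 0` the protective level is `X = 0` and
#'   `DN = det / ((a+c)(c+d))`, `DS = det / ((a+b)(b+d))`; for `det < 0` the
#'   exposure coding is reversed (protective level `X = 1`).  Both variants
#'   coincide, and `EV = DN * DS = det^2` over the product of the four
#'   margins.  The result carries `protective_level` (`0`, `1`, or `NA` when
#'   the odds ratio is 1 and all measures vanish).
#' @export
dn_ds.two_by_two <- function(x, ...) {
  a <- x$a; b <- x$b; c <- x$c; d <- x$d; n <- x$n
  det <- a * d - b * c
  ev <- det^2 / ((a + b) * (a + c) * (b + d) * (c + d))
  if (det > 0) {
    dn <- det / ((a + c) * (c + d))
    ds <- det / ((a + b) * (b + d))
    protective <- 0L; alpha <- (b + d) / n
    n_less <- a + c; n_greater <- b + d
  } else if (det < 0) {
    dn <- -det / ((b + d) * (c + d))
    ds <- -det / ((a + b) * (a + c))
    protective <- 1L; alpha <- (a + c) / n
    n_less <- b + d; n_greater <- a + c
  } else {
    dn <- ds <- 0; protective <- NA_integer_; alpha <- 0
    n_less <- n_greater <- 0
  }
  out <- list(dn1 = dn, dn2 = dn, ds1 = ds, ds2 = ds, ev = ev,
              ev_mode = "indirect", alpha = alpha,
              n_less = n_less, n_greater = n_greater,
              p_bar = (c + d) / n, n = n, protective_level = protective)
  class(out) <- "necsuff"
  out
}

#' Attributable and reverse attributable risk of a 2x2 table
#'
#' The attributable risk `AR = (P(D) - P(D | X = protective)) / P(D)` is the
#' relative reduction in event probability if all subjects were shifted to
#' the protective level; the reverse attributable risk
#' `AR* = (P(not D) - P(not D | X = harmful)) / P(not D)` is the relative
#' reduction of the non-event probability if all were shifted to the harmful
#' level.  For a dichotomous factor these equal DN and DS respectively, and
#' `AR * AR*` equals the explained variation of the table.
#'
#' @param table a [two_by_two()] table (counts or probabilities).
#' @return A list with components `ar`, `ar_star` and `protective_level`.
#' @examples
#' attributable_risks(two_by_two(8120, 4331, 36, 177))
#' @export
attributable_risks <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  m <- dn_ds(table)
  list(ar = m$dn1, ar_star = m$ds1, protective_level = m$protective_level)
}

#' Relative risk of a 2x2 table
#'
#' Event-probability ratio of the harmful versus the protective exposure
#' level, using the same direction resolution as [dn_ds()] (so the ratio is
#' at least 1 unless the odds ratio equals 1).
#'
#' @inheritParams attributable_risks
#' @return The relative risk as a single number.
#' @examples
#' relative_risk(two_by_two(8120, 4331, 36, 177))
#' @export
relative_risk <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  r0 <- c / (a + c)   # event rate at X = 0
  r1 <- d / (b + d)   # event rate at X = 1
  det <- a * d - b * c
  if (det >= 0) {
    if (r0 == 0) stop("undefined ratio: no events at the protective level (X = 0)")
    r1 / r0
  } else {
    if (r1 == 0) stop("undefined ratio: no events at the protective level (X = 1)")
    r0 / r1
  }
}

#' The Swedish smoking / lung-cancer-death cohort table
#'
#' Counts from a 33-year follow-up of 12,664 Swedish males cross-classifying
#' smoking history (never/ever) with death from lung cancer, the canonical
#' worked example for a factor that is highly necessary (DN about 0.74) yet
#' barely sufficient (DS about 0.02) for an outcome.  Also shipped as
#' `system.file("extdata", "lung_cancer_2x2.csv", package = "necsuff")`.
#'
#' @return A [two_by_two()] table with `a = 8120`, `b = 4331`, `c = 36`,
#'   `d = 177` (exposure `X = 1` is "ever smoked", the event is death from
#'   lung cancer).
#' @examples
#' dn_ds(lung_cancer_table())
#' @export
lung_cancer_table <- function() two_by_two(8120, 4331, 36, 177)
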