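#' Fit a DTNB (Ellman) calibration line
#'
#' Least-squares fit of absorbance at 412 nm against free-cysteine
#' concentration. An intercept is fitted (blank drift is common even though
#' Beer-Lambert implies a zero intercept) but the quantity of interest is
#' the slope `a`, in absorbance units per micromolar.
#'
#' @param data data frame with the calibration series.
#' @param concentration,absorbance columns of `data` holding concentrations
#'   (uM) and absorbances (tidy-eval columns; defaults `concentration`,
#'   `absorbance`).
#' @return An object of class `dtnb_fit` wrapping the underlying [lm()];
#'   supports [tidy()], [glance()], `coef()` and [calibration_slope()].
#' @export
fit_dtnb_calibration <- function(data, concentration = concentration,
                                 absorbance = absorbance) {
  conc <- dplyr::pull(data, {{ concentration }})
  abs412 <- dplyr::pull(data, {{ absorbance }})
  if (length(conc) < 2) abort("need at least 2 calibration points")
  if (any(conc < 0)) abort("concentrations must be non-negative")
  if (length(unique(conc)) < 2) {
    abort("degenerate calibration design: all concentrations equal")
  }
  fit <- stats::lm(abs412 ~ conc)
  structure(
    list(fit = fit,
         slope = unname(stats::coef(fit)[["conc"]]),
         intercept = unname(stats::coef(fit)[["(Intercept)"]]),
         n = length(conc)),
    class = "dtnb_fit")
}

#' Slope of a fitted DTNB calibration
#' @param x a `dtnb_fit`.
#' @return Slope in absorbance per uM.
#' @export
calibration_slope <- function(x) {
  stopifnot(inherits(x, "dtnb_fit"))
  x$slope
}

#' @export
print.dtnb_fit <- function(x, ...) {
  cat("DTNB calibration fit (", x$n, " points)\n", sep = "")
  cat(sprintf("  slope a = %.6g A412 / uM, intercept = %.6g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_dtnb_calibration
#' @param x a `dtnb_fit`.
#' @param ... unused.
#' @method tidy dtnb_fit
#' @export
tidy.dtnb_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @rdname fit_dtnb_calibration
#' @method glance dtnb_fit
#' @export
glance.dtnb_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r.squared = sm$r.squared,
    sigma = sm$sigma,
    nobs = x$n
  )
}

#' Accessible cysteines from the Ellman assay
#'
#' `N_Cys = E / (a * c)`: the total 412 nm absorbance of a sample divided
#' by the calibration slope and the protein concentration gives the number
#' of solvent-accessible (DTNB-reactive) cysteines per protein molecule.
#'
#' @param E total absorbance at 412 nm (dimensionless); vectorised.
#' @param a calibration slope, absorbance per uM (or a `dtnb_fit`).
#' @param c protein concentration, uM.
#' @return Accessible-cysteine count (real-valued), same length as `E`.
#' @export
count_accessible_cysteines <- function(E, a, c) {
  if (inherits(a, "dtnb_fit")) a <- a$slope
  if (any(a <= 0)) abort("calibration slope a must be positive")
  if (any(c <= 0)) abort("protein concentration c must be positive")
  if (any(E < 0)) abort("absorbance E must be non-negative")
  E / (a * c)
}
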