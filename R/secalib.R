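#' Size-exclusion column geometry
#'
#' Void volume `V0` and total column volume `Vc_col` (mL). Defaults are
#' the 24-mL analytical column with an 8-mL void used for the calibration.
#'
#' @param V0 void volume (mL).
#' @param Vc_col total column volume (mL), > V0.
#' @return object of class `column_geometry`.
#' @export
column_geometry <- function(V0 = 8, Vc_col = 24) {
  .check_pos(V0, "V0")
  if (Vc_col <= V0) stop("invalid geometry: total column volume must exceed the void volume")
  structure(list(V0 = V0, Vc_col = Vc_col), class = "column_geometry")
}

#' Partition coefficient from elution volume
#'
#' `Kav = (Ve - V0) / (Vc_col - V0)`. Values outside `[0, 1]` (elution
#' before the void or after the total volume) are allowed but flagged
#' with a warning.
#'
#' @param Ve elution volume (mL), vectorised.
#' @param geom a [column_geometry()].
#' @return partition coefficient(s).
#' @export
kav <- function(Ve, geom = column_geometry()) {
  stopifnot(inherits(geom, "column_geometry"))
  k <- (Ve - geom$V0) / (geom$Vc_col - geom$V0)
  if (any(k < 0 | k > 1)) {
    warning("elution volume outside [V0, Vc]: Kav outside [0, 1]")
  }
  k
}

#' Calibrate the column from protein standards
#'
#' Least-squares line of `Kav` against `log10(MW)` (the standard
#' semi-log relationship for globular proteins); a literal linear-in-MW
#' variant is available via `form = "linear"`. A non-negative slope
#' (larger proteins eluting later) fails the calibration.
#'
#' @param standards data frame with columns `mw_da` and `ve_ml` (>= 3
#'   rows); a `name` column is carried through if present.
#' @param geom a [column_geometry()].
#' @param form `"log10"` (default) or `"linear"`.
#' @return object of class `sec_calibration`: `slope`, `intercept`,
#'   `r_squared`, the standards table with Kav, the fitted `lm`.
#' @export
fit_calibration <- function(standards, geom = column_geometry(),
                            form = c("log10", "linear")) {
  form <- match.arg(form)
  stopifnot(is.data.frame(standards), all(c("mw_da", "ve_ml") %in% names(standards)))
  if (nrow(standards) < 3) stop("need at least 3 standards")
  standards$kav <- kav(standards$ve_ml, geom)
  x <- if (form == "log10") log10(standards$mw_da) else standards$mw_da
  fit <- stats::lm(standards$kav ~ x)
  slope <- stats::coef(fit)[[2]]
  if (slope >= 0) {
    stop("calibration-order error: Kav must decrease with molecular weight")
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope, intercept = stats::coef(fit)[[1]],
                 r_squared = r2, form = form,
                 standards = standards, kav_range = range(standards$kav),
                 geom = geom, lm = fit),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf("SEC calibration (%s): Kav = %.4f %+.4f * %s, R2 = %.4f (%d standards)\n",
              x$form, x$intercept, x$slope,
              if (x$form == "log10") "log10(MW)" else "MW",
              x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' Apparent molecular weight from an elution volume
#'
#' Inverts the calibration: `MW = 10^((Kav - intercept)/slope)` for the
#' semi-log form. Elutions outside the calibrated Kav range are
#' extrapolations and are flagged (attribute `extrapolated`), never
#' errors.
#'
#' @param Ve elution volume (mL), vectorised.
#' @param cal a [fit_calibration()] result.
#' @param geom a [column_geometry()]; defaults to the calibration's.
#' @return apparent molecular weight(s) in Da, with attribute
#'   `extrapolated` (logical vector).
#' @export
apparent_mw <- function(Ve, cal, geom = NULL) {
  stopifnot(inherits(cal, "sec_calibration"))
  if (is.null(geom)) geom <- cal$geom
  k <- kav(Ve, geom)
  extra <- k < cal$kav_range[1] | k > cal$kav_range[2]
  if (any(extra)) warning("Kav outside the calibrated range: extrapolated molecular weight")
  x <- (k - cal$intercept) / cal$slope
  mw <- if (cal$form == "log10") 10^x else x
  attr(mw, "extrapolated") <- extra
  mw
}

#' Predicted elution volume for a molecular weight
#'
#' Forward evaluation of the calibration line, the inverse of
#' [apparent_mw()]; useful for building synthetic standards.
#'
#' @param mw_da molecular weight (Da), vectorised.
#' @param cal a [fit_calibration()] result (or a list with `slope`,
#'   `intercept`, `form`).
#' @param geom a [column_geometry()].
#' @return elution volume (mL).
#' @export
elution_volume <- function(mw_da, cal, geom = column_geometry()) {
  x <- if (cal$form == "log10") log10(mw_da) else mw_da
  k <- cal$intercept + cal$slope * x
  geom$V0 + k * (geom$Vc_col - geom$V0)
}
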