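# Bis-ANS surface-hydrophobicity analysis: reverse-titration calibration,
# conversion of forward titrations to Scatchard coordinates, and linear
# Scatchard estimation of site number n and dissociation constant KD
# (v = n - KD * v/S; intercept n, slope -KD).

#' Calibrate fluorescence against bound dye (reverse titration)
#'
#' In a reverse titration a small amount of dye is titrated into a large
#' protein excess, so essentially all dye is bound and the signal is linear
#' through the origin in total dye. The slope `phi` (a.u. per uM bound
#' dye) converts fluorescence to bound-dye concentration in forward
#' titrations.
#'
#' @param series A reverse-mode [titration_series()].
#' @return List of class `uvf_calibration`: `phi`, `stderr`, `r2`.
#' @export
calibrate_reverse <- function(series) {
  if (!inherits(series, "uvf_titration") || series$mode != "reverse")
    abort_uvf("`series` must be a reverse-mode titration",
              "uvf_invalid_input")
  x <- series$conc
  y <- series$signal
  if (sum(x^2) == 0)
    abort_uvf("reverse titration has no nonzero dye points",
              "uvf_calibration_failure")
  fit <- lm(y ~ 0 + x)
  phi <- unname(coef(fit)[1L])
  if (!is.finite(phi) || phi <= 0)
    abort_uvf("calibration slope is not positive", "uvf_calibration_failure")
  s <- suppressWarnings(summary(fit)) # noiseless data fits exactly
  tss <- sum(y^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else NA_real_
  structure(list(phi = phi, stderr = unname(s$coefficients[1L, 2L]),
                 r2 = r2),
            class = "uvf_calibration")
}

#' @export
print.uvf_calibration <- function(x, ...) {
  cat(sprintf("<calibration> phi = %.5g a.u./uM (se %.3g), r2 %.5f\n",
              x$phi, x$stderr, x$r2))
  invisible(x)
}

#' Convert a forward titration to Scatchard coordinates
#'
#' Bound dye B = signal / phi; binding density v = B per protein subunit;
#' free dye S = total - B. Points with S <= 0 (including the zero-dye
#' origin, where v/S is undefined) are dropped, not clamped, and counted.
#'
#' @param series A forward-mode [titration_series()] with `protein_uM` set.
#' @param cal A [calibrate_reverse()] calibration with `phi > 0`.
#' @return List with vectors `v`, `v_over_s`, plus `dropped` (count) and
#'   `points_used`.
#' @export
to_scatchard <- function(series, cal) {
  if (!inherits(series, "uvf_titration") || series$mode != "forward")
    abort_uvf("`series` must be a forward-mode titration",
              "uvf_invalid_input")
  if (!inherits(cal, "uvf_calibration") || cal$phi <= 0)
    abort_uvf("`cal` must be a valid calibration with phi > 0",
              "uvf_invalid_input")
  b <- series$signal / cal$phi
  s <- series$conc - b
  keep <- s > 0
  if (!any(keep))
    abort_uvf("no usable points: free ligand <= 0 everywhere",
              "uvf_no_usable_points")
  v <- b[keep] / series$protein_uM
  list(v = v, v_over_s = v / (s[keep] / 1), # v/S in uM^-1 * v units
       dropped = sum(!keep), points_used = sum(keep))
}

#' Scatchard regression
#'
#' Ordinary least squares of v on v/S: the intercept estimates the site
#' number n per subunit and the negative slope estimates KD (uM). A
#' nonnegative slope is a nonphysical fit; it is flagged and KD reported
#' as `NA`.
#'
#' @param v Binding densities (bound dye per subunit).
#' @param v_over_s v divided by free dye (uM^-1).
#' @return List of class `uvf_binding_fit`: `n`, `kd`, `stderr_n`,
#'   `stderr_kd`, `r2`, `points_used`, `nonphysical`.
#' @export
scatchard_fit <- function(v, v_over_s) {
  if (length(v) != length(v_over_s))
    abort_uvf("v and v_over_s must have equal length", "uvf_invalid_input")
  if (length(v) < 2L)
    abort_uvf("Scatchard regression needs >= 2 usable points",
              "uvf_insufficient_data")
  fit <- lm(v ~ v_over_s)
  cf <- coef(fit)
  n <- unname(cf[1L])
  slope <- unname(cf[2L])
  nonphysical <- !is.finite(slope) || slope >= 0
  kd <- if (nonphysical) NA_real_ else -slope
  se <- if (length(v) > 2L) {
    sm <- suppressWarnings(summary(fit))$coefficients
    c(sm[1L, 2L], sm[2L, 2L])
  } else c(NA_real_, NA_real_)
  pred <- fitted(fit)
  tss <- sum((v - mean(v))^2)
  r2 <- if (tss > 0) 1 - sum((v - pred)^2) / tss else NA_real_
  structure(list(n = n, kd = kd, stderr_n = se[1L], stderr_kd = se[2L],
                 r2 = r2, points_used = length(v),
                 nonphysical = nonphysical),
            class = "uvf_binding_fit")
}

#' @export
print.uvf_binding_fit <- function(x, ...) {
  cat(sprintf("<Scatchard fit> n = %.4g (se %.3g), KD = %.4g uM (se %.3g), r2 %.5f, %d points%s\n",
              x$n, x$stderr_n, x$kd, x$stderr_kd, x$r2, x$points_used,
              if (x$nonphysical) " [nonphysical slope]" else ""))
  invisible(x)
}

#' Direct nonlinear one-site binding fit
#'
#' Cross-check for the Scatchard regression: fits the raw forward-titration
#' signal to phi * B(n, KD) with B the exact identical-sites quadratic
#' root, avoiding the error distortion Scatchard linearization introduces
#' under noise.
#'
#' @param series A forward-mode [titration_series()].
#' @param cal A calibration supplying `phi`.
#' @return List of class `uvf_binding_fit` (stderr from the nonlinear fit).
#' @export
one_site_fit_direct <- function(series, cal) {
  if (!inherits(series, "uvf_titration") || series$mode != "forward")
    abort_uvf("`series` must be a forward-mode titration",
              "uvf_invalid_input")
  p <- series$protein_uM
  resid_fn <- function(par) {
    series$signal -
      cal$phi * bound_one_site(par[["n"]], p, series$conc, par[["kd"]])
  }
  # moment starts: saturation bound / protein for n, half-saturation for kd
  bmax <- max(series$signal) / cal$phi
  st <- c(n = max(bmax / p, 1e-3), kd = max(stats::median(series$conc), 0.1))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = st, fn = resid_fn, lower = c(1e-8, 1e-8),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit))
    abort_uvf("direct one-site fit failed", "uvf_fit_failure")
  cf <- coef(fit)
  cov <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else c(NA_real_, NA_real_)
  pred <- series$signal - resid_fn(cf)
  tss <- sum((series$signal - mean(series$signal))^2)
  structure(list(n = unname(cf[["n"]]), kd = unname(cf[["kd"]]),
                 stderr_n = unname(se[1L]), stderr_kd = unname(se[2L]),
                 r2 = if (tss > 0) 1 - deviance(fit) / tss else NA_real_,
                 points_used = length(series$conc), nonphysical = FALSE),
            class = "uvf_binding_fit")
}
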