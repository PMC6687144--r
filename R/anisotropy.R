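# Steady-state fluorescence anisotropy and protein-titration isotherms for
# labelled-oligo binding.

#' Steady-state anisotropy from polarized intensities
#'
#' A = (I_VV - G * I_VH) / (I_VV + 2 * G * I_VH), where I_VV and I_VH are
#' the vertically and horizontally polarized emission components and G the
#' instrument sensitivity factor. G has no safe default and must be given.
#'
#' @param i_vv,i_vh Nonnegative polarized intensities (a.u.).
#' @param g Instrument G factor, > 0.
#' @return Anisotropy value; always in `[-0.5, 1]` for valid inputs.
#' @examples
#' anisotropy(3, 1, g = 1) # 0.4
#' @export
anisotropy <- function(i_vv, i_vh, g) {
  if (missing(g))
    abort_uvf("instrument G factor must be supplied explicitly",
              "uvf_invalid_input")
  check_scalar(g, "g", positive = TRUE)
  if (any(!is.finite(i_vv)) || any(!is.finite(i_vh)) ||
      any(i_vv < 0) || any(i_vh < 0))
    abort_uvf("intensities must be finite and nonnegative",
              "uvf_invalid_input")
  denom <- i_vv + 2 * g * i_vh
  if (any(denom <= 0))
    abort_uvf("anisotropy denominator <= 0: no signal", "uvf_invalid_reading")
  (i_vv - g * i_vh) / denom
}

#' Fit a hyperbolic anisotropy binding isotherm
#'
#' Nonlinear least squares of y = y0 + Bmax * x / (KD + x) to anisotropy
#' versus total protein concentration, the estimator used for
#' fluorescein-labelled oligo titrations. The offset y0 is fixed at 0 by
#' default (`offset_mode = "free"` frees it). With `probe_uM` supplied, a
#' depletion-corrected mode replaces the free-ligand hyperbola by the
#' exact 1:1 quadratic bound fraction, which matters when the probe
#' concentration is far above KD; the default mirrors the simple
#' free-ligand estimator.
#'
#' @param conc_uM Protein concentrations, uM (should include ~0).
#' @param aniso Anisotropy values, same length; at least 4 points.
#' @param offset_mode `"zero"` (default) or `"free"`.
#' @param probe_uM Optional labelled-oligo concentration (uM) enabling the
#'   depletion-corrected quadratic isotherm.
#' @return List of class `uvf_aniso_fit`: `bmax`, `kd_nM`, `stderr_bmax`,
#'   `stderr_kd_nM`, `y0`, `r2`, `extrapolated` (TRUE if KD is more than
#'   10x beyond the titration range).
#' @export
fit_isotherm <- function(conc_uM, aniso, offset_mode = c("zero", "free"),
                         probe_uM = NULL) {
  offset_mode <- match.arg(offset_mode)
  if (inherits(conc_uM, "uvf_titration")) {
    series <- conc_uM
    conc_uM <- series$conc
    aniso <- series$signal
  }
  if (length(conc_uM) != length(aniso) || length(conc_uM) < 4L)
    abort_uvf("isotherm fit needs >= 4 matched points",
              "uvf_insufficient_data")
  if (min(conc_uM) > 0.05 * max(conc_uM))
    warn_uvf("titration does not include a near-zero protein point",
             "uvf_missing_origin")
  model_y <- function(par, x) {
    y0 <- if (offset_mode == "free") par[["y0"]] else 0
    if (is.null(probe_uM)) {
      y0 + par[["bmax"]] * x / (par[["kd"]] + x)
    } else {
      frac_bound <- bound_one_site(1, probe_uM, x, par[["kd"]]) / probe_uM
      y0 + par[["bmax"]] * frac_bound
    }
  }
  # half-saturation start for kd
  ymax <- max(aniso)
  i <- which.min(abs(aniso - ymax / 2))
  st <- c(bmax = max(ymax, 1e-6), kd = max(conc_uM[i], 1e-3))
  if (offset_mode == "free") st <- c(st, y0 = min(aniso))
  resid_fn <- function(par) aniso - model_y(par, conc_uM)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = st, fn = resid_fn,
                       lower = c(1e-10, 1e-10,
                                 if (offset_mode == "free") -Inf),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4)
    abort_uvf("isotherm fit failed to converge", "uvf_fit_failure")
  cf <- coef(fit)
  cov <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else
    rep(NA_real_, length(cf))
  names(se) <- names(cf)
  pred <- model_y(cf, conc_uM)
  tss <- sum((aniso - mean(aniso))^2)
  extrap <- cf[["kd"]] > 10 * max(conc_uM)
  if (extrap)
    warn_uvf("fitted KD lies more than 10x beyond the titration range",
             "uvf_extrapolation")
  structure(list(bmax = cf[["bmax"]], kd_nM = cf[["kd"]] * 1000,
                 stderr_bmax = se[["bmax"]],
                 stderr_kd_nM = se[["kd"]] * 1000,
                 y0 = if (offset_mode == "free") cf[["y0"]] else 0,
                 r2 = if (tss > 0) 1 - sum((aniso - pred)^2) / tss
                      else NA_real_,
                 extrapolated = extrap, offset_mode = offset_mode,
                 depletion_corrected = !is.null(probe_uM)),
            class = "uvf_aniso_fit")
}

#' @export
print.uvf_aniso_fit <- function(x, ...) {
  cat(sprintf("<anisotropy fit> Bmax = %.4g (se %.3g), KD = %.4g nM (se %.3g), r2 %.5f%s\n",
              x$bmax, x$stderr_bmax, x$kd_nM, x$stderr_kd_nM, x$r2,
              if (x$depletion_corrected) " [depletion-corrected]" else ""))
  invisible(x)
}
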