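# Spectrum preprocessing and single-spectrum analyses.

#' Interpolated intensity at an axis position
#'
#' Linear interpolation between the bracketing grid points; exact at grid
#' points. No smoothing is applied: reported peaks and point readouts come
#' from the raw scan.
#'
#' @param spec A [spectrum()].
#' @param x Axis position, must lie within the axis range.
#' @return Interpolated intensity.
#' @export
intensity_at <- function(spec, x) {
  if (!inherits(spec, "uvf_spectrum"))
    abort_uvf("`spec` must be a spectrum", "uvf_invalid_input")
  check_scalar(x, "x")
  if (x < min(spec$axis) || x > max(spec$axis))
    abort_uvf(sprintf("x = %g outside axis range [%g, %g]",
                      x, min(spec$axis), max(spec$axis)),
              "uvf_range_error")
  approx(spec$axis, spec$intensity, xout = x, method = "linear")$y
}

#' Emission maximum of a spectrum
#'
#' Axis position and value of the global intensity maximum. Ties break to
#' the smaller axis value so the result is deterministic; an all-flat
#' spectrum returns the smallest axis value with `degenerate = TRUE`.
#'
#' @param spec A [spectrum()].
#' @return List with `x_at_max`, `max_intensity`, `degenerate`.
#' @export
emission_max <- function(spec) {
  if (!inherits(spec, "uvf_spectrum"))
    abort_uvf("`spec` must be a spectrum", "uvf_invalid_input")
  i <- which.max(spec$intensity) # first maximum = smallest axis value
  list(x_at_max = spec$axis[i],
       max_intensity = spec$intensity[i],
       degenerate = length(unique(spec$intensity)) == 1L)
}

#' Normalize a spectrum per tryptophan residue
#'
#' Divides every intensity by the number of tryptophan residues recorded in
#' the metadata, giving fluorescence per tryptophan so constructs with
#' different Trp counts (6, 3 and 1 for the full-length and deletion forms)
#' can be compared. A second call on an already normalized spectrum is an
#' error (double-normalization guard).
#'
#' @param spec A [spectrum()] with `meta$n_trp >= 1`.
#' @return The normalized [spectrum()], flagged `meta$normalized = TRUE`.
#' @export
normalize_per_trp <- function(spec) {
  if (!inherits(spec, "uvf_spectrum"))
    abort_uvf("`spec` must be a spectrum", "uvf_invalid_input")
  if (isTRUE(spec$meta$normalized))
    abort_uvf("spectrum is already normalized per tryptophan",
              "uvf_invalid_input")
  n <- spec$meta$n_trp
  if (is.null(n) || !is.numeric(n) || length(n) != 1L || n < 1)
    abort_uvf("meta$n_trp missing or < 1", "uvf_invalid_input")
  spec$intensity <- spec$intensity / n
  spec$meta$normalized <- TRUE
  spec
}

#' Fractional intensity drop between two spectra
#'
#' (I_control(x) - I_treated(x)) / I_control(x): e.g. a control intensity
#' of 100 and a treated intensity of 80 at 340 nm is a drop of 0.20.
#'
#' @param control,treated Two [spectrum()] objects covering `x`.
#' @param x Axis position at which to compare.
#' @return Fractional drop (negative if the treated spectrum is brighter).
#' @export
intensity_drop <- function(control, treated, x) {
  ic <- intensity_at(control, x)
  it <- intensity_at(treated, x)
  if (ic <= 0)
    abort_uvf("control intensity <= 0 at x: drop undefined",
              "uvf_undefined_ratio")
  (ic - it) / ic
}

#' Stern-Volmer quenching fit
#'
#' Least-squares fit of F0/F = 1 + KSV * Q. By default the intercept is
#' fixed at 1 (the canonical Stern-Volmer form), so KSV is the
#' through-origin slope of (F0/F - 1) on Q; `fix_intercept = FALSE` frees
#' the intercept and reports both parameters. A negative fitted KSV
#' (fluorescence rising with quencher) sets the `nonphysical` flag.
#'
#' @param q A [quench_series()] with at least 3 points.
#' @param fix_intercept Fix the intercept at 1 (default TRUE).
#' @return List of class `uvf_quench_fit`: `ksv` (M^-1), `intercept`,
#'   `r2`, `nonphysical`.
#' @export
stern_volmer_fit <- function(q, fix_intercept = TRUE) {
  if (!inherits(q, "uvf_quench_series"))
    abort_uvf("`q` must be a quench_series", "uvf_invalid_input")
  if (length(q$quencher_conc) < 3L)
    abort_uvf("Stern-Volmer fit needs >= 3 points", "uvf_insufficient_data")
  x <- q$quencher_conc
  y <- q$f0_over_f
  if (fix_intercept) {
    ksv <- if (sum(x^2) > 0) sum(x * (y - 1)) / sum(x^2) else 0
    intercept <- 1
  } else {
    fit <- lm(y ~ x)
    ksv <- unname(coef(fit)[2L])
    intercept <- unname(coef(fit)[1L])
  }
  pred <- intercept + ksv * x
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - sum((y - pred)^2) / tss)) else 1
  structure(list(ksv = ksv, intercept = intercept, r2 = r2,
                 nonphysical = ksv < 0),
            class = "uvf_quench_fit")
}

#' @export
print.uvf_quench_fit <- function(x, ...) {
  cat(sprintf("<Stern-Volmer fit> KSV = %.4g M^-1, intercept %.4g, r2 %.4f%s\n",
              x$ksv, x$intercept, x$r2,
              if (x$nonphysical) " [nonphysical: KSV < 0]" else ""))
  invisible(x)
}

#' Band peak position inside a window
#'
#' Axis position of the maximum intensity inside `[lo, hi]`, as used to
#' locate the FT-IR amide-I band (near 1640 cm-1 for helical protein,
#' shifting toward 1660 cm-1 on conformational change). A flat window
#' returns the smallest axis value with attribute `degenerate = TRUE`.
#'
#' @param spec A [spectrum()].
#' @param window Numeric `c(lo, hi)` inside the axis range.
#' @return Axis position of the in-window maximum.
#' @export
band_peak <- function(spec, window) {
  if (!inherits(spec, "uvf_spectrum"))
    abort_uvf("`spec` must be a spectrum", "uvf_invalid_input")
  if (length(window) != 2L || window[1L] >= window[2L])
    abort_uvf("`window` must be c(lo, hi) with lo < hi", "uvf_invalid_input")
  sel <- spec$axis >= window[1L] & spec$axis <= window[2L]
  if (!any(sel))
    abort_uvf("window contains no axis points", "uvf_invalid_input")
  xs <- spec$axis[sel]
  ys <- spec$intensity[sel]
  out <- xs[which.max(ys)]
  if (length(unique(ys)) == 1L) attr(out, "degenerate") <- TRUE
  out
}

#' CD secondary-structure fractions
#'
#' Secondary-structure composition (fractions of helix, sheet, turn,
#' unordered).
#'
#' @param helix,sheet,turn,unordered Fractions in `[0, 1]` summing to 1.
#' @return An object of class `uvf_cd_fractions`.
#' @export
cd_fractions <- function(helix, sheet, turn, unordered) {
  f <- c(helix = helix, sheet = sheet, turn = turn, unordered = unordered)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    abort_uvf("fractions must lie in [0, 1]", "uvf_invalid_input")
  if (abs(sum(f) - 1) > 1e-9)
    abort_uvf("fractions must sum to 1", "uvf_invalid_input")
  structure(as.list(f), class = "uvf_cd_fractions")
}

#' @export
print.uvf_cd_fractions <- function(x, ...) {
  cat(sprintf(
    "<CD fractions> helix %.3f, sheet %.3f, turn %.3f, unordered %.3f\n",
    x$helix, x$sheet, x$turn, x$unordered))
  invisible(x)
}

#' Constrained CD decomposition
#'
#' Estimates secondary-structure fractions by nonnegative least squares of
#' the spectrum against four basis spectra, followed by renormalization to
#' unit sum. The output always satisfies nonnegativity and unit sum,
#' whatever the input spectrum.
#'
#' @param spec A [spectrum()] on the basis grid.
#' @param basis List of 4 basis spectra (default [cd_basis_spectra()]),
#'   in the order helix, sheet, turn, unordered.
#' @return A [cd_fractions()] object.
#' @export
cd_fraction_fit <- function(spec, basis = cd_basis_spectra()) {
  if (!inherits(spec, "uvf_spectrum"))
    abort_uvf("`spec` must be a spectrum", "uvf_invalid_input")
  if (length(basis) != 4L)
    abort_uvf("`basis` must contain 4 spectra", "uvf_invalid_input")
  grid <- basis[[1L]]$axis
  for (b in basis)
    if (!isTRUE(all.equal(b$axis, grid)))
      abort_uvf("basis spectra must share one grid", "uvf_invalid_input")
  if (!isTRUE(all.equal(spec$axis, grid)))
    abort_uvf("spectrum must be on the basis grid", "uvf_invalid_input")
  A <- vapply(basis, function(b) b$intensity, numeric(length(grid)))
  if (qr(A)$rank < 4L)
    abort_uvf("basis spectra are rank deficient", "uvf_ill_conditioned")
  w <- pracma::lsqnonneg(A, spec$intensity)$x
  if (sum(w) <= 0)
    # spectrum orthogonal to (or opposing) every basis shape: report the
    # uninformative uniform composition rather than 0/0
    w <- rep(1, 4L)
  w <- w / sum(w)
  cd_fractions(w[1L], w[2L], w[3L], w[4L])
}
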