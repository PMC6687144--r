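# Core containers. Lightweight S3 lists with validating constructors; every
# downstream operation assumes the invariants enforced here.

#' Construct a spectrum
#'
#' A single emission or absorbance scan: a strictly increasing axis (nm for
#' fluorescence/CD, cm-1 for FT-IR) with one intensity per axis point and
#' acquisition metadata.
#'
#' @param axis Strictly increasing numeric vector of axis values.
#' @param intensity Numeric vector, same length as `axis`, all finite.
#' @param unit Axis unit, `"nm"` or `"cm-1"`.
#' @param meta Named list of acquisition metadata. Recognised keys:
#'   `sample_id`, `excitation_nm`, `dose_Jm2`, `hours`, `n_trp`,
#'   `normalized` (logical flag set by [normalize_per_trp()]).
#' @return An object of class `uvf_spectrum`.
#' @export
spectrum <- function(axis, intensity, unit = c("nm", "cm-1"), meta = list()) {
  unit <- match.arg(unit)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) == 0L)
    abort_uvf("spectrum axis is empty", "uvf_invalid_input")
  if (length(axis) != length(intensity))
    abort_uvf("axis and intensity lengths differ", "uvf_invalid_input")
  if (any(!is.finite(axis)) || any(diff(axis) <= 0))
    abort_uvf("spectrum axis must be finite and strictly increasing",
              "uvf_invalid_input")
  if (any(!is.finite(intensity)))
    abort_uvf("spectrum intensities must be finite", "uvf_invalid_input")
  structure(list(axis = axis, intensity = intensity, unit = unit,
                 meta = meta),
            class = "uvf_spectrum")
}

#' @export
print.uvf_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.6g-%.6g %s\n",
              length(x$axis), min(x$axis), max(x$axis), x$unit))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a titration series
#'
#' Paired concentration/signal vectors for dye titrations (forward or
#' reverse), quenching experiments or anisotropy isotherms.
#'
#' @param conc Nonnegative, strictly increasing concentration vector
#'   (micromolar for dye/protein titrations).
#' @param signal Signal vector (fluorescence a.u. or anisotropy units),
#'   same length as `conc`.
#' @param protein_uM Protein subunit concentration in micromolar; required
#'   (> 0) for forward dye titrations, may be `NA` otherwise.
#' @param mode One of `"forward"`, `"reverse"`, `"anisotropy"`.
#' @return An object of class `uvf_titration`.
#' @export
titration_series <- function(conc, signal, protein_uM = NA_real_,
                             mode = c("forward", "reverse", "anisotropy")) {
  mode <- match.arg(mode)
  conc <- as.numeric(conc)
  signal <- as.numeric(signal)
  if (length(conc) == 0L || length(conc) != length(signal))
    abort_uvf("conc and signal must be nonempty and of equal length",
              "uvf_invalid_input")
  if (any(!is.finite(conc)) || any(conc < 0))
    abort_uvf("concentrations must be finite and nonnegative",
              "uvf_invalid_input")
  if (any(diff(conc) <= 0))
    abort_uvf("concentrations must be strictly increasing",
              "uvf_invalid_input")
  if (mode == "forward" && (!is.finite(protein_uM) || protein_uM <= 0))
    abort_uvf("forward titrations require protein_uM > 0",
              "uvf_invalid_input")
  structure(list(conc = conc, signal = signal, protein_uM = protein_uM,
                 mode = mode),
            class = "uvf_titration")
}

#' @export
print.uvf_titration <- function(x, ...) {
  cat(sprintf("<titration:%s> %d points, conc %.4g-%.4g uM\n",
              x$mode, length(x$conc), min(x$conc), max(x$conc)))
  invisible(x)
}

#' Construct an equilibrium unfolding curve
#'
#' Denaturant grid with the I337/I350 tryptophan-fluorescence intensity
#' ratio, the observable used to follow urea-induced unfolding.
#'
#' @param urea_M Nonnegative, strictly increasing urea concentrations (M).
#' @param ratio I337/I350 ratio at each urea concentration.
#' @param temperature_K Temperature in kelvin (default 298.15, i.e. 25 C).
#' @return An object of class `uvf_unfolding_curve`.
#' @export
unfolding_curve <- function(urea_M, ratio, temperature_K = 298.15) {
  urea_M <- as.numeric(urea_M)
  ratio <- as.numeric(ratio)
  if (length(urea_M) == 0L || length(urea_M) != length(ratio))
    abort_uvf("urea_M and ratio must be nonempty and of equal length",
              "uvf_invalid_input")
  if (any(!is.finite(urea_M)) || any(urea_M < 0) || any(diff(urea_M) <= 0))
    abort_uvf("urea_M must be nonnegative and strictly increasing",
              "uvf_invalid_input")
  check_scalar(temperature_K, "temperature_K", positive = TRUE)
  structure(list(urea_M = urea_M, ratio = ratio,
                 temperature_K = temperature_K),
            class = "uvf_unfolding_curve")
}

#' Construct an aggregation trace
#'
#' Turbidity (OD at 360 nm) followed over time, typically 0-120 min.
#'
#' @param time_min Strictly increasing times in minutes.
#' @param od360 Nonnegative optical densities, same length.
#' @return An object of class `uvf_aggregation_trace`.
#' @export
aggregation_trace <- function(time_min, od360) {
  time_min <- as.numeric(time_min)
  od360 <- as.numeric(od360)
  if (length(time_min) == 0L || length(time_min) != length(od360))
    abort_uvf("time_min and od360 must be nonempty and of equal length",
              "uvf_invalid_input")
  if (any(diff(time_min) <= 0))
    abort_uvf("time_min must be strictly increasing", "uvf_invalid_input")
  if (any(!is.finite(od360)) || any(od360 < 0))
    abort_uvf("od360 must be finite and nonnegative", "uvf_invalid_input")
  structure(list(time_min = time_min, od360 = od360),
            class = "uvf_aggregation_trace")
}

#' Construct a DLS size distribution
#'
#' Intensity-weighted hydrodynamic-radius distribution over increasing bin
#' centres; fractions must sum to one.
#'
#' @param rh_nm Strictly increasing bin centres (nm).
#' @param intensity_frac Fractions in `[0, 1]` summing to 1 (tolerance 1e-9).
#' @return An object of class `uvf_dls`.
#' @export
dls_distribution <- function(rh_nm, intensity_frac) {
  rh_nm <- as.numeric(rh_nm)
  intensity_frac <- as.numeric(intensity_frac)
  if (length(rh_nm) == 0L || length(rh_nm) != length(intensity_frac))
    abort_uvf("rh_nm and intensity_frac must be nonempty and equal length",
              "uvf_invalid_input")
  if (any(diff(rh_nm) <= 0) || any(rh_nm <= 0))
    abort_uvf("rh_nm must be positive and strictly increasing",
              "uvf_invalid_input")
  if (any(intensity_frac < 0) || any(intensity_frac > 1))
    abort_uvf("intensity fractions must lie in [0, 1]", "uvf_invalid_input")
  if (abs(sum(intensity_frac) - 1) > 1e-9)
    abort_uvf("intensity fractions must sum to 1", "uvf_invalid_input")
  structure(list(rh_nm = rh_nm, intensity_frac = intensity_frac),
            class = "uvf_dls")
}

#' Construct a promoter record
#'
#' A promoter fragment whose 3' end sits immediately 5' of the transcription
#' start site: the last base is position -1, the TSS is +1 and there is no
#' position 0.
#'
#' @param id Sequence identifier.
#' @param sequence A/C/G/T/N string (lowercase accepted, uppercased).
#' @return An object of class `uvf_promoter`.
#' @export
promoter_record <- function(id, sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) < 1L)
    abort_uvf("sequence must be a nonempty string", "uvf_invalid_input")
  seq_up <- toupper(sequence)
  if (grepl("[^ACGTN]", seq_up)) {
    bad <- regmatches(seq_up, regexpr("[^ACGTN]", seq_up))
    abort_uvf(sprintf("invalid nucleotide character '%s' in sequence '%s'",
                      bad, id),
              "uvf_invalid_alphabet")
  }
  structure(list(id = as.character(id), sequence = seq_up,
                 length = nchar(seq_up)),
            class = "uvf_promoter")
}

#' @export
print.uvf_promoter <- function(x, ...) {
  cat(sprintf("<promoter> %s, %d bp (positions -%d..-1, TSS = +1)\n",
              x$id, x$length, x$length))
  invisible(x)
}

#' Construct a quenching series
#'
#' Stern-Volmer data: quencher concentrations with the ratio of unquenched
#' to quenched fluorescence, F0/F.
#'
#' @param quencher_conc Nonnegative, strictly increasing concentrations (M).
#' @param f0_over_f F0/F ratios, same length (values >= 1 expected for a
#'   quencher; smaller values are allowed but flagged by the fit).
#' @return An object of class `uvf_quench_series`.
#' @export
quench_series <- function(quencher_conc, f0_over_f) {
  quencher_conc <- as.numeric(quencher_conc)
  f0_over_f <- as.numeric(f0_over_f)
  if (length(quencher_conc) == 0L ||
      length(quencher_conc) != length(f0_over_f))
    abort_uvf("quencher_conc and f0_over_f must be equal length",
              "uvf_invalid_input")
  if (any(quencher_conc < 0) || any(diff(quencher_conc) <= 0))
    abort_uvf("quencher_conc must be nonnegative and strictly increasing",
              "uvf_invalid_input")
  structure(list(quencher_conc = quencher_conc, f0_over_f = f0_over_f),
            class = "uvf_quench_series")
}
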