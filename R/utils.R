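# Internal helpers: classed conditions, seeded RNG, unit conversion.

abort_uvf <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "uvf_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

warn_uvf <- function(msg, class) {
  warning(structure(
    class = c(class, "uvf_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Evaluate expr with a private RNG stream; global .Random.seed is untouched.
with_gen_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_uvf(sprintf("`%s` must be a finite numeric scalar", name),
              "uvf_invalid_input")
  if (positive && x <= 0)
    abort_uvf(sprintf("`%s` must be > 0", name), "uvf_invalid_input")
  if (nonnegative && x < 0)
    abort_uvf(sprintf("`%s` must be >= 0", name), "uvf_invalid_input")
  invisible(x)
}

#' Convert a mass concentration to micromolar subunit concentration
#'
#' Protein stocks are usually quantified in mg/ml while binding models work
#' in molar subunit units. For the AtMYB4 constructs the monomer masses are
#' 32 kDa (full length), 24 kDa (single N-terminal MYB repeat deleted) and
#' 18 kDa (both repeats deleted).
#'
#' @param mgml Mass concentration in mg/ml.
#' @param mass_kDa Monomer molecular mass in kDa.
#' @return Subunit concentration in micromolar.
#' @examples
#' mgml_to_uM(0.02, 32) # 0.625 uM full-length subunits
#' @export
mgml_to_uM <- function(mgml, mass_kDa) {
  check_scalar(mass_kDa, "mass_kDa", positive = TRUE)
  if (any(!is.finite(mgml)) || any(mgml < 0))
    abort_uvf("`mgml` must be finite and nonnegative", "uvf_invalid_input")
  mgml / mass_kDa * 1000
}

#' Residue count of a coding sequence
#'
#' Counts the amino acids encoded by an open reading frame. A terminal stop
#' codon (TAA, TAG or TGA) is not counted as a residue, so an 849-nt CDS
#' ending in a stop encodes 849/3 - 1 = 282 residues.
#'
#' @param x Either a DNA sequence (character scalar, A/C/G/T) whose length is
#'   a multiple of 3, or a single numeric length in nucleotides (assumed to
#'   include a terminal stop).
#' @return Integer residue count.
#' @examples
#' orf_residue_count(849)
#' orf_residue_count("ATGGCCTAA") # 2 residues
#' @export
orf_residue_count <- function(x) {
  stops <- c("TAA", "TAG", "TGA")
  if (is.numeric(x)) {
    check_scalar(x, "x", positive = TRUE)
    if (x %% 3 != 0)
      abort_uvf("coding-sequence length must be a multiple of 3",
                "uvf_invalid_input")
    return(as.integer(x / 3 - 1))
  }
  if (!is.character(x) || length(x) != 1L)
    abort_uvf("`x` must be a DNA string or a numeric length",
              "uvf_invalid_input")
  s <- toupper(x)
  n <- nchar(s)
  if (n %% 3 != 0)
    abort_uvf("coding-sequence length must be a multiple of 3",
              "uvf_invalid_input")
  if (grepl("[^ACGT]", s))
    abort_uvf("coding sequence may contain only A/C/G/T", "uvf_invalid_input")
  last <- substr(s, n - 2, n)
  as.integer(n / 3 - if (last %in% stops) 1L else 0L)
}
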