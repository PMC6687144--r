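# Seeded synthetic-data generators. Each emulates the statistical structure
# of one assay so that every downstream fitting stage can be validated by a
# parameter-recovery round trip. Noise is additive i.i.d. Gaussian in signal
# units; noise_sd = 0 returns the deterministic model curve exactly.

#' Generator configuration
#'
#' Shared configuration for all synthetic-data generators: an explicit RNG
#' seed (no global state is consumed or altered), the noise standard
#' deviation in the units of the generated signal, and an optional
#' generator-specific grid (wavelength nm, concentration uM/M, or time min).
#'
#' @param seed Integer RNG seed.
#' @param noise_sd Nonnegative Gaussian noise SD in signal units.
#' @param grid Optional ordered numeric grid; each generator supplies its
#'   assay's default when `NULL`.
#' @return An object of class `uvf_gen_config`.
#' @export
generator_config <- function(seed = 1L, noise_sd = 0, grid = NULL) {
  check_scalar(seed, "seed")
  check_scalar(noise_sd, "noise_sd", nonnegative = TRUE)
  if (!is.null(grid)) {
    grid <- as.numeric(grid)
    if (length(grid) == 0L)
      abort_uvf("grid must be nonempty when supplied", "uvf_invalid_input")
    if (any(!is.finite(grid)) || any(diff(grid) <= 0))
      abort_uvf("grid must be finite and strictly increasing",
                "uvf_invalid_input")
  }
  structure(list(seed = as.integer(seed), noise_sd = noise_sd, grid = grid),
            class = "uvf_gen_config")
}

gen_noise <- function(cfg, n) {
  if (cfg$noise_sd == 0) return(numeric(n))
  with_gen_seed(cfg$seed, rnorm(n, sd = cfg$noise_sd))
}

gen_grid <- function(cfg, default) {
  g <- if (is.null(cfg$grid)) default else cfg$grid
  if (length(g) == 0L) abort_uvf("empty grid", "uvf_invalid_input")
  g
}

#' Simulate a tryptophan emission spectrum
#'
#' Gaussian emission band centred near 340 nm whose peak amplitude decays
#' exponentially with UV-B exposure time, emulating photo-oxidative loss of
#' tryptophan fluorescence at constant emission maximum.
#'
#' @param center_nm Band centre (nm), default 340.
#' @param amplitude Peak amplitude at zero exposure (a.u.).
#' @param width_nm Gaussian SD of the band (nm), > 0.
#' @param n_trp Number of tryptophan residues in the construct (6 for the
#'   full-length protein, 3 and 1 for the deletion constructs).
#' @param uvb_hours Hours of UV-B exposure (dose 200 J/m2 convention).
#' @param decay_rate Amplitude decay rate per hour.
#' @param cfg A [generator_config()]; default grid 300-400 nm at 1 nm.
#' @return A [spectrum()] with metadata recording `n_trp`, `hours` and dose.
#' @export
gen_trp_spectrum <- function(center_nm = 340, amplitude = 100,
                             width_nm = 25, n_trp = 6L, uvb_hours = 0,
                             decay_rate = 0,
                             cfg = generator_config()) {
  check_scalar(width_nm, "width_nm", positive = TRUE)
  check_scalar(uvb_hours, "uvb_hours", nonnegative = TRUE)
  check_scalar(decay_rate, "decay_rate")
  x <- gen_grid(cfg, seq(300, 400, by = 1))
  peak <- amplitude * exp(-decay_rate * uvb_hours)
  y <- peak * exp(-(x - center_nm)^2 / (2 * width_nm^2)) +
    gen_noise(cfg, length(x))
  spectrum(x, y, unit = "nm",
           meta = list(excitation_nm = 295, dose_Jm2 = 200,
                       hours = uvb_hours, n_trp = as.integer(n_trp)))
}

#' Simulate a kynurenine emission spectrum
#'
#' Single emission band near 450 nm, the signature of tryptophan
#' photo-oxidation products (N-formylkynurenine/kynurenine) excited at
#' 365 nm.
#'
#' @param center_nm Band centre (nm), default 450.
#' @param amplitude Peak amplitude (a.u.).
#' @param width_nm Gaussian SD (nm), > 0.
#' @param cfg A [generator_config()]; default grid 390-530 nm at 1 nm.
#' @return A [spectrum()].
#' @export
gen_kynurenine_spectrum <- function(center_nm = 450, amplitude = 10,
                                    width_nm = 35,
                                    cfg = generator_config()) {
  check_scalar(width_nm, "width_nm", positive = TRUE)
  x <- gen_grid(cfg, seq(390, 530, by = 1))
  y <- amplitude * exp(-(x - center_nm)^2 / (2 * width_nm^2)) +
    gen_noise(cfg, length(x))
  spectrum(x, y, unit = "nm", meta = list(excitation_nm = 365))
}

# Bound ligand for n identical independent sites per subunit:
# exact root of B^2 - (nP + S + KD) B + nP S = 0 (the physical branch).
bound_one_site <- function(n_sites, protein_uM, s_tot_uM, kd_uM) {
  a <- n_sites * protein_uM + s_tot_uM + kd_uM
  b <- (a - sqrt(a^2 - 4 * n_sites * protein_uM * s_tot_uM)) / 2
  pmin(b, pmin(n_sites * protein_uM, s_tot_uM)) # guard rounding
}

#' Simulate a forward Bis-ANS titration
#'
#' One-site mass-action binding of the hydrophobic probe Bis-ANS to n
#' identical independent sites per protein subunit. For each total dye
#' concentration the bound amount is the exact root of the identical-sites
#' quadratic and the fluorescence signal is `phi` times the bound
#' concentration.
#'
#' @param n_sites Sites per subunit (dimensionless).
#' @param kd_uM Dissociation constant, uM, > 0.
#' @param protein_uM Protein subunit concentration, uM.
#' @param phi Fluorescence yield, a.u. per uM bound dye.
#' @param dye_grid_uM Total dye grid, uM; default 0-30 uM in 31 steps.
#' @param cfg A [generator_config()].
#' @return A forward-mode [titration_series()].
#' @export
gen_bisans_titration <- function(n_sites, kd_uM, protein_uM, phi = 50,
                                 dye_grid_uM = seq(0, 30, by = 1),
                                 cfg = generator_config()) {
  check_scalar(n_sites, "n_sites", positive = TRUE)
  check_scalar(kd_uM, "kd_uM", positive = TRUE)
  check_scalar(protein_uM, "protein_uM", positive = TRUE)
  if (any(dye_grid_uM < 0))
    abort_uvf("dye concentrations must be nonnegative", "uvf_invalid_input")
  x <- gen_grid(cfg, dye_grid_uM)
  b <- bound_one_site(n_sites, protein_uM, x, kd_uM)
  y <- phi * b + gen_noise(cfg, length(x))
  titration_series(x, y, protein_uM = protein_uM, mode = "forward")
}

#' Simulate a reverse Bis-ANS titration
#'
#' Calibration design: a small fixed amount of dye titrated into a large
#' protein excess so that essentially all dye is bound; the signal is then
#' linear through the origin with slope `phi`.
#'
#' @param phi Fluorescence yield, a.u. per uM bound dye.
#' @param dye_grid_uM Total dye grid, uM; default 0-0.2 uM in 9 steps,
#'   mirroring a 0.2 uM dye titration against 4-10 mg/ml protein.
#' @param cfg A [generator_config()].
#' @return A reverse-mode [titration_series()].
#' @export
gen_bisans_reverse <- function(phi = 50,
                               dye_grid_uM = seq(0, 0.2, length.out = 9),
                               cfg = generator_config()) {
  check_scalar(phi, "phi")
  x <- gen_grid(cfg, dye_grid_uM)
  y <- phi * x + gen_noise(cfg, length(x))
  titration_series(x, y, mode = "reverse")
}

#' Simulate an equilibrium urea-unfolding curve
#'
#' I337/I350 ratio over a denaturant grid (default 0-8 M urea at 0.5 M
#' steps, 17 points) under the two- or three-state linear extrapolation
#' model of [predict_unfolding_signal()].
#'
#' @param model `"three_state"` or `"two_state"`.
#' @param params Named list of true parameters (three-state: `dG1`, `dG2`,
#'   `m1`, `m2` in kJ/mol(/M), baselines `yN`, `yI`, `yU`; two-state:
#'   `dG0`, `m`, `yN`, `yU`). A missing key raises an error naming it.
#' @param temperature_K Temperature, K.
#' @param cfg A [generator_config()].
#' @return An [unfolding_curve()].
#' @export
gen_unfolding_curve <- function(model = c("three_state", "two_state"),
                                params, temperature_K = 298.15,
                                cfg = generator_config()) {
  model <- match.arg(model)
  x <- gen_grid(cfg, seq(0, 8, by = 0.5))
  y <- predict_unfolding_signal(params, x, model, temperature_K) +
    gen_noise(cfg, length(x))
  unfolding_curve(x, y, temperature_K = temperature_K)
}

#' Simulate a fluorescence-anisotropy binding isotherm
#'
#' Hyperbolic one-site isotherm y = Bmax * x / (KD + x) over a protein
#' concentration grid (default 0-1.4 uM, the titration range used for the
#' fluorescein-labelled MYB4 oligos).
#'
#' @param bmax Maximum anisotropy, > 0.
#' @param kd_nM Dissociation constant in nM, > 0 (converted to uM
#'   internally).
#' @param conc_grid_uM Protein concentration grid, uM.
#' @param cfg A [generator_config()].
#' @return An anisotropy-mode [titration_series()].
#' @export
gen_anisotropy_curve <- function(bmax, kd_nM,
                                 conc_grid_uM = seq(0, 1.4,
                                                    length.out = 15),
                                 cfg = generator_config()) {
  check_scalar(bmax, "bmax", positive = TRUE)
  check_scalar(kd_nM, "kd_nM", positive = TRUE)
  x <- gen_grid(cfg, conc_grid_uM)
  kd_uM <- kd_nM / 1000
  y <- bmax * x / (kd_uM + x) + gen_noise(cfg, length(x))
  titration_series(x, y, mode = "anisotropy")
}

#' Simulate a light-scattering aggregation trace
#'
#' Single-exponential approach of OD(360 nm) from `baseline` to `plateau`
#' over 0-120 min: OD(t) = baseline + (plateau - baseline)(1 - e^(-rate t)).
#'
#' @param baseline Initial OD.
#' @param plateau Final OD.
#' @param rate Aggregation rate per minute, >= 0.
#' @param cfg A [generator_config()]; default grid 0-120 min at 2 min.
#' @return An [aggregation_trace()].
#' @export
gen_aggregation_trace <- function(baseline = 0.1, plateau = 0.3,
                                  rate = 0.05,
                                  cfg = generator_config()) {
  check_scalar(baseline, "baseline", nonnegative = TRUE)
  check_scalar(plateau, "plateau", nonnegative = TRUE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate < 0)
    abort_uvf("`rate` must be >= 0", "uvf_invalid_input")
  t <- gen_grid(cfg, seq(0, 120, by = 2))
  y <- baseline + (plateau - baseline) * (1 - exp(-rate * t)) +
    gen_noise(cfg, length(t))
  aggregation_trace(t, pmax(y, 0))
}

#' Simulate a promoter with planted cis-elements
#'
#' Random background sequence at a given GC content with motif instances
#' written at stated TSS-relative upstream positions. The sequence's last
#' base is position -1; the TSS is +1 (no position 0). With
#' `mask_accidental = TRUE` (default) any chance background match to a
#' planted motif outside its planted window is rejection-resampled, so
#' planted-position recovery by [scan_motifs()] is well defined.
#'
#' @param length Promoter length in bp.
#' @param planted List of `list(motif =, pos =)` entries; `pos` is the
#'   upstream (negative) position of the motif's 5'-most base. Sites must
#'   fit inside the sequence and must not overlap.
#' @param gc Background GC fraction in `[0, 1]`.
#' @param mask_accidental Mask chance background matches (default TRUE).
#' @param id Sequence identifier.
#' @param cfg A [generator_config()].
#' @return A [promoter_record()] with attribute `planted`.
#' @export
gen_promoter <- function(length = 1000L, planted = list(), gc = 0.4,
                         mask_accidental = TRUE, id = "synthetic_promoter",
                         cfg = generator_config()) {
  check_scalar(length, "length", positive = TRUE)
  check_scalar(gc, "gc", nonnegative = TRUE)
  if (gc > 1) abort_uvf("`gc` must be <= 1", "uvf_invalid_input")
  L <- as.integer(length)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  # validate plants: upstream pos -L..-1, motif must fit, no overlap
  windows <- list()
  for (p in planted) {
    if (is.null(p$motif) || is.null(p$pos))
      abort_uvf("each planted entry needs `motif` and `pos`",
                "uvf_invalid_input")
    motif <- toupper(p$motif)
    if (grepl("[^ACGT]", motif))
      abort_uvf("planted motifs must be concrete A/C/G/T strings",
                "uvf_invalid_input")
    start <- p$pos + L + 1L            # upstream pos -> 1-based index
    end <- start + nchar(motif) - 1L
    if (p$pos >= 0 || start < 1L || end > L)
      abort_uvf(sprintf("planted motif at %d does not fit inside [-%d, -1]",
                        p$pos, L),
                "uvf_invalid_input")
    windows[[length(windows) + 1L]] <-
      list(motif = motif, start = start, end = end, pos = p$pos)
  }
  if (length(windows) > 1L) {
    iv <- do.call(rbind, lapply(windows, function(w) c(w$start, w$end)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
      abort_uvf("planted motifs overlap", "uvf_invalid_input")
  }
  seq_chr <- with_gen_seed(cfg$seed, {
    bases <- sample(names(probs), L, replace = TRUE, prob = probs)
    for (w in windows)
      bases[w$start:w$end] <- strsplit(w$motif, "")[[1L]]
    if (mask_accidental && length(windows)) {
      planted_idx <- unlist(lapply(windows, function(w) w$start:w$end))
      for (iter in 1:100) {
        s <- paste(bases, collapse = "")
        clash <- integer()
        for (w in windows) {
          k <- nchar(w$motif)
          starts <- seq_len(L - k + 1L)
          m <- starts[substring(s, starts, starts + k - 1L) == w$motif]
          for (st in m) {
            if (st == w$start) next
            clash <- c(clash, setdiff(st:(st + k - 1L), planted_idx))
          }
        }
        clash <- unique(clash)
        if (!length(clash)) break
        bases[clash] <- sample(names(probs), length(clash),
                               replace = TRUE, prob = probs)
      }
    }
    paste(bases, collapse = "")
  })
  rec <- promoter_record(id, seq_chr)
  attr(rec, "planted") <- lapply(windows, function(w)
    list(motif = w$motif, pos = w$pos))
  rec
}

#' Simulate a DLS size distribution
#'
#' Two-component intensity-weighted hydrodynamic-radius distribution over
#' log-spaced bins: a monomer mode (default 1.8 nm, inside the "up to 2 nm"
#' monomer range) and an aggregate mode, mixed by `aggregate_fraction`.
#' Fractions always sum to one.
#'
#' @param monomer_rh_nm Monomer mode radius, nm.
#' @param aggregate_rh_nm Aggregate mode radius, nm.
#' @param aggregate_fraction Intensity fraction of the aggregate mode in
#'   `[0, 1]`.
#' @param cfg A [generator_config()]; default grid: 60 log-spaced bins over
#'   0.3-1000 nm.
#' @return A [dls_distribution()].
#' @export
gen_dls_distribution <- function(monomer_rh_nm = 1.8,
                                 aggregate_rh_nm = 30,
                                 aggregate_fraction = 0,
                                 cfg = generator_config()) {
  check_scalar(monomer_rh_nm, "monomer_rh_nm", positive = TRUE)
  check_scalar(aggregate_rh_nm, "aggregate_rh_nm", positive = TRUE)
  if (!is.numeric(aggregate_fraction) || length(aggregate_fraction) != 1L ||
      !is.finite(aggregate_fraction) ||
      aggregate_fraction < 0 || aggregate_fraction > 1)
    abort_uvf("`aggregate_fraction` must lie in [0, 1]", "uvf_invalid_input")
  rh <- gen_grid(cfg, exp(seq(log(0.3), log(1000), length.out = 60L)))
  comp <- function(mu, sd) exp(-(log(rh) - log(mu))^2 / (2 * sd^2))
  w <- (1 - aggregate_fraction) * comp(monomer_rh_nm, 0.15) +
    aggregate_fraction * comp(aggregate_rh_nm, 0.25)
  if (cfg$noise_sd > 0)
    w <- pmax(w + gen_noise(cfg, length(w)), 0)
  if (sum(w) <= 0)
    abort_uvf("degenerate DLS distribution (zero total intensity)",
              "uvf_invalid_input")
  dls_distribution(rh, w / sum(w))
}

#' Synthetic circular-dichroism basis spectra
#'
#' Four smooth, linearly independent far-UV CD reference shapes over
#' 200-260 nm, standing for alpha-helix, beta-sheet, turn and unordered
#' structure. These are synthetic curves built from Gaussian bands with the
#' qualitative features of each class (helix: double minima near 208/222
#' nm; sheet: single minimum near 218 nm; unordered: strong negative
#' shoulder toward 200 nm); they are a self-contained fixture for
#' decomposition round trips, not an experimental reference set.
#'
#' @param grid Wavelength grid, nm (default 200-260 at 1 nm).
#' @return Named list of four [spectrum()] objects: `helix`, `sheet`,
#'   `turn`, `unordered`.
#' @export
cd_basis_spectra <- function(grid = seq(200, 260, by = 1)) {
  g <- function(center, width) exp(-(grid - center)^2 / (2 * width^2))
  list(
    helix = spectrum(grid, -10 * (g(208, 6) + g(222, 6)) + 2 * g(195, 8),
                     meta = list(sample_id = "synthetic_helix_basis")),
    sheet = spectrum(grid, -8 * g(218, 9) + 4 * g(198, 6),
                     meta = list(sample_id = "synthetic_sheet_basis")),
    turn = spectrum(grid, 5 * g(206, 7) - 2 * g(228, 10),
                    meta = list(sample_id = "synthetic_turn_basis")),
    unordered = spectrum(grid, -12 * g(200, 8) + 1.5 * g(230, 15),
                         meta = list(sample_id = "synthetic_unordered_basis"))
  )
}

#' Simulate a far-UV CD spectrum from secondary-structure fractions
#'
#' Linear mixture of the four basis spectra weighted by the secondary
#' structure fractions (helix, sheet, turn, unordered), plus noise.
#'
#' @param fractions Numeric length-4 vector `(helix, sheet, turn,
#'   unordered)`, nonnegative, summing to 1 within 1e-6.
#' @param basis List of four basis spectra on a common grid (default
#'   [cd_basis_spectra()]).
#' @param cfg A [generator_config()].
#' @return A [spectrum()] on the basis grid.
#' @export
gen_cd_spectrum <- function(fractions, basis = cd_basis_spectra(),
                            cfg = generator_config()) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 4L || any(!is.finite(fractions)) ||
      any(fractions < 0))
    abort_uvf("`fractions` must be 4 nonnegative numbers",
              "uvf_invalid_input")
  if (abs(sum(fractions) - 1) > 1e-6)
    abort_uvf("`fractions` must sum to 1 (tolerance 1e-6)",
              "uvf_invalid_input")
  if (length(basis) != 4L)
    abort_uvf("`basis` must contain 4 spectra", "uvf_invalid_input")
  grid <- basis[[1L]]$axis
  for (b in basis)
    if (!isTRUE(all.equal(b$axis, grid)))
      abort_uvf("basis spectra must share one grid", "uvf_invalid_input")
  y <- Reduce(`+`, Map(function(f, b) f * b$intensity, fractions, basis)) +
    gen_noise(cfg, length(grid))
  spectrum(grid, y, meta = list(sample_id = "synthetic_cd_mixture"))
}
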