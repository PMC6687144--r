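test_that("generators are deterministic under a fixed seed and exact at zero noise", {
  cfg <- generator_config(seed = 42, noise_sd = 0.5)
  expect_identical(gen_trp_spectrum(cfg = cfg), gen_trp_spectrum(cfg = cfg))
  expect_identical(gen_bisans_titration(0.31, 3.2, 1, cfg = cfg),
                   gen_bisans_titration(0.31, 3.2, 1, cfg = cfg))
  expect_identical(
    gen_promoter(500, planted = list(list(motif = "ACCAAAC", pos = -100)),
                 cfg = cfg),
    gen_promoter(500, planted = list(list(motif = "ACCAAAC", pos = -100)),
                 cfg = cfg))

  # zero noise reproduces the closed-form model at every grid point
  s <- gen_trp_spectrum(center_nm = 340, amplitude = 100, width_nm = 25,
                        cfg = generator_config(seed = 1))
  expect_equal(s$intensity,
               100 * exp(-(s$axis - 340)^2 / (2 * 25^2)),
               tolerance = 1e-12)
  a <- gen_anisotropy_curve(0.2, 122, cfg = generator_config(seed = 1))
  expect_equal(a$signal, 0.2 * a$conc / (0.122 + a$conc), tolerance = 1e-12)
})

test_that("tryptophan spectrum peaks at its centre and decays exponentially with dose", {
  s0 <- gen_trp_spectrum(center_nm = 340, uvb_hours = 0,
                         cfg = generator_config(seed = 1))
  expect_equal(emission_max(s0)$x_at_max, 340)

  # no decay: any exposure time gives the unexposed spectrum
  s_nodecay <- gen_trp_spectrum(uvb_hours = 7, decay_rate = 0,
                                cfg = generator_config(seed = 1))
  expect_equal(s_nodecay$intensity, s0$intensity)

  # closed-form amplitude decay: 100 * e^-1
  s_dec <- gen_trp_spectrum(amplitude = 100, decay_rate = 0.25,
                            uvb_hours = 4, cfg = generator_config(seed = 1))
  expect_equal(emission_max(s_dec)$max_intensity, 100 * exp(-1),
               tolerance = 1e-12)
  expect_equal(100 * exp(-1), 36.78794, tolerance = 1e-6)

  expect_error(gen_trp_spectrum(cfg = generator_config(grid = numeric())),
               class = "uvf_invalid_input")
  expect_error(gen_trp_spectrum(width_nm = 0), class = "uvf_invalid_input")
})

test_that("kynurenine band sits at 450 nm and scales with amplitude", {
  k <- gen_kynurenine_spectrum(cfg = generator_config(seed = 1))
  expect_equal(emission_max(k)$x_at_max, 450)
  k0 <- gen_kynurenine_spectrum(amplitude = 0,
                                cfg = generator_config(seed = 1))
  expect_true(all(k0$intensity == 0))
  k10 <- gen_kynurenine_spectrum(amplitude = 10,
                                 cfg = generator_config(seed = 1))
  expect_equal(intensity_at(k10, 450), 10, tolerance = 1e-12)
})

test_that("Bis-ANS generator obeys mass action (quadratic = numeric root)", {
  ser0 <- gen_bisans_titration(0.31, 3.20, protein_uM = 1, phi = 50,
                               dye_grid_uM = c(0, 3.2),
                               cfg = generator_config(seed = 1))
  expect_equal(ser0$signal[1L], 0) # no ligand, no signal

  # independent oracle: solve B (free + bound balance) by uniroot
  mass_action_bound <- function(n, p, s_tot, kd) {
    if (s_tot == 0) return(0)
    f <- function(b) b - n * p * (s_tot - b) / (kd + (s_tot - b))
    stats::uniroot(f, c(0, min(n * p, s_tot)), tol = 1e-14)$root
  }
  b_oracle <- mass_action_bound(0.31, 1, 3.20, 3.20)
  expect_equal(ser0$signal[2L] / 50, b_oracle, tolerance = 1e-9)

  # saturation: bound approaches n*P as dye -> infinity
  sat <- gen_bisans_titration(0.31, 3.20, protein_uM = 1, phi = 1,
                              dye_grid_uM = c(0, 1e6),
                              cfg = generator_config(seed = 1))
  expect_equal(sat$signal[2L], 0.31, tolerance = 1e-4)

  expect_error(gen_bisans_titration(0.31, 3.20, 1,
                                    dye_grid_uM = c(-1, 0, 1)),
               class = "uvf_invalid_input")
})

test_that("unfolding-curve generator hits limits and the default grid has 17 points", {
  tp <- three_state_truth("myb4_ctrl")
  cv <- gen_unfolding_curve("three_state", tp,
                            cfg = generator_config(seed = 1))
  expect_length(cv$urea_M, 17L)

  # folded limit at 0 M with large positive free energies
  big <- modifyList(tp, list(dG1 = 50, dG2 = 50))
  y0 <- predict_unfolding_signal(big, 0)
  expect_equal(y0, tp$yN, tolerance = 1e-9)
  # unfolded limit far past the transitions
  yU <- predict_unfolding_signal(tp, 30)
  expect_equal(yU, tp$yU, tolerance = 1e-9)

  expect_error(gen_unfolding_curve("three_state",
                                   list(dG1 = 10, dG2 = 5, m1 = 3)),
               regexp = "m2")
})

test_that("anisotropy generator evaluates the hyperbola exactly", {
  a <- gen_anisotropy_curve(0.2, 122, conc_grid_uM = c(0, 0.122, 1.4),
                            cfg = generator_config(seed = 1))
  expect_equal(a$signal[1L], 0)
  expect_equal(a$signal[2L], 0.1) # half saturation at x = KD
  expect_equal(a$signal[3L], 0.2 * 1.4 / (0.122 + 1.4), tolerance = 1e-12)
  expect_equal(a$signal[3L], 0.18397, tolerance = 1e-4)
})

test_that("aggregation generator starts at baseline and approaches plateau", {
  tr <- gen_aggregation_trace(0.1, 0.3, rate = 0.05,
                              cfg = generator_config(seed = 1))
  expect_equal(tr$od360[1L], 0.1)
  span_frac <- (tr$od360[length(tr$od360)] - 0.1) / 0.2
  expect_equal(span_frac, 1 - exp(-0.05 * 120), tolerance = 1e-12)
  expect_equal(span_frac, 0.99752, tolerance = 1e-4)

  flat <- gen_aggregation_trace(0.1, 0.3, rate = 0,
                                cfg = generator_config(seed = 1))
  expect_true(all(flat$od360 == 0.1))
  expect_error(gen_aggregation_trace(rate = -0.1),
               class = "uvf_invalid_input")
})

test_that("promoter generator plants motifs at stated positions and rejects bad plants", {
  p <- gen_promoter(1000, planted = list(list(motif = "ACCAAAC",
                                              pos = -212),
                                         list(motif = "ATAATATCT",
                                              pos = -908)),
                    cfg = generator_config(seed = 11))
  expect_equal(substr(p$sequence, 1000 + 1 - 212, 1000 + 1 - 212 + 6),
               "ACCAAAC")
  expect_equal(substr(p$sequence, 1000 + 1 - 908, 1000 + 1 - 908 + 8),
               "ATAATATCT")

  # controlled negative: all-A/T background cannot contain a C-bearing motif
  neg <- gen_promoter(2000, gc = 0, cfg = generator_config(seed = 3))
  expect_length(naive_scan_starts(neg$sequence, "ACCAAAC"), 0L)

  expect_error(gen_promoter(100, planted = list(list(motif = "ACCAAAC",
                                                     pos = -3))),
               class = "uvf_invalid_input") # runs past the TSS end
  expect_error(gen_promoter(1000,
                            planted = list(list(motif = "ACCAAAC",
                                                pos = -212),
                                           list(motif = "ACCAAAC",
                                                pos = -210))),
               class = "uvf_invalid_input") # overlap
})

test_that("accidental-match masking leaves exactly the planted occurrences", {
  # AT-only motif in AT-rich background: chance matches are likely, masking
  # must remove all of them
  for (seed in 1:5) {
    p <- gen_promoter(3000, planted = list(list(motif = "ATAAT",
                                                pos = -1500)),
                      gc = 0.1, cfg = generator_config(seed = seed))
    expect_identical(naive_scan_starts(p$sequence, "ATAAT"),
                     3000L + 1L - 1500L)
  }
})

test_that("DLS generator normalizes and respects the aggregate fraction", {
  d0 <- gen_dls_distribution(aggregate_fraction = 0,
                             cfg = generator_config(seed = 1))
  expect_equal(sum(d0$intensity_frac), 1, tolerance = 1e-12)
  expect_true(dls_summary(d0)$monomer_flag) # 1.8 nm mode is monomeric

  d5 <- gen_dls_distribution(aggregate_fraction = 0.5,
                             cfg = generator_config(seed = 1))
  expect_equal(sum(d5$intensity_frac), 1, tolerance = 1e-12)
  expect_error(gen_dls_distribution(aggregate_fraction = 1.2),
               class = "uvf_invalid_input")
})

test_that("CD generator is linear in the fractions", {
  f1 <- c(1, 0, 0, 0)
  f2 <- c(0, 0, 0, 1)
  a <- 0.3
  cfg <- generator_config(seed = 1)
  mix <- gen_cd_spectrum(a * f1 + (1 - a) * f2, cfg = cfg)
  lin <- a * gen_cd_spectrum(f1, cfg = cfg)$intensity +
    (1 - a) * gen_cd_spectrum(f2, cfg = cfg)$intensity
  expect_equal(mix$intensity, lin, tolerance = 1e-12)

  basis <- cd_basis_spectra()
  pure <- gen_cd_spectrum(c(1, 0, 0, 0), cfg = cfg)
  expect_equal(pure$intensity, basis$helix$intensity, tolerance = 1e-12)

  expect_error(gen_cd_spectrum(c(0.5, 0.5, 0.1, 0)),
               class = "uvf_invalid_input") # sum != 1
})
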