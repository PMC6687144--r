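# Shared ground-truth parameter sets (the published fitted values used as
# generator truths) and a brute-force IUPAC scanning oracle.

# Bis-ANS one-site parameters: sites per subunit and KD (uM)
table1_rows <- list(
  myb4_ctrl  = list(n = 0.31, kd = 3.20),
  myb4_uvb   = list(n = 0.22, kd = 4.17),
  d1_ctrl    = list(n = 0.50, kd = 4.60),
  d1_uvb     = list(n = 0.32, kd = 5.32),
  d2_ctrl    = list(n = 0.62, kd = 5.81),
  d2_uvb     = list(n = 0.43, kd = 6.10)
)

# Step free energies (kJ/mol); m-values are free fit parameters, fixed here
# at the generation values used throughout
table2_rows <- list(
  myb4_ctrl = c(dG1 = 11.6, dG2 = 5.1),
  myb4_uvb  = c(dG1 = 10.8, dG2 = 5.2),
  d1_ctrl   = c(dG1 = 11.4, dG2 = 5.4),
  d1_uvb    = c(dG1 = 10.3, dG2 = 5.5),
  d2_ctrl   = c(dG1 = 11.3, dG2 = 5.7),
  d2_uvb    = c(dG1 = 10.8, dG2 = 4.8)
)
unfold_m <- c(m1 = 3.5, m2 = 1.8)
unfold_baselines <- c(yN = 1.2, yI = 1.0, yU = 0.8)

three_state_truth <- function(row) {
  as.list(c(table2_rows[[row]], unfold_m, unfold_baselines))
}

# Anisotropy KDs (nM) for protein/oligo combinations
table5_kds <- c(122, 95, 149, 130, 260, 150, 190, 180)

# Brute-force position-by-position IUPAC scanner (independent oracle for
# scan_motifs); subject must be concrete A/C/G/T
naive_scan_starts <- function(seq_chr, motif) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(motif), "")[[1L]]
  k <- length(chars)
  L <- nchar(seq_chr)
  if (L < k) return(integer())
  starts <- seq_len(L - k + 1L)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(k)) {
    allowed <- strsplit(map[[chars[j]]], "")[[1L]]
    b <- substring(seq_chr, starts + j - 1L, starts + j - 1L)
    ok <- ok & (b %in% allowed)
  }
  starts[ok]
}

random_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}
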