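test_that("planted cis-elements are recovered at their stated upstream positions", {
  p <- gen_promoter(1000,
                    planted = list(list(motif = "ACCAAAC", pos = -212),
                                   list(motif = "ATAATATCT", pos = -908)),
                    cfg = generator_config(seed = 5))
  hits <- scan_motifs(p, c("ACCAAAC", "ATAATATCT"))
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$upstream_pos, c(-908L, -212L)) # sorted upstream-first
  expect_equal(hits$motif_id, c("ATAATATCT", "ACCAAAC"))
  expect_equal(hits$matched_seq, c("ATAATATCT", "ACCAAAC"))
  expect_true(all(hits$strand == "+"))
  # coordinate round trip: promoter-local start <-> TSS-relative position
  expect_equal(hits$start, hits$upstream_pos + p$length + 1L)
})

test_that("a motif absent from the sequence yields a zero-row table", {
  allt <- promoter_record("t_only", strrep("T", 500))
  hits <- scan_motifs(allt, "ACCAAAC")
  expect_equal(nrow(hits), 0L)
  expect_named(hits, c("motif_id", "matched_seq", "upstream_pos",
                       "strand", "start", "end"))
})

test_that("invalid IUPAC characters are rejected with the offending code named", {
  p <- promoter_record("p", strrep("ACGT", 25))
  expect_error(scan_motifs(p, "ACCXAAC"), class = "uvf_invalid_motif")
  expect_error(scan_motifs(p, "ACCXAAC"), regexp = "X")
  expect_error(scan_motifs(p, character()), class = "uvf_invalid_input")
  expect_error(scan_motifs("ACGTACGT", "ACCA"), class = "uvf_invalid_input")
})

test_that("forward scanning agrees with a brute-force IUPAC oracle on random sequences", {
  motifs <- c("ACCAAAC", "ACCWACC", "MYBR", "ATAATATCT", "NNAN", "AA")
  for (seed in 1:30) {
    seqc <- random_dna(400, seed = seed)
    p <- promoter_record(paste0("r", seed), seqc)
    for (m in motifs) {
      got <- scan_motifs(p, m)
      got <- got[got$strand == "+", , drop = FALSE]
      expect_identical(sort(got$start), naive_scan_starts(seqc, m),
                       info = sprintf("seed %d motif %s", seed, m))
    }
  }
})

test_that("overlapping and degenerate matches are all reported", {
  p <- promoter_record("ov", "AAAAA")
  hits <- scan_motifs(p, "AA")
  expect_equal(nrow(hits), 4L) # overlapping hits at starts 1..4
  nn <- scan_motifs(p, "NN")
  expect_equal(nrow(nn), 4L) # fully degenerate motif matches everywhere
})

test_that("minus-strand hits are anchored at their own 5'-most base", {
  # GTTTGGT at forward starts 3..9 is the reverse complement of ACCAAAC;
  # its 5'-most base on the minus strand is the forward coordinate 9
  p <- promoter_record("rc", paste0("AA", "GTTTGGT", "AAAA")) # length 13
  fwd_only <- scan_motifs(p, "ACCAAAC")
  expect_equal(nrow(fwd_only), 0L)
  both <- scan_motifs(p, "ACCAAAC", strand_mode = "both")
  expect_equal(nrow(both), 1L)
  expect_equal(both$strand, "-")
  expect_equal(both$matched_seq, "ACCAAAC") # read 5'->3' on the hit strand
  expect_equal(both$end, 9L)
  expect_equal(both$upstream_pos, 9L - 13L - 1L)
})

test_that("coordinate convention round-trips for arbitrary planted positions", {
  withr::with_seed(21, {
    for (i in 1:10) {
      L <- sample(200:2000, 1)
      pos <- -sample(seq(8, L - 8), 1)
      p <- gen_promoter(L, planted = list(list(motif = "ACCAAAC",
                                               pos = pos)),
                        cfg = generator_config(seed = i))
      hits <- scan_motifs(p, "ACCAAAC")
      expect_true(pos %in% hits$upstream_pos)
      expect_true(all(hits$upstream_pos < 0)) # no position 0, TSS is +1
      expect_equal(hits$start, hits$upstream_pos + L + 1L)
    }
  })
})

test_that("consensus frequencies sum to one and IC hits the closed-form limits", {
  # invariant columns with no pseudocount carry the full 2 bits
  cons <- build_consensus(c("ACCAAAC", "ACCAAAC", "ACCAAAC"),
                          pseudocount = 0)
  expect_equal(unname(cons$ic), rep(2, 7), tolerance = 1e-12)
  expect_equal(colSums(cons$freq), rep(1, 7), tolerance = 1e-12)

  # a half/half column has H = 1 bit, IC = 1
  cons2 <- build_consensus(c("A", "C"), pseudocount = 0)
  expect_equal(unname(cons2$ic), 1, tolerance = 1e-12)

  # pseudocounts strictly reduce IC below 2 even for invariant columns
  cons3 <- build_consensus(c("AAAA", "AAAA"), pseudocount = 0.5)
  expect_true(all(cons3$ic < 2))
  expect_true(all(cons3$ic > 0))
  expect_equal(colSums(cons3$freq), rep(1, 4), tolerance = 1e-12)
  # closed form: freqs (2.5, .5, .5, .5)/4
  pf <- c(2.5, 0.5, 0.5, 0.5) / 4
  expect_equal(unname(cons3$freq[, 1]), pf, tolerance = 1e-12)
  expect_equal(cons3$ic[1], 2 + sum(pf * log2(pf)), tolerance = 1e-12)

  # observed MYB-element family: invariant CC core outscores the variable
  # positions 4 and 6
  fam <- build_consensus(c("ACCAAAC", "ACCTACC", "ACCAACC", "ACCTAAC"))
  expect_gt(min(fam$ic[2:3]), max(fam$ic[c(4, 6)]))

  expect_error(build_consensus("ACCAAAC"), class = "uvf_invalid_input")
  expect_error(build_consensus(c("ACCA", "ACCAA")),
               class = "uvf_invalid_input")
  expect_error(build_consensus(c("ACCN", "ACCA")),
               class = "uvf_invalid_input")
})

test_that("oligo_diff pinpoints the mutated bases of the binding-site mutants", {
  d <- oligo_diff("ACCAAAC", "GCCGAAC")
  expect_equal(d$position, c(1L, 4L))
  expect_equal(d$wild, c("A", "A"))
  expect_equal(d$mutant, c("G", "G"))

  d2 <- oligo_diff("ACCTACC", "ATCTACT")
  expect_equal(d2$position, c(2L, 7L))
  expect_equal(d2$wild, c("C", "C"))
  expect_equal(d2$mutant, c("T", "T"))

  expect_equal(nrow(oligo_diff("ACCAAAC", "accaaac")), 0L)
  expect_error(oligo_diff("ACCA", "ACCAA"), class = "uvf_invalid_input")
})
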