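# Promoter scanning for MYB-class cis-elements in TSS-relative coordinates,
# consensus matrices from aligned instances, and wild-type/mutant oligo
# comparison.
#
# Coordinate convention: the promoter's last base is -1 and the TSS is +1
# (no position 0). A hit's position is the forward-strand coordinate of its
# 5'-most base; minus-strand hits are reported at the forward-strand
# coordinate of their own 5'-most base (the match's right end), tagged "-".

iupac_ok <- function(motif) {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  chars <- strsplit(toupper(motif), "")[[1L]]
  bad <- setdiff(chars, codes)
  if (length(bad))
    abort_uvf(sprintf("invalid IUPAC code '%s' in motif '%s'",
                      bad[1L], motif),
              "uvf_invalid_motif")
  invisible(TRUE)
}

#' Scan a promoter for cis-element motifs
#'
#' Reports every exact IUPAC match of each motif (overlapping hits
#' included), sorted by upstream position. Matching is degenerate-aware:
#' the query may use the full IUPAC alphabet, so the family of observed
#' MYB elements (ACCAAAC, ACCTACC, ACCAACC, ACCTAAC, ...) can be collapsed
#' to one degenerate query.
#'
#' @param promoter A [promoter_record()].
#' @param motifs Character vector of IUPAC motif strings.
#' @param strand_mode `"forward"` (default; the reported plant elements are
#'   sense-strand) or `"both"`.
#' @return Data frame with columns `motif_id`, `matched_seq` (read 5'->3'
#'   on the hit strand), `upstream_pos` (negative, TSS = +1), `strand`,
#'   `start`, `end` (1-based promoter-local), sorted by `upstream_pos`.
#' @examples
#' p <- gen_promoter(1000, planted = list(list(motif = "ACCAAAC", pos = -212)),
#'                   cfg = generator_config(seed = 7))
#' scan_motifs(p, "ACCAAAC")
#' @export
scan_motifs <- function(promoter, motifs,
                        strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  if (!inherits(promoter, "uvf_promoter"))
    abort_uvf("`promoter` must be a promoter_record", "uvf_invalid_input")
  if (length(motifs) == 0L)
    abort_uvf("`motifs` must be nonempty", "uvf_invalid_input")
  for (m in motifs) iupac_ok(m)
  L <- promoter$length
  subject <- Biostrings::DNAString(promoter$sequence)
  rows <- list()
  add_hits <- function(motif_id, pattern, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                     subject, fixed = FALSE)
    st <- Biostrings::start(hits)
    en <- Biostrings::end(hits)
    if (!length(st)) return()
    anchor <- if (strand == "+") st else en # 5'-most base on hit strand
    seqs <- as.character(hits)
    if (strand == "-")
      seqs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs)))
    rows[[length(rows) + 1L]] <<- data.frame(
      motif_id = motif_id, matched_seq = seqs,
      upstream_pos = anchor - L - 1L, strand = strand,
      start = st, end = en, stringsAsFactors = FALSE)
  }
  for (m in motifs) {
    mu <- toupper(m)
    add_hits(mu, mu, "+")
    if (strand_mode == "both") {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(mu)))
      add_hits(mu, rc, "-")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(), matched_seq = character(),
               upstream_pos = integer(), strand = character(),
               start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$upstream_pos, out$motif_id, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a consensus frequency/information matrix
#'
#' Pseudocount-adjusted per-position base frequencies from aligned,
#' equal-length motif instances, with per-position information content
#' IC = 2 - H (bits), H the Shannon entropy of the column.
#'
#' @param instances Character vector of >= 2 aligned A/C/G/T sequences of
#'   equal length.
#' @param pseudocount Added to each base count per column (default 0.5).
#' @return List of class `uvf_consensus`: `freq` (4 x L matrix, rows
#'   A/C/G/T, columns summing to 1), `ic` (bits, in `[0, 2]`), `n`.
#' @export
build_consensus <- function(instances, pseudocount = 0.5) {
  if (length(instances) < 2L)
    abort_uvf("consensus needs >= 2 instances", "uvf_invalid_input")
  check_scalar(pseudocount, "pseudocount", nonnegative = TRUE)
  instances <- toupper(instances)
  lens <- nchar(instances)
  if (length(unique(lens)) != 1L)
    abort_uvf("instances must be aligned to equal length",
              "uvf_invalid_input")
  if (any(grepl("[^ACGT]", instances)))
    abort_uvf("instances must contain only A/C/G/T", "uvf_invalid_input")
  L <- lens[1L]
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(instances, ""))
  counts <- vapply(seq_len(L), function(j)
    table(factor(mat[, j], levels = bases)), numeric(4L))
  freq <- (counts + pseudocount) /
    rep(colSums(counts) + 4 * pseudocount, each = 4L)
  h <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(freq = matrix(freq, nrow = 4L,
                               dimnames = list(bases, NULL)),
                 ic = 2 - h, n = length(instances),
                 pseudocount = pseudocount),
            class = "uvf_consensus")
}

#' @export
print.uvf_consensus <- function(x, ...) {
  cat(sprintf("<consensus> %d instances, %d columns\n", x$n, ncol(x$freq)))
  cat("IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' Differences between a wild-type and a mutant oligo
#'
#' Positions (1-based from the 5' end) at which two equal-length sequences
#' differ, with the wild-type and mutant base at each.
#'
#' @param wild,mutant Equal-length sequences.
#' @return Data frame with columns `position`, `wild`, `mutant` (zero rows
#'   if identical).
#' @examples
#' oligo_diff("ACCAAAC", "GCCGAAC") # positions 1 and 4
#' @export
oligo_diff <- function(wild, mutant) {
  wild <- toupper(wild)
  mutant <- toupper(mutant)
  if (nchar(wild) != nchar(mutant))
    abort_uvf("sequences must have equal length", "uvf_invalid_input")
  w <- strsplit(wild, "")[[1L]]
  m <- strsplit(mutant, "")[[1L]]
  idx <- which(w != m)
  data.frame(position = idx, wild = w[idx], mutant = m[idx],
             stringsAsFactors = FALSE)
}
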