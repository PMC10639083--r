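# Splice-site motif definitions used by the toy-genome generator and as the
# source of the packaged synthetic reference sets.
#
# The 5' splice-site window covers positions -3..+8 around the donor (three
# exonic bases followed by the first eight intronic bases). The branch-point
# window is nine bases long and is planted (and later searched for) within
# -40..-5 of the acceptor. Minor introns here carry the AT-AC subtype
# consensus (ATATCCTT donor, TTCCTTAAC branch point); major introns carry the
# U2-type consensus (GTAAGTAT donor, weak TACTAACAT branch point) and a
# polypyrimidine tract upstream of their AG acceptor.

DONOR_EXONIC <- 3L
DONOR_INTRONIC <- 8L
DONOR_WIDTH <- DONOR_EXONIC + DONOR_INTRONIC
BPS_WIDTH <- 9L
BPS_SEARCH <- c(-40L, -5L) # window relative to the acceptor's last base

MINOR_DONOR_CONSENSUS <- "CAGATATCCTT" # -3..-1 exon | +1..+8 intron
MAJOR_DONOR_CONSENSUS <- "CAGGTAAGTAT"
MINOR_BPS_CONSENSUS <- "TTCCTTAAC"
MAJOR_BPS_CONSENSUS <- "TACTAACAT"
MINOR_ACCEPTOR <- "AC"
MAJOR_ACCEPTOR <- "AG"

# Position frequency matrix concentrated on a consensus string.
# `noise` spreads probability mass uniformly over the other three bases.
consensus_pfm <- function(consensus, noise = 0) {
  chars <- strsplit(consensus, "")[[1]]
  stopifnot(all(chars %in% BASES), noise >= 0, noise < 1)
  m <- matrix(noise / 3, nrow = 4, ncol = length(chars),
              dimnames = list(BASES, NULL))
  for (i in seq_along(chars)) m[chars[i], i] <- 1 - noise
  m
}

check_pfm <- function(m, name) {
  if (!is.matrix(m) || nrow(m) != 4 || is.null(rownames(m)) ||
      !all(rownames(m) == BASES)) {
    stop_param(name, " must be a 4-row matrix with rows A, C, G, T")
  }
  if (any(abs(colSums(m) - 1) > 1e-6)) {
    stop_param(name, " columns must each sum to 1 (tolerance 1e-6)")
  }
  invisible(m)
}

#' Default splice-site motif specification
#'
#' Position frequency matrices for the donor (5'SS, positions -3..+8) and
#' branch-point (9 nt) motifs of both intron types, used by
#' [generate_toy_genome()] to plant introns and by the packaged synthetic
#' reference sets. `noise = 0` gives consensus-exact motifs, under which the
#' classifier separates the types perfectly; larger values spread probability
#' onto non-consensus bases.
#'
#' @param noise per-position probability mass moved off the consensus base.
#' @return list with elements `donor_minor`, `donor_major`, `bps_minor`,
#'   `bps_major` (4 x width matrices) and `acceptor_minor`, `acceptor_major`
#'   (terminal dinucleotide strings).
#' @export
default_motif_spec <- function(noise = 0) {
  list(
    donor_minor = consensus_pfm(MINOR_DONOR_CONSENSUS, noise),
    donor_major = consensus_pfm(MAJOR_DONOR_CONSENSUS, noise),
    bps_minor = consensus_pfm(MINOR_BPS_CONSENSUS, noise),
    bps_major = consensus_pfm(MAJOR_BPS_CONSENSUS, noise),
    acceptor_minor = MINOR_ACCEPTOR,
    acceptor_major = MAJOR_ACCEPTOR
  )
}

check_motif_spec <- function(spec) {
  for (nm in c("donor_minor", "donor_major", "bps_minor", "bps_major")) {
    check_pfm(spec[[nm]], nm)
  }
  stopifnot(nchar(spec$acceptor_minor) == 2, nchar(spec$acceptor_major) == 2)
  invisible(spec)
}

sample_from_pfm <- function(pfm) {
  paste(vapply(seq_len(ncol(pfm)), function(i) {
    sample(BASES, 1, prob = pfm[, i])
  }, character(1)), collapse = "")
}
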