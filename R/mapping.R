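# Mapping protected 3' ends to ribosomal P-site codons.

#' Distribution of fragment 3' ends
#'
#' Tallies the 3'-end positions of processed reads and the fraction of
#' reads in each of the three reading-frame phases (`end_pos mod 3`).
#' A strong tri-nucleotide periodicity (one dominant phase) is the
#' signature of single-position exonucleolytic cleavage downstream of
#' stalled ribosomes.
#'
#' @param end_pos Integer vector of 3'-end positions (>= 1 read).
#' @return list of class `EndDistribution`: `histogram` (data.frame
#'   `end_pos`, `n`), `phase_fractions` (named fractions for phases
#'   0/1/2), `dominant_phase`, `n_reads`.
#' @export
end_distribution <- function(end_pos) {
  end_pos <- end_pos[!is.na(end_pos)]
  if (!length(end_pos)) stop("end_distribution needs at least one read")
  tab <- table(end_pos)
  hist <- data.frame(end_pos = as.integer(names(tab)), n = as.integer(tab))
  ph <- factor(end_pos %% 3L, levels = 0:2)
  pf <- as.numeric(table(ph)) / length(end_pos)
  names(pf) <- as.character(0:2)
  structure(list(histogram = hist, phase_fractions = pf,
                 dominant_phase = as.integer(names(pf)[which.max(pf)]),
                 n_reads = length(end_pos)),
            class = "EndDistribution")
}

#' @export
print.EndDistribution <- function(x, ...) {
  cat("EndDistribution:", x$n_reads, "reads, 3' ends",
      min(x$histogram$end_pos), "-", max(x$histogram$end_pos), "\n")
  cat("  phase fractions (end mod 3):",
      paste(sprintf("%s=%.3f", names(x$phase_fractions), x$phase_fractions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the P-site to 3'-end cleavage offset from UAG-stalled reads
#'
#' Ribosomes pause with a UAG codon in the A-site, so reads containing an
#' in-frame UAG carry an internal calibration point: if the UAG occupies
#' codon q of a read, the ribosome paused with codon q - 1 in the P-site
#' and the candidate offset is `end_pos - 3 * (q - 1)` (distance from the
#' last nucleotide of that P-site codon to the protected 3' end).
#' Candidates are accumulated over all in-frame UAGs at codons q >= 3
#' (so that the upstream motif residue exists) that are fully contained
#' in the read, and the modal candidate is returned; ties are broken
#' towards the larger offset, since cleavage jitter only shortens
#' fragments.
#'
#' @param pr Processed reads (data.frame with `seq`, `end_pos`).
#' @return list of class `OffsetEstimate`: `offset`, `support` (data.frame
#'   `offset`, `n`), `n_reads_used`.
#' @export
estimate_offset <- function(pr) {
  seqs <- pr$seq
  end_pos <- pr$end_pos
  q_max <- max(end_pos) %/% 3L
  cand <- list(); used <- logical(length(seqs))
  for (q in seq(3L, max(3L, q_max))) {
    if (3L * q > max(end_pos)) break
    hit <- substr(seqs, 3L * q - 2L, 3L * q) == "TAG" & end_pos >= 3L * q
    off <- end_pos[hit] - 3L * (q - 1L)
    off <- off[off >= 0L]
    if (length(off)) {
      cand[[length(cand) + 1L]] <- off
      used <- used | hit
    }
  }
  if (!length(cand)) {
    stop("no reads with an in-frame UAG codon; use a fixed offset instead")
  }
  off <- unlist(cand)
  tab <- table(off)
  support <- data.frame(offset = as.integer(names(tab)), n = as.integer(tab))
  best <- support$offset[support$n == max(support$n)]
  structure(list(offset = max(best), support = support,
                 n_reads_used = sum(used)),
            class = "OffsetEstimate")
}

#' @export
print.OffsetEstimate <- function(x, ...) {
  cat("OffsetEstimate: +", x$offset, " nt (", x$n_reads_used,
      " reads used)\n", sep = "")
  invisible(x)
}

#' Assign a P-site codon to each read from its 3'-end position
#'
#' With cleavage a fixed `offset` downstream of the last nucleotide of
#' the P-site codon, and jitter shortening fragments by at most two
#' nucleotides, the P-site codon is `ceiling((end_pos - offset) / 3)`:
#' the ceiling absorbs -1/-2 jitter so that all three jittered ends of
#' one stall event map to the same codon.  Codon 1 is the ATG.
#'
#' @param end_pos Integer vector of 3'-end positions.
#' @param offset Cleavage offset in nucleotides (>= 0).
#' @return Integer vector of P-site codons; `NA` where unassignable
#'   (p < 1, or the A-site codon lies within the protected region but is
#'   not fully covered by the read).
#' @export
assign_psite <- function(end_pos, offset = 17L) {
  if (offset < 0L) stop("offset must be >= 0")
  p <- as.integer(ceiling((end_pos - offset) / 3))
  p[!is.na(p) & p < 1L] <- NA_integer_
  if (offset >= 3L) {
    # A-site codon (p + 1) is inside the protected region; require it whole
    p[!is.na(p) & 3L * (p + 1L) > end_pos] <- NA_integer_
  }
  p
}
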