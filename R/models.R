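# Biochemical model objects used by the simulator.

#' Pause model for sequential ribosome stalling
#'
#' During the codon-by-codon walk of a simulated ribosome, the stall
#' probability at each elongation step is looked up from the tripeptide
#' motif X1X2(X3) formed by the residues in the E-, P- and A-site
#' positions (X2 in the P-site, X3 in the A-site).  Motifs not listed in
#' `motif_pause` fall back to `default_pause`.  When the incoming A-site
#' codon is the UAG stop, the ribosome pauses with probability
#' `stop_pause` (release factor 1 is present, so stop pausing is partial);
#' a '*' in the third motif position may override this per motif.  A
#' fraction `initiation_fraction` of ribosomes never leaves the start
#' codon, emulating initiation-complex contamination.
#'
#' @param motif_pause Named numeric vector, names are 3-symbol motifs over
#'   the 20 amino acids with '*' permitted only in position 3; values are
#'   stall probabilities in `[0, 1]`.
#' @param default_pause Stall probability for unlisted motifs.
#' @param stop_pause Stall probability with UAG in the A-site.
#' @param initiation_fraction Fraction of ribosomes stalled at codon 1.
#' @return Object of class `PauseModel`.
#' @export
pause_model <- function(motif_pause = numeric(0), default_pause = 0,
                        stop_pause = 0, initiation_fraction = 0) {
  p <- c(unname(motif_pause), default_pause, stop_pause, initiation_fraction)
  if (any(p < 0 | p > 1)) stop("all pause probabilities must lie in [0, 1]")
  if (length(motif_pause)) {
    keys <- names(motif_pause)
    if (is.null(keys) || any(nchar(keys) != 3L)) {
      stop("motif_pause names must be length-3 motifs")
    }
    ok12 <- substr(keys, 1, 1) %in% AA_ALPHABET &
            substr(keys, 2, 2) %in% AA_ALPHABET
    ok3 <- substr(keys, 3, 3) %in% c(AA_ALPHABET, "*")
    if (!all(ok12 & ok3)) {
      stop("motif_pause keys must use amino-acid letters ('*' only in position 3)")
    }
  }
  structure(list(motif_pause = motif_pause, default_pause = default_pause,
                 stop_pause = stop_pause,
                 initiation_fraction = initiation_fraction),
            class = "PauseModel")
}

#' RNase R cleavage geometry
#'
#' The exonuclease halts a fixed distance downstream of the stalled
#' ribosome: `offset` is the number of nucleotides from the last
#' nucleotide of the P-site codon to the final protected nucleotide
#' (inclusive), 17 by default.  The experimentally observed cleavage
#' pattern is a dominant position with minor one- and two-nucleotide
#' shorter products; `jitter_probs` gives the weights of offsets
#' `offset`, `offset - 1` and `offset - 2`.
#'
#' @param offset Non-negative integer distance in nucleotides.
#' @param jitter_probs Numeric length 3, summing to 1.
#' @return Object of class `CleavageModel`.
#' @export
cleavage_model <- function(offset = 17L, jitter_probs = c(0.70, 0.20, 0.10)) {
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L) stop("offset must be a non-negative integer")
  if (length(jitter_probs) != 3L || any(jitter_probs < 0) ||
      abs(sum(jitter_probs) - 1) > 1e-8) {
    stop("jitter_probs must be three non-negative weights summing to 1")
  }
  structure(list(offset = offset, jitter_probs = jitter_probs),
            class = "CleavageModel")
}
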