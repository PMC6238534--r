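# Sequence-level helpers shared by the simulator and the analysis stages.

#' Default 5' flanking sequence
#'
#' Ribosome-binding-site region located immediately upstream of the start
#' codon in the template designs; it is removed during trimming.
#' @export
FLANK5_DEFAULT <- "GTATAAGGAGGAAAAAAT"

#' Default 3' flanking sequence
#'
#' Linker sequence ligated downstream of the RNase R cleavage site for the
#' NNS15 and ErmBL-style libraries; removed during trimming.
#' @export
FLANK3_DEFAULT <- "GCGATCTCGGTGTGATG"

#' Alternative 3' flanking sequence used for non-library samples
#' @export
FLANK3_ALT <- "GGTATCTCGGTGTGACTG"

# Standard genetic code over DNA codons, '*' for the three stop codons.
.GC <- Biostrings::GENETIC_CODE

#' The 20 proteinogenic amino acids (one-letter codes)
#' @export
AA_ALPHABET <- sort(unique(unname(.GC[.GC != "*"])))

#' Enumerate the sense tripeptide motif space
#'
#' All X1X2(X3) motifs over the 20 amino acids, where X2 occupies the
#' ribosomal P-site and X3 the A-site.  There are exactly 20^3 = 8000 such
#' motifs; motifs with a stop symbol ('*') in the A-site position form a
#' separate 400-member space and are not included here.
#'
#' @return Character vector of 8000 three-letter motifs.
#' @export
aa_motif_space <- function() {
  g <- expand.grid(x3 = AA_ALPHABET, x2 = AA_ALPHABET, x1 = AA_ALPHABET,
                   stringsAsFactors = FALSE)
  paste0(g$x1, g$x2, g$x3)
}

#' Convert a printed log2 spread into a fold factor
#'
#' Replicate scatter and error bands are often quoted both in log2 units
#' and as an equivalent multiplicative factor (e.g. an SD of 0.2 log2
#' units corresponds to a 2^0.2 = 1.15-fold spread).
#'
#' @param x Numeric, value(s) in log2 units.
#' @return `2^x`.
#' @export
log2_units_to_fold <- function(x) 2^x

# Split equal-length sequences into a codon character matrix
# (n_seq x n_codons). Positions past the end of a sequence give "".
codon_matrix <- function(seqs, n_codons = NULL) {
  if (is.null(n_codons)) n_codons <- max(nchar(seqs)) %/% 3L
  m <- matrix("", nrow = length(seqs), ncol = n_codons)
  for (j in seq_len(n_codons)) {
    m[, j] <- substr(seqs, 3L * j - 2L, 3L * j)
  }
  m
}

# Translate a codon character matrix to an amino-acid matrix ('*' = stop,
# NA for incomplete codons).
translate_codon_matrix <- function(cm) {
  aa <- .GC[cm]
  dim(aa) <- dim(cm)
  aa
}

#' Translate in-frame nucleotide strings to peptides
#'
#' Vectorised translation with the standard genetic code; stop codons
#' render '*' and incomplete trailing codons are ignored.
#'
#' @param seqs Character vector of nucleotide sequences (frame starts at
#'   position 1).
#' @return Character vector of peptide strings.
#' @export
translate_nt <- function(seqs) {
  if (!length(seqs)) return(character())
  out <- character(length(seqs))
  nc <- nchar(seqs) %/% 3L
  for (k in unique(nc)) {
    idx <- which(nc == k)
    if (k == 0L) { out[idx] <- ""; next }
    cm <- codon_matrix(seqs[idx], k)
    aa <- translate_codon_matrix(cm)
    out[idx] <- do.call(paste0, as.data.frame(aa, stringsAsFactors = FALSE))
  }
  out
}

# Vectorised Hamming distance between equal-length strings and a single
# reference (compared over the reference's width).
hamming_to_ref <- function(seqs, ref) {
  n <- nchar(ref)
  d <- integer(length(seqs))
  for (i in seq_len(n)) {
    d <- d + (substr(seqs, i, i) != substr(ref, i, i))
  }
  d
}

# Minimum Phred score within a window of a Phred+33 quality string.
# Reads whose window is empty (window entirely past the read end) give Inf.
phred_min_in_window <- function(qual, lo, hi) {
  n <- length(qual)
  if (!n) return(numeric())
  hi_eff <- pmin(hi, nchar(qual))
  qsub <- substr(qual, lo, hi_eff)
  lens <- nchar(qsub)
  mins <- rep(Inf, n)
  nz <- lens > 0L
  if (any(nz)) {
    codes <- utf8ToInt(paste(qsub[nz], collapse = ""))
    grp <- rep.int(seq_len(sum(nz)), lens[nz])
    dt <- data.table(grp = grp, q = codes)
    agg <- dt[, list(m = min(q)), by = grp]
    mins[which(nz)[agg$grp]] <- agg$m - 33
  }
  mins
}

#' Read a FASTQ file into a read table
#'
#' @param path Path to a (Phred+33) FASTQ file.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
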