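# Fixture builders shared across the test files.  Everything is built in
# code; no binary fixtures are stored.

F5 <- FLANK5_DEFAULT
F3 <- FLANK3_DEFAULT

# Phred+33 character for a given Q score.
qchar <- function(q) intToUtf8(q + 33L)

# Assemble a read data.frame from inserts (sequences between the flanks).
# `qual` may be a single string recycled per read or NULL for constant Q37.
make_reads <- function(inserts, flank5 = F5, flank3 = F3, qual = NULL,
                       ids = NULL) {
  seqs <- paste0(flank5, inserts, flank3)
  if (is.null(qual)) qual <- strrep(qchar(37), nchar(seqs))
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(id = ids, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

# Random sense insert of a given length starting with ATG (no in-frame
# stop codons: built from NNS codons minus TAG).
random_insert <- function(len) {
  n_cod <- ceiling((len - 3) / 3)
  repeat {
    cod <- paste0(sample(c("A", "C", "G", "T"), n_cod, TRUE),
                  sample(c("A", "C", "G", "T"), n_cod, TRUE),
                  sample(c("G", "C"), n_cod, TRUE))
    if (!any(cod == "TAG")) break
  }
  substr(paste0("ATG", paste(cod, collapse = "")), 1, len)
}

# Substitute bases at given positions of a sequence (cycles replacements).
subst_at <- function(seq, pos, repl = "N") {
  for (i in seq_along(pos)) {
    substr(seq, pos[i], pos[i]) <- substr(repl, (i - 1) %% nchar(repl) + 1,
                                          (i - 1) %% nchar(repl) + 1)
  }
  seq
}

# Build a nucleotide coding sequence for a peptide (first listed codon of
# each amino acid; deterministic).
nt_for_peptide <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  first_codon <- vapply(strsplit(pep, "")[[1]], function(a) {
    names(gc)[gc == a][1]
  }, character(1))
  paste(first_codon, collapse = "")
}

# Wild-type peptide and coding sequence used by the focused-library tests.
WT_PEP <- "MKTIHQFKDSVN"
WT_NT <- "ATGAAAACCATTCACCAATTCAAGGATAGCGTGAAC"

# Build a ProcessedRead-like data.frame directly (sequences start at the
# ATG; end_pos = sequence length).
processed_df <- function(seqs, ids = sprintf("p%03d", seq_along(seqs))) {
  data.frame(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
             end_pos = nchar(seqs), stringsAsFactors = FALSE)
}
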