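# Trimming and filtering of merged reads.

#' Trim 5' and 3' flanking sequences
#'
#' The 5' flank is matched as a prefix and the 3' linker flank as a
#' suffix, each allowing up to `max_mismatch` substitutions (Hamming
#' distance; the flanks are fixed length, so no gaps are modelled).
#' Trimming leaves the start codon directly at the 5' end and the RNase R
#' cleavage site at the 3' end.  Reads whose interior would be shorter
#' than 3 nt (overlapping flank placements) are rejected on the 3' side.
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`.
#' @param flank5,flank3 Flanking sequences.
#' @param max_mismatch Maximum substitutions tolerated in each flank.
#' @return data.frame `id`, `seq`, `qual`, `end_pos`, `status`; `status`
#'   is `"ok"`, `"flank5_mismatch"` or `"flank3_mismatch"`, and `seq` /
#'   `qual` hold the trimmed interior for `"ok"` rows (`end_pos` its
#'   length, i.e. the 1-based 3'-end coordinate relative to the ATG).
#' @export
trim_flanks <- function(reads, flank5 = FLANK5_DEFAULT,
                        flank3 = FLANK3_DEFAULT, max_mismatch = 2L) {
  if (!nzchar(flank5) || !nzchar(flank3)) stop("flanks must be non-empty")
  seqs <- toupper(reads$seq)
  qual <- if (!is.null(reads$qual)) reads$qual else strrep("I", nchar(seqs))
  n5 <- nchar(flank5); n3 <- nchar(flank3)
  len <- nchar(seqs)

  d5 <- hamming_to_ref(substr(seqs, 1L, n5), flank5)
  d5[len < n5] <- n5
  suff <- substr(seqs, pmax(len - n3 + 1L, 1L), len)
  d3 <- hamming_to_ref(suff, flank3)
  d3[len < n3] <- n3

  status <- rep("ok", length(seqs))
  status[d3 > max_mismatch | (len - n5 - n3) < 3L] <- "flank3_mismatch"
  status[d5 > max_mismatch] <- "flank5_mismatch"  # 5' side checked first

  ok <- status == "ok"
  out_seq <- out_qual <- rep(NA_character_, length(seqs))
  out_seq[ok] <- substr(seqs[ok], n5 + 1L, len[ok] - n3)
  out_qual[ok] <- substr(qual[ok], n5 + 1L, len[ok] - n3)
  data.frame(id = reads$id, seq = out_seq, qual = out_qual,
             end_pos = ifelse(ok, len - n5 - n3, NA_integer_),
             status = status, stringsAsFactors = FALSE)
}

#' Apply poly-A, start-codon and quality filters
#'
#' Filters are applied in a fixed first-fail order so that rejection
#' reports are deterministic: (1) poly-A: at least `polya_count` 'A'
#' bases within the first `polya_window` nucleotides; (2) missing ATG at
#' the 5' end; (3) any base call within the quality window (intersected
#' with the read) below `min_q`.
#'
#' @param pr Trimmed reads from [trim_flanks()] (rows with status `"ok"`).
#' @param quality_roi Inclusive 1-based nucleotide interval whose base
#'   calls must all reach `min_q` (default 24-47).
#' @param min_q Minimum Phred score inside the window (default 30).
#' @param polya_count,polya_window Poly-A filter parameters (default 18
#'   within 22).
#' @return Character vector per read: `"pass"`, `"polyA"`, `"no_start"`
#'   or `"low_quality"`.
#' @export
filter_reads <- function(pr, quality_roi = c(24L, 47L), min_q = 30L,
                         polya_count = 18L, polya_window = 22L) {
  if (length(quality_roi) != 2L || quality_roi[1L] > quality_roi[2L]) {
    stop("quality_roi must be an inclusive interval lo <= hi")
  }
  seqs <- pr$seq
  head_nt <- substr(seqs, 1L, polya_window)
  n_a <- nchar(head_nt) - nchar(gsub("A", "", head_nt, fixed = TRUE))
  minq <- phred_min_in_window(pr$qual, quality_roi[1L], quality_roi[2L])

  status <- rep("pass", nrow(pr))
  status[minq < min_q] <- "low_quality"
  status[substr(seqs, 1L, 3L) != "ATG"] <- "no_start"
  status[n_a >= polya_count] <- "polyA"   # assigned last = checked first
  status
}

#' Region-of-interest selection on the fragment 3' end
#'
#' Retains reads whose RNase R cleavage position (`end_pos`, nucleotides
#' downstream of the start codon) lies inside the given window.  The
#' default 24-47 corresponds to ribosomes stalled after translating
#' roughly 2-10 codons, the range in which fragment sizes show clean
#' tri-nucleotide periodicity.
#'
#' @param end_pos Integer vector of 3'-end positions.
#' @param window Inclusive interval, default `c(24, 47)`.
#' @return Logical vector.
#' @export
select_roi <- function(end_pos, window = c(24L, 47L)) {
  if (length(window) != 2L || window[1L] > window[2L]) {
    stop("window must be an inclusive interval lo <= hi")
  }
  !is.na(end_pos) & end_pos >= window[1L] & end_pos <= window[2L]
}

FILTER_REASONS <- c("flank5_mismatch", "flank3_mismatch", "polyA",
                    "no_start", "low_quality", "outside_roi")

#' Trim and filter a set of merged reads
#'
#' Runs [trim_flanks()], [filter_reads()] and [select_roi()] and tallies
#' a first-fail rejection report whose counts, together with the pass
#' count, sum to the number of input reads.
#'
#' @inheritParams trim_flanks
#' @inheritParams filter_reads
#' @param end_window Window on the fragment 3' end ([select_roi()]);
#'   `NULL` disables the size selection.
#' @return list with `reads` (passing reads: `id`, `seq`, `qual`,
#'   `end_pos`) and `report` (data.frame `reason`, `n`).
#' @export
process_reads <- function(reads, flank5 = FLANK5_DEFAULT,
                          flank3 = FLANK3_DEFAULT, max_mismatch = 2L,
                          quality_roi = c(24L, 47L), min_q = 30L,
                          polya_count = 18L, polya_window = 22L,
                          end_window = c(24L, 47L)) {
  tr <- trim_flanks(reads, flank5, flank3, max_mismatch)
  status <- tr$status
  ok <- status == "ok"
  if (any(ok)) {
    st2 <- filter_reads(tr[ok, , drop = FALSE], quality_roi, min_q,
                        polya_count, polya_window)
    if (!is.null(end_window)) {
      in_roi <- select_roi(tr$end_pos[ok], end_window)
      st2[st2 == "pass" & !in_roi] <- "outside_roi"
    }
    status[ok] <- st2
  }
  counts <- vapply(c(FILTER_REASONS, "pass"),
                   function(r) sum(status == r), integer(1L))
  keep <- status == "pass"
  list(reads = tr[keep, c("id", "seq", "qual", "end_pos")],
       report = data.frame(reason = names(counts), n = unname(counts),
                           stringsAsFactors = FALSE))
}
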