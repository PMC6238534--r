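# Focused-library (deep mutational) variant analysis.

#' Extract the fixed-length variant window from processed reads
#'
#' Variant calling compares peptides over a window matching the wild-type
#' length, so only reads whose protected region covers the full window
#' are usable; shorter reads (ribosomes stalled too early) are dropped
#' and counted.
#'
#' @param pr Processed reads (`id`, `seq`, `end_pos`).
#' @param wt_len Wild-type peptide length (codons).
#' @return data.frame `id`, `peptide` (length `wt_len`), `nt` (the
#'   underlying `3 * wt_len` nucleotides); attribute `n_dropped` counts
#'   reads too short for the window.
#' @export
variant_window <- function(pr, wt_len) {
  need <- 3L * wt_len
  keep <- pr$end_pos >= need
  nt <- substr(pr$seq[keep], 1L, need)
  pep <- translate_nt(nt)
  # nonsense windows do not encode a full-length peptide variant
  sense <- !grepl("*", pep, fixed = TRUE)
  out <- data.frame(id = pr$id[keep][sense], peptide = pep[sense],
                    nt = nt[sense], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_nonsense") <- sum(!sense)
  out
}

#' Call peptide variants against a wild type
#'
#' Groups reads by their translated peptide over the wild-type window,
#' recording the substitution count versus the wild type, per-sample read
#' counts and the number of distinct nucleotide sequences yielding each
#' peptide (independent mutational origins).  Indels are not modelled:
#' the libraries are substitution-mutagenised, and length-mismatched
#' reads have already been dropped by [variant_window()].
#'
#' @param samples Named list of data.frames from [variant_window()] (one
#'   per sample).
#' @param wt Wild-type peptide (length must match the window).
#' @return data.frame of class `VariantTable`: `peptide`, `n_mut`, one
#'   count column per sample (`n_<sample>`), `n_nt_variants`.
#' @export
call_variants <- function(samples, wt) {
  stopifnot(is.list(samples), length(names(samples)) == length(samples))
  L <- nchar(wt)
  pieces <- lapply(names(samples), function(s) {
    x <- samples[[s]]
    bad <- nchar(x$peptide) != L
    if (any(bad)) {
      warning(sum(bad), " length-mismatched read(s) excluded from sample ", s)
      x <- x[!bad, , drop = FALSE]
    }
    data.table(sample = s, peptide = x$peptide, nt = x$nt)
  })
  dt <- rbindlist(pieces)
  counts <- dcast(dt[, list(n = .N), by = c("peptide", "sample")],
                  peptide ~ sample, value.var = "n", fill = 0L)
  ntv <- dt[, list(n_nt_variants = length(unique(nt))), by = "peptide"]
  out <- as.data.frame(merge(counts, ntv, by = "peptide"))
  for (s in setdiff(names(samples), names(out))) out[[s]] <- 0L
  present <- match(names(samples), names(out))
  names(out)[present] <- paste0("n_", names(samples))
  out$n_mut <- hamming_to_ref(out$peptide, wt)
  out <- out[order(-out$n_nt_variants, out$peptide),
             c("peptide", "n_mut", paste0("n_", names(samples)),
               "n_nt_variants")]
  rownames(out) <- NULL
  class(out) <- c("VariantTable", "data.frame")
  out
}

#' Per-variant enrichment of a selected sample over the input library
#'
#' Fold change of each variant's frequency (count / sample total) in the
#' selected sample relative to the input library.  Variants absent from
#' the input have undefined fold change (`NA`, flagged); variants absent
#' from the selected sample give 0.
#'
#' @param vt A `VariantTable` from [call_variants()].
#' @param selected,input Sample names (count columns `n_<name>` of `vt`).
#' @return data.frame `peptide`, `n_selected`, `n_input`, `FC`,
#'   `undefined`.
#' @export
variant_enrichment <- function(vt, selected, input) {
  cs <- vt[[paste0("n_", selected)]]
  ci <- vt[[paste0("n_", input)]]
  if (is.null(cs) || is.null(ci)) stop("unknown sample name")
  ts <- sum(cs); ti <- sum(ci)
  if (ts == 0L || ti == 0L) stop("sample with zero total reads")
  fs <- cs / ts; fi <- ci / ti
  data.frame(peptide = vt$peptide, n_selected = cs, n_input = ci,
             FC = ifelse(fi > 0, fs / fi, NA_real_),
             undefined = fi == 0, stringsAsFactors = FALSE)
}

#' Select variants that discriminate between two conditions
#'
#' Keeps variants with at least `min_combined` reads combined across the
#' two selected samples that are enriched at least `fc_min`-fold over the
#' input library in exactly one of the two conditions (exclusive or):
#' variants enriched in both or neither are rejected.
#'
#' @param fcA,fcB Enrichment tables from [variant_enrichment()] for
#'   conditions A and B (shared variant universe).
#' @param min_combined Combined selected-sample read threshold
#'   (default 150).
#' @param fc_min Enrichment threshold (default 2).
#' @return data.frame `peptide`, `FC_A`, `FC_B`, `combined_reads`,
#'   `selected_for` (`"A"` or `"B"`).
#' @export
select_discriminating <- function(fcA, fcB, min_combined = 150L,
                                  fc_min = 2.0) {
  m <- merge(fcA[, c("peptide", "n_selected", "FC")],
             fcB[, c("peptide", "n_selected", "FC")],
             by = "peptide", suffixes = c("_A", "_B"))
  m$combined_reads <- m$n_selected_A + m$n_selected_B
  hitA <- !is.na(m$FC_A) & m$FC_A >= fc_min
  hitB <- !is.na(m$FC_B) & m$FC_B >= fc_min
  sel <- m$combined_reads >= min_combined & xor(hitA, hitB)
  out <- m[sel, c("peptide", "FC_A", "FC_B", "combined_reads")]
  out$selected_for <- ifelse(hitA[sel], "A", "B")
  out <- out[order(-out$combined_reads), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position residue over/under-representation
#'
#' For each peptide position and residue, the log2 ratio of the residue's
#' frequency in the foreground read set versus the background read set,
#' smoothed with epsilon = 1 / (n_bg + 20) so that residues absent from
#' one set remain finite.  A two-sided binomial tail p-value is reported
#' per cell, testing the foreground count against a smoothed background
#' frequency `(count_bg + 0.5) / (n_bg + 1)` (the smoothing keeps cells
#' absent from the background from being declared infinitely
#' significant); it is descriptive and uncorrected.  The log2 ratio is
#' the effect size; cells are ranked by evidence via
#' [top_enriched_cells()].
#'
#' @param fg,bg Character vectors of equal-length peptides (foreground
#'   and background read sets, one entry per read).
#' @return data.frame of class `PositionEnrichment`: `position`,
#'   `residue`, `count_fg`, `count_bg`, `f_fg`, `f_bg`, `log2_ratio`,
#'   `p_value`.
#' @export
position_enrichment <- function(fg, bg) {
  L <- unique(c(nchar(fg), nchar(bg)))
  if (length(L) != 1L) stop("all peptides must have equal length")
  n_fg <- length(fg); n_bg <- length(bg)
  eps <- 1 / (n_bg + 20)
  residues <- sort(unique(unlist(
    lapply(seq_len(L), function(i) unique(c(substr(fg, i, i),
                                            substr(bg, i, i)))))))
  rows <- lapply(seq_len(L), function(i) {
    cf <- table(factor(substr(fg, i, i), levels = residues))
    cb <- table(factor(substr(bg, i, i), levels = residues))
    f_fg <- as.numeric(cf) / n_fg
    f_bg <- as.numeric(cb) / n_bg
    k <- as.numeric(cf)
    p0 <- (as.numeric(cb) + 0.5) / (n_bg + 1)
    pv <- pmin(1, 2 * pmin(pbinom(k, n_fg, p0),
                           1 - pbinom(k - 1, n_fg, p0)))
    data.frame(position = i, residue = residues,
               count_fg = as.integer(cf), count_bg = as.integer(cb),
               f_fg = f_fg, f_bg = f_bg,
               log2_ratio = log2((f_fg + eps) / (f_bg + eps)),
               p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("PositionEnrichment", "data.frame")
  out
}

#' Top overrepresented position/residue cells
#'
#' Ranks overrepresented cells (`f_fg > f_bg`) of a
#' [position_enrichment()] table by their binomial evidence (p-value,
#' with the log2 ratio breaking ties); low-count cells with large but
#' poorly supported ratios rank below well-supported enrichments.
#'
#' @param pe A `PositionEnrichment` table.
#' @param n Number of cells to return.
#' @return The top `n` rows.
#' @export
top_enriched_cells <- function(pe, n = 3L) {
  up <- pe[pe$f_fg > pe$f_bg, , drop = FALSE]
  up <- up[order(up$p_value, -up$log2_ratio), , drop = FALSE]
  head(up, n)
}
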