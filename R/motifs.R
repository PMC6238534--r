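# Tripeptide / tricodon motif statistics: frequencies, pause strengths,
# replicate error models, fold changes and enrichment classes.

#' Translate the ribosome-protected region of each read
#'
#' Assigns a P-site codon via [assign_psite()], then translates codons 1
#' through p + 1; the final symbol is the A-site residue ('*' when the
#' A-site codon is the UAG stop).  The protected mRNA downstream of the
#' A-site codon is excluded from translation.  Reads with an internal
#' (pre-A-site) stop codon cannot arise from NNS designs; elsewhere they
#' are flagged and excluded from motif counting, with a warning.
#'
#' @param pr Processed reads (data.frame with `id`, `seq`, `end_pos`).
#' @param offset Cleavage offset passed to [assign_psite()].
#' @return data.frame `id`, `seq`, `end_pos`, `p_site`, `peptide` (length
#'   p + 1, A-site last), `a_site`, `excluded`; attribute `n_total` holds
#'   the number of processed reads (the denominator of motif
#'   frequencies), including reads excluded from counting.
#' @export
translate_protected <- function(pr, offset = 17L) {
  p <- assign_psite(pr$end_pos, offset)
  pep <- rep(NA_character_, nrow(pr))
  ok <- !is.na(p)
  if (any(ok)) {
    pep[ok] <- translate_nt(substr(pr$seq[ok], 1L, 3L * (p[ok] + 1L)))
  }
  a_site <- ifelse(ok, substr(pep, nchar(pep), nchar(pep)), NA_character_)
  internal_stop <- partial_a <- logical(nrow(pr))
  if (any(ok)) {
    internal_stop[ok] <- grepl("*", substr(pep[ok], 1L, p[ok]), fixed = TRUE)
    partial_a[ok] <- nchar(pep[ok]) < p[ok] + 1L  # A-site codon incomplete
  }
  if (any(internal_stop)) {
    warning(sum(internal_stop),
            " read(s) with an internal stop codon excluded from motif counting")
  }
  out <- data.frame(id = pr$id, seq = pr$seq, end_pos = pr$end_pos,
                    p_site = p, peptide = pep, a_site = a_site,
                    excluded = !ok | internal_stop | partial_a,
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- nrow(pr)
  out
}

# Build a completed MotifTable from stall (nP) and bypass (nB) count
# data.tables keyed by motif.
.motif_table <- function(nP_dt, nB_dt, kind, n_total) {
  motifs <- if (kind == "aa3") {
    union(aa_motif_space(), union(nP_dt$motif, nB_dt$motif))
  } else {
    union(nP_dt$motif, nB_dt$motif)
  }
  out <- data.table(motif = motifs)
  out <- merge(out, nP_dt, by = "motif", all.x = TRUE)
  out <- merge(out, nB_dt, by = "motif", all.x = TRUE)
  out[is.na(out$nP), "nP"] <- 0L
  out[is.na(out$nB), "nB"] <- 0L
  out <- as.data.frame(out)
  out$F <- out$nP / n_total
  out$sense <- !grepl("*", out$motif, fixed = TRUE)
  out <- out[order(out$motif), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  attr(out, "n_total") <- n_total
  class(out) <- c("MotifTable", "data.frame")
  out
}

# Extract the 3-symbol motif centred on position i (P-site) of a read,
# in amino-acid or codon coordinates.
.motif_at <- function(tp, i, kind) {
  if (kind == "aa3") {
    substr(tp$peptide, i - 1L, i + 1L)
  } else {
    paste(substr(tp$seq, 3L * i - 5L, 3L * i - 3L),
          substr(tp$seq, 3L * i - 2L, 3L * i),
          substr(tp$seq, 3L * i + 1L, 3L * i + 3L), sep = ".")
  }
}

#' Count stalled and bypassed tripeptide (or tricodon) motifs
#'
#' For every read with P-site codon p >= 2, the terminal motif
#' (aa[p-1], aa[p], A-site symbol) gains one stall count (`nP`), and each
#' interior motif centred on positions 2 <= i < p gains a bypass count
#' (`nB`) - at most once per read per motif under the default read-level
#' mode (`nB` counts reads that translated through the motif; the
#' occurrence-level variant counts every occurrence).  Motif frequencies
#' are `F = nP / n_total` with `n_total` all processed reads in the
#' sample, including reads that contribute no terminal motif.
#'
#' @param tp Translated reads from [translate_protected()].
#' @param kind `"aa3"` (tripeptide) or `"codon3"` (tricodon; codons are
#'   joined with '.').
#' @param bypass `"read"` (default) or `"occurrence"`.
#' @param n_total Override the processed-read total (defaults to the
#'   `n_total` attribute of `tp`).
#' @return A `MotifTable` data.frame: `motif`, `nP`, `nB`, `F`, `sense`
#'   (FALSE for motifs with '*' in the A-site position, which are tallied
#'   separately from the 8000-member sense space).
#' @export
count_motifs <- function(tp, kind = c("aa3", "codon3"),
                         bypass = c("read", "occurrence"), n_total = NULL) {
  kind <- match.arg(kind)
  bypass <- match.arg(bypass)
  if (is.null(n_total)) n_total <- attr(tp, "n_total")
  if (is.null(n_total)) n_total <- nrow(tp)

  use <- !tp$excluded & !is.na(tp$p_site) & tp$p_site >= 2L
  tpu <- tp[use, , drop = FALSE]
  p <- tpu$p_site

  if (nrow(tpu)) {
    term <- .motif_at(tpu, p, kind)
    nP_dt <- data.table(motif = term)[, list(nP = .N), by = "motif"]
  } else {
    nP_dt <- data.table(motif = character(), nP = integer())
  }

  pieces <- list()
  if (nrow(tpu) && max(p) >= 3L) {
    for (i in 2L:(max(p) - 1L)) {
      sel <- which(p > i)
      if (!length(sel)) next
      pieces[[length(pieces) + 1L]] <- data.table(
        read = sel, motif = .motif_at(tpu[sel, , drop = FALSE], i, kind))
    }
  }
  if (length(pieces)) {
    byp <- rbindlist(pieces)
    if (bypass == "read") byp <- unique(byp, by = c("read", "motif"))
    nB_dt <- byp[, list(nB = .N), by = "motif"]
  } else {
    nB_dt <- data.table(motif = character(), nB = integer())
  }
  .motif_table(nP_dt, nB_dt, kind, n_total)
}

#' Motif occurrence table for an unselected input library
#'
#' In the sequenced input library no ribosome has stalled, so every
#' in-frame motif position of the coding region counts as an encounter.
#' Occurrences are counted read-level (at most once per read per motif)
#' over positions 2..L-1 of the sense coding region (up to the first
#' stop), and frequencies are occurrences / `n_total`.
#'
#' @param seqs Nucleotide sequences starting at the ATG (full templates
#'   or full-length reads).
#' @param kind `"aa3"` or `"codon3"`.
#' @param n_total Denominator (defaults to `length(seqs)`).
#' @return A `MotifTable` with `nP` = occurrence counts and `nB` = 0.
#' @export
input_motif_table <- function(seqs, kind = c("aa3", "codon3"),
                              n_total = length(seqs)) {
  kind <- match.arg(kind)
  pep <- translate_nt(seqs)
  stop_at <- regexpr("*", pep, fixed = TRUE)
  L_eff <- ifelse(stop_at > 0L, stop_at - 1L, nchar(pep))
  tp <- data.frame(seq = seqs, peptide = pep, stringsAsFactors = FALSE)
  pieces <- list()
  if (length(seqs) && max(L_eff) >= 3L) {
    for (i in 2L:(max(L_eff) - 1L)) {
      sel <- which(L_eff >= i + 1L)
      if (!length(sel)) next
      pieces[[length(pieces) + 1L]] <- data.table(
        read = sel, motif = .motif_at(tp[sel, , drop = FALSE], i, kind))
    }
  }
  if (length(pieces)) {
    occ <- unique(rbindlist(pieces), by = c("read", "motif"))
    nP_dt <- occ[, list(nP = .N), by = "motif"]
  } else {
    nP_dt <- data.table(motif = character(), nP = integer())
  }
  .motif_table(nP_dt, data.table(motif = character(), nB = integer()),
               kind, n_total)
}

#' Pause strength per motif
#'
#' The pause strength of a motif is `nP / (nP + nB)`: the fraction of
#' ribosome encounters with the motif that ended in a stall rather than
#' read-through.  A value of 1 means ribosomes never bypass the motif; a
#' value of 0.2 means 80% of encountering ribosomes translated through
#' and stalled elsewhere.  Motifs never encountered (nP + nB = 0) have
#' undefined pause strength (`NA`).
#'
#' @param mt A `MotifTable`.
#' @return The table with an added `PS` column.
#' @export
pause_strength <- function(mt) {
  tot <- mt$nP + mt$nB
  mt$PS <- ifelse(tot > 0L, mt$nP / tot, NA_real_)
  mt
}

#' Predicted replicate-fraction SD under binomial partitioning
#'
#' If a motif's reads were split between two replicates purely at random
#' (binomially, with success probability equal to replicate 1's share of
#' the total), the SD of the replicate-1 fraction across motifs with a
#' common total `total` approaches `sqrt(prob * (1 - prob) / total)`.
#' This simulates that partition.
#'
#' @param total Combined read count per motif.
#' @param n_motifs Number of simulated motifs.
#' @param prob Replicate-1 share of reads (0.5 for equal replicates).
#' @return SD across motifs of the simulated replicate-1 fraction.
#' @export
predicted_partition_sd <- function(total, n_motifs = 10000L, prob = 0.5) {
  if (total < 1L) stop("total must be >= 1")
  sd(rbinom(n_motifs, total, prob) / total)
}

#' Replicate counting-noise model by binomial partitioning
#'
#' Compares, per bin of combined read count, the observed SD of the
#' replicate-1 fraction across motifs with the SD predicted if reads
#' were randomly partitioned between replicates in proportion to the
#' replicate totals.  Agreement indicates that counting statistics
#' dominate the inter-replicate error; the read-count threshold is the
#' smallest bin whose predicted SD falls below `sd_cutoff`.
#'
#' @param tabA,tabB `MotifTable`s for the two replicates of a condition.
#' @param breaks Bin breaks on the combined count (right-closed).
#' @param n_sim Simulated motifs per bin for the prediction.
#' @param sd_cutoff SD level defining the threshold (default 0.05).
#' @param seed Optional seed for the simulated partitions.
#' @return list of class `PartitionErrorModel`: `bins` (data.frame
#'   `bin_total` (median combined count), `n_motifs`, `sd_observed`,
#'   `sd_predicted`), `threshold` (smallest `bin_total` with predicted SD
#'   < `sd_cutoff`), `prob` (replicate-1 share).
#' @export
partition_error_model <- function(tabA, tabB,
                                  breaks = c(0, 2, 5, 10, 20, 50, 100, 150,
                                             250, 500, 1000, 2000, Inf),
                                  n_sim = 2000L, sd_cutoff = 0.05,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- merge(tabA[, c("motif", "nP")], tabB[, c("motif", "nP")],
             by = "motif", suffixes = c("_A", "_B"))
  m$total <- m$nP_A + m$nP_B
  m <- m[m$total > 0L, , drop = FALSE]
  prob <- sum(m$nP_A) / sum(m$total)
  bin <- cut(m$total, breaks = breaks)
  res <- lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    if (length(sel) < 2L) return(NULL)
    tot_med <- round(stats::median(m$total[sel]))
    data.frame(bin = b, bin_total = tot_med, n_motifs = length(sel),
               sd_observed = sd(m$nP_A[sel] / m$total[sel]),
               sd_predicted = predicted_partition_sd(tot_med, n_sim, prob),
               stringsAsFactors = FALSE)
  })
  empty <- sum(vapply(res, is.null, logical(1L)))
  if (empty > 0L) warning(empty, " empty/singleton bin(s) skipped")
  bins <- do.call(rbind, res)
  thr <- bins$bin_total[bins$sd_predicted < sd_cutoff]
  structure(list(bins = bins,
                 threshold = if (length(thr)) min(thr) else NA_integer_,
                 prob = prob),
            class = "PartitionErrorModel")
}

#' Fold changes between conditions with propagated replicate errors
#'
#' Per motif, replicate frequencies are averaged within the foreground
#' and background conditions, `F = (F1 + F2) / 2`, with inter-replicate
#' spread `dF = |F1 - F2|`.  The fold change is `FC = F_fg / F_bg` and
#' its propagated error
#' `dFC = sqrt((dF_bg / F_bg)^2 + (dF_fg / F_fg)^2) * FC`.
#' A motif is well measured when its combined stall count across all
#' supplied replicate tables exceeds `min_counts`.
#'
#' @param fg,bg Lists of one or two `MotifTable`s (replicates of the
#'   foreground and background condition).
#' @param min_counts Well-measured threshold on the combined count
#'   (strict: `> min_counts`), default 150.
#' @param pseudo Optional pseudo-count added to `nP` before frequencies
#'   (default 0: motifs absent from the background give `FC = NA`,
#'   flagged `undefined`).
#' @return data.frame of class `EnrichmentTable`: `motif`, `F_fg`,
#'   `F_bg`, `dF_fg`, `dF_bg`, `FC`, `dFC`, `log2FC`, `n_reads`,
#'   `well_measured`, `undefined`, `sense`.
#' @export
fold_change <- function(fg, bg, min_counts = 150L, pseudo = 0) {
  if (inherits(fg, "MotifTable")) fg <- list(fg)
  if (inherits(bg, "MotifTable")) bg <- list(bg)
  stopifnot(length(fg) >= 1L, length(bg) >= 1L)
  kinds <- vapply(c(fg, bg), attr, character(1L), "kind")
  if (length(unique(kinds)) != 1L) stop("all tables must share one motif kind")
  if (length(fg) == 1L || length(bg) == 1L) {
    message("single-replicate input: inter-replicate errors unavailable")
  }

  freq <- function(tab, motifs) {
    i <- match(motifs, tab$motif)
    nP <- ifelse(is.na(i), 0L, tab$nP[i])
    (nP + pseudo) / attr(tab, "n_total")
  }
  counts <- function(tab, motifs) {
    i <- match(motifs, tab$motif)
    ifelse(is.na(i), 0L, tab$nP[i])
  }
  motifs <- sort(Reduce(union, lapply(c(fg, bg), `[[`, "motif")))
  Ffg <- vapply(fg, freq, numeric(length(motifs)), motifs = motifs)
  Fbg <- vapply(bg, freq, numeric(length(motifs)), motifs = motifs)
  Ffg <- matrix(Ffg, nrow = length(motifs))
  Fbg <- matrix(Fbg, nrow = length(motifs))

  F_fg <- rowMeans(Ffg); F_bg <- rowMeans(Fbg)
  dF_fg <- if (ncol(Ffg) >= 2L) abs(Ffg[, 1L] - Ffg[, 2L]) else NA_real_
  dF_bg <- if (ncol(Fbg) >= 2L) abs(Fbg[, 1L] - Fbg[, 2L]) else NA_real_
  FC <- ifelse(F_bg > 0, F_fg / F_bg, NA_real_)
  dFC <- ifelse(!is.na(FC) & F_fg > 0,
                sqrt((dF_bg / F_bg)^2 + (dF_fg / F_fg)^2) * FC, NA_real_)
  n_reads <- Reduce(`+`, lapply(c(fg, bg), counts, motifs = motifs))

  out <- data.frame(motif = motifs, F_fg = F_fg, F_bg = F_bg,
                    dF_fg = dF_fg, dF_bg = dF_bg, FC = FC, dFC = dFC,
                    log2FC = log2(FC), n_reads = n_reads,
                    well_measured = n_reads > min_counts,
                    undefined = F_bg == 0,
                    sense = !grepl("*", motifs, fixed = TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "kind") <- kinds[1L]
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Classify motifs as intrinsic or drug-dependent pausers
#'
#' Using pause strengths in the drug-treated (foreground) and untreated
#' (background) samples together with the motif's enrichment: a motif is
#' `intrinsic` when its background pause strength already reaches
#' `ps_min`; `drug_dependent` when its foreground pause strength reaches
#' `ps_min`, is at least `ps_ratio`-fold greater than background, and the
#' motif's frequency log2 fold change reaches `log2fc_min`; otherwise
#' `none`.  Only well-measured motifs are classified.
#'
#' @param ps_fg,ps_bg `MotifTable`s with a `PS` column
#'   (see [pause_strength()]) for the two conditions.
#' @param enrich An `EnrichmentTable` comparing fg to bg.
#' @param ps_min Pause-strength cutoff (default 0.25).
#' @param ps_ratio Minimum fg/bg pause-strength ratio (default 1.5).
#' @param log2fc_min Minimum log2 fold change (default 0.5).
#' @return data.frame `motif`, `PS_fg`, `PS_bg`, `log2FC`, `class`.
#' @export
classify_motifs <- function(ps_fg, ps_bg, enrich, ps_min = 0.25,
                            ps_ratio = 1.5, log2fc_min = 0.5) {
  wm <- enrich[enrich$well_measured, c("motif", "log2FC")]
  m <- merge(wm, ps_fg[, c("motif", "PS")], by = "motif")
  names(m)[names(m) == "PS"] <- "PS_fg"
  m <- merge(m, ps_bg[, c("motif", "PS")], by = "motif")
  names(m)[names(m) == "PS"] <- "PS_bg"

  intrinsic <- !is.na(m$PS_bg) & m$PS_bg >= ps_min
  drug <- !intrinsic & !is.na(m$PS_fg) & m$PS_fg >= ps_min &
    (is.na(m$PS_bg) | m$PS_fg >= ps_ratio * m$PS_bg) &
    !is.na(m$log2FC) & m$log2FC >= log2fc_min
  m$class <- ifelse(intrinsic, "intrinsic",
                    ifelse(drug, "drug_dependent", "none"))
  m[, c("motif", "PS_fg", "PS_bg", "log2FC", "class")]
}

#' Correlation of motif enrichment with codon usage
#'
#' Tests whether tricodon-motif enrichment merely reflects codon usage:
#' Pearson correlation of the motif log2 fold change against the usage
#' frequency of the motif's first, second and third codon separately,
#' over well-measured motifs with finite log2 fold change.
#'
#' @param enrich An `EnrichmentTable` over tricodon motifs (codons joined
#'   with '.').
#' @param usage Named numeric vector mapping each of the 61 sense codons
#'   to its usage frequency.
#' @return data.frame `position`, `r`, `r_squared`, `n`; `r` is `NA`
#'   (flagged by `zero_variance`) when either variable is constant.
#' @export
usage_correlation <- function(enrich, usage) {
  sense_codons <- names(.GC)[.GC != "*"]
  missing <- setdiff(sense_codons, names(usage))
  if (length(missing)) {
    stop("usage table is missing ", length(missing), " sense codon(s), e.g. ",
         paste(head(missing, 3L), collapse = ", "))
  }
  wm <- enrich[enrich$well_measured & is.finite(enrich$log2FC), , drop = FALSE]
  cods <- tstrsplit(wm$motif, ".", fixed = TRUE)
  if (length(cods) != 3L) stop("enrichment table does not hold tricodon motifs")
  out <- lapply(1:3, function(k) {
    u <- unname(usage[cods[[k]]])
    zero_var <- length(wm$log2FC) < 3L || sd(u) == 0 || sd(wm$log2FC) == 0
    r <- if (zero_var) NA_real_ else cor(wm$log2FC, u)
    data.frame(position = k, r = r, r_squared = r^2, n = nrow(wm),
               zero_variance = zero_var)
  })
  do.call(rbind, out)
}
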