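# Simulation of sequential stalling, cleavage and read rendering.

#' Simulate ribosome stalling on a template library
#'
#' Each event follows one ribosome down one template.  With probability
#' `initiation_fraction` it never leaves the start codon (cause
#' `"initiation"`, P-site codon 1).  Otherwise the ribosome walks codons
#' p = 2, 3, ...: at each step the stall probability is looked up from
#' the motif (aa[p-1], aa[p], aa_or_stop[p+1]) (see [pause_model()]) and a
#' Bernoulli trial decides whether it stalls there.  The first success
#' yields cause `"motif"` (sense A-site) or `"stop_pause"` (UAG A-site).
#' A ribosome that reaches a stop codon without stalling is released
#' (cause `"readthrough"`); such events are flagged for removal, mirroring
#' the restriction digest that eliminates non-stalled messages.
#'
#' @param templates A `TemplateSet` (or a single template row of one).
#' @param pm A `PauseModel`.
#' @param reads_per_template Number of independent ribosomes walked down
#'   each template.
#' @param seed Optional integer seed.
#' @return data.frame with one row per event: `template_id`,
#'   `p_site_codon` (codon 1 = ATG), `cause` in
#'   `{"motif","stop_pause","initiation","readthrough"}`.
#' @export
simulate_stalling <- function(templates, pm, reads_per_template = 1L,
                              seed = NULL) {
  stopifnot(inherits(templates, "TemplateSet"), inherits(pm, "PauseModel"))
  if (!is.null(seed)) set.seed(seed)

  seqs <- templates$templates$nt_sequence
  ids <- templates$templates$id
  n_codons <- max(nchar(seqs)) %/% 3L
  cm <- codon_matrix(seqs, n_codons)
  aa <- translate_codon_matrix(cm)

  # first in-frame stop per template (the walk cannot continue past it)
  is_stop <- !is.na(aa) & aa == "*"
  stop_idx <- apply(is_stop, 1L, function(z) {
    w <- which(z)
    if (!length(w)) NA_integer_ else w[1L]
  })
  if (anyNA(stop_idx)) {
    bad <- ids[which(is.na(stop_idx))[1L]]
    stop("template ", bad, " has no in-frame stop codon; cannot simulate")
  }

  # per-(template, p) stall probabilities for p = 2 .. stop_idx - 1
  n <- length(seqs)
  p_max <- max(stop_idx) - 1L
  prob <- matrix(0, n, p_max)
  for (p in 2:p_max) {
    active <- stop_idx - 1L >= p
    if (!any(active)) next
    a_stop <- is_stop[, p + 1L]
    motif <- paste0(aa[, p - 1L], aa[, p],
                    ifelse(a_stop, "*", aa[, p + 1L]))
    pr <- unname(pm$motif_pause[motif])
    fallback <- ifelse(a_stop & cm[, p + 1L] == "TAG", pm$stop_pause,
                       ifelse(a_stop, 0, pm$default_pause))
    pr[is.na(pr)] <- fallback[is.na(pr)]
    prob[, p] <- ifelse(active, pr, 0)
  }
  prob[, 1L] <- 0

  # expand to events and draw the walk
  ev_t <- rep(seq_len(n), times = reads_per_template)
  m <- length(ev_t)
  u <- matrix(runif(m * p_max), m, p_max)
  hit <- u < prob[ev_t, , drop = FALSE]
  first <- rep(NA_integer_, m)
  w <- which(hit, arr.ind = TRUE)
  if (nrow(w)) {
    dt <- data.table(row = w[, 1L], col = w[, 2L])
    agg <- dt[, list(col = min(col)), by = row]
    first[agg$row] <- agg$col
  }

  p_site <- ifelse(is.na(first), stop_idx[ev_t] - 1L, first)
  a_is_stop <- is_stop[cbind(ev_t, pmin(p_site + 1L, ncol(is_stop)))]
  cause <- ifelse(is.na(first), "readthrough",
                  ifelse(a_is_stop, "stop_pause", "motif"))

  if (pm$initiation_fraction > 0) {
    init <- runif(m) < pm$initiation_fraction
    p_site[init] <- 1L
    cause[init] <- "initiation"
  }

  data.frame(template_id = ids[ev_t], p_site_codon = as.integer(p_site),
             cause = cause, stringsAsFactors = FALSE)
}

# Phred+33 quality string generators.
quality_string <- function(lens, model = c("constant", "decay"), q0 = 37L) {
  model <- match.arg(model)
  maxlen <- max(lens, 0L)
  if (maxlen == 0L) return(rep("", length(lens)))
  if (model == "constant") {
    full <- strrep(intToUtf8(q0 + 33L), maxlen)
  } else {
    q <- pmax(2L, q0 - (seq_len(maxlen) - 1L) %/% 10L)
    full <- intToUtf8(q + 33L, multiple = FALSE)
  }
  substr(rep(full, length(lens)), 1L, lens)
}

#' Render stall events into sequencing reads
#'
#' Every retained event becomes one merged read: the 5' flank, the
#' template from the ATG through the cleavage position, and the 3' linker
#' flank.  The cleavage position is `3 * p_site_codon + offset - jitter`,
#' i.e. the configured distance downstream of the last nucleotide of the
#' P-site codon, with jitter drawn from the cleavage model.  Readthrough
#' events are dropped (the restriction-digest analogue) except for a
#' configurable contaminant fraction, which is rendered full length
#' (stop-protected geometry).  Events whose cleavage position would fall
#' beyond the template end are skipped with a warning.
#'
#' @param events data.frame from [simulate_stalling()].
#' @param templates The `TemplateSet` the events refer to.
#' @param cleavage A `CleavageModel`.
#' @param substitution_rate Per-base sequencing error rate.
#' @param quality `"constant"` (Q37 throughout) or `"decay"`.
#' @param readthrough_keep_fraction Fraction of readthrough events emitted
#'   as full-length contaminants (default 0: all dropped).
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for read identifiers.
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (data.frame `read_id`, `template_id`, `p_site_codon`, `cleavage_pos`,
#'   `cause`); `cleavage_pos` is 1-based from the first nucleotide of the
#'   ATG.
#' @export
render_reads <- function(events, templates, cleavage = cleavage_model(),
                         substitution_rate = 0,
                         quality = c("constant", "decay"),
                         readthrough_keep_fraction = 0, seed = NULL,
                         id_prefix = "read") {
  stopifnot(inherits(templates, "TemplateSet"),
            inherits(cleavage, "CleavageModel"))
  quality <- match.arg(quality)
  if (!is.null(seed)) set.seed(seed)

  tmap <- setNames(templates$templates$nt_sequence, templates$templates$id)
  if (!all(events$template_id %in% names(tmap))) {
    stop("events reference unknown template ids")
  }

  keep <- events$cause != "readthrough"
  if (readthrough_keep_fraction > 0) {
    rt <- which(!keep)
    keep[rt] <- runif(length(rt)) < readthrough_keep_fraction
  }
  ev <- events[keep, , drop = FALSE]
  n <- nrow(ev)
  if (!n) {
    return(list(reads = data.frame(id = character(), seq = character(),
                                   qual = character(),
                                   stringsAsFactors = FALSE),
                truth = data.frame(read_id = character(),
                                   template_id = character(),
                                   p_site_codon = integer(),
                                   cleavage_pos = integer(),
                                   cause = character(),
                                   stringsAsFactors = FALSE)))
  }

  delta <- sample(0:2, n, replace = TRUE, prob = cleavage$jitter_probs)
  end <- 3L * ev$p_site_codon + cleavage$offset - delta
  tseq <- unname(tmap[ev$template_id])
  # readthrough contaminants carry the stop-protected full geometry too;
  # anything extending past the template is a defective event
  ok <- end <= nchar(tseq)
  if (!all(ok)) {
    warning(sum(!ok), " event(s) skipped: cleavage position beyond template end")
    ev <- ev[ok, , drop = FALSE]
    end <- end[ok]; tseq <- tseq[ok]
    n <- nrow(ev)
  }

  insert <- substr(tseq, 1L, end)
  seqs <- paste0(templates$flank5, insert, templates$flank3)
  lens <- nchar(seqs)
  quals <- quality_string(lens, quality)

  if (substitution_rate > 0) {
    nsub <- rbinom(n, lens, substitution_rate)
    for (i in which(nsub > 0L)) {
      pos <- sample.int(lens[i], nsub[i])
      s <- strsplit(seqs[i], "")[[1L]]
      for (p in pos) {
        s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      }
      seqs[i] <- paste(s, collapse = "")
    }
  }

  ids <- sprintf("%s_%07d", id_prefix, seq_len(n))
  list(reads = data.frame(id = ids, seq = seqs, qual = quals,
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = ids, template_id = ev$template_id,
                          p_site_codon = ev$p_site_codon,
                          cleavage_pos = as.integer(end), cause = ev$cause,
                          stringsAsFactors = FALSE))
}

# Deterministic sub-seed derivation: replicate r of a master seed s uses
# (s * 48271 + r * 1009) mod (2^31 - 1), a fixed documented rule.
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(r) * 1009) %% 2147483647)
}

#' Simulate a complete inverse-toeprinting sample
#'
#' Builds one template library, then simulates `replicates` independent
#' translation reactions of that library under a shared pause model
#' (biological replicates share the pool and the biochemistry; only the
#' stochastic stalling differs).  Each replicate is written as a FASTQ
#' file plus a tab-separated ground-truth table.
#'
#' @param config list with elements: `design` (`"nns15"`,
#'   `"mutant_library"` or `"fixed"`), `n_reads` (ribosomes simulated per
#'   replicate), `replicates` (default 2), `pause_model` (a `PauseModel`),
#'   `cleavage` (a `CleavageModel`, default [cleavage_model()]), `wt`,
#'   `mutation_rate`, `substitution_rate` (default 0), `quality`
#'   (default `"constant"`), `readthrough_keep_fraction` (default 0),
#'   `out_dir` (created if missing), `name` (sample name, default
#'   `"sample"`).
#' @param seed Master integer seed; library and replicate sub-seeds are
#'   derived deterministically from it (see Details in the vignette).
#' @return list with `fastq` and `truth` path vectors (one per replicate)
#'   and the `TemplateSet` used.
#' @export
simulate_sample <- function(config, seed) {
  stopifnot(is.list(config), !is.null(config$design), !is.null(config$n_reads))
  pm <- config$pause_model %||% pause_model()
  cl <- config$cleavage %||% cleavage_model()
  reps <- config$replicates %||% 2L
  out_dir <- config$out_dir %||% tempfile("invtoe_sim_")
  name <- config$name %||% "sample"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  lib <- build_template_library(
    design = config$design, n_templates = config$n_reads,
    seed = derive_seed(seed, 0L), wt = config$wt,
    mutation_rate = config$mutation_rate %||% 0.07,
    flank5 = config$flank5 %||% FLANK5_DEFAULT,
    flank3 = config$flank3 %||% FLANK3_DEFAULT)

  fq <- tr <- character(reps)
  for (r in seq_len(reps)) {
    sub <- derive_seed(seed, r)
    ev <- simulate_stalling(lib, pm, reads_per_template = 1L, seed = sub)
    rr <- render_reads(ev, lib, cleavage = cl,
                       substitution_rate = config$substitution_rate %||% 0,
                       quality = config$quality %||% "constant",
                       readthrough_keep_fraction =
                         config$readthrough_keep_fraction %||% 0,
                       seed = sub + 1L,
                       id_prefix = sprintf("%s_rep%d", name, r))
    fq[r] <- file.path(out_dir, sprintf("%s_rep%d.fastq", name, r))
    tr[r] <- file.path(out_dir, sprintf("%s_rep%d_truth.tsv", name, r))
    write_fastq(rr$reads, fq[r])
    write.table(rr$truth, tr[r], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(fastq = fq, truth = tr, templates = lib)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
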