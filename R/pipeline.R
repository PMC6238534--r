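# Pipeline orchestration: simulate -> process -> offset -> motifs ->
# compare, with deterministic seeding and a machine-readable summary.

PIPELINE_SCHEMA_VERSION <- "1.0"

#' Default analysis thresholds
#'
#' The standard parameter set: 2 flank mismatches, minimum Q30 inside the
#' quality window, poly-A filter of 18 'A's within 22 nt, 3'-end window
#' 24-47 nt, cleavage offset +17 nt, well-measured threshold of 150
#' combined reads, pause-strength cutoff 0.25, pause-strength ratio 1.5,
#' log2 fold-change cutoff 0.5 and variant enrichment cutoff 2.0.
#'
#' @return Named list of defaults, suitable for editing and passing to
#'   [run_pipeline()].
#' @export
default_thresholds <- function() {
  list(max_mismatch = 2L, min_q = 30L, polya_count = 18L, polya_window = 22L,
       quality_roi = c(24L, 47L), end_window = c(24L, 47L), offset = 17L,
       min_counts = 150L, ps_min = 0.25, ps_ratio = 1.5, log2fc_min = 0.5,
       fc_min = 2.0)
}

# Coerce a plain list (e.g. from YAML) into the model objects.
.as_pause_model <- function(x) {
  if (inherits(x, "PauseModel")) return(x)
  if (is.null(x)) return(pause_model())
  pause_model(motif_pause = unlist(x$motif_pause %||% list()),
              default_pause = x$default_pause %||% 0,
              stop_pause = x$stop_pause %||% 0,
              initiation_fraction = x$initiation_fraction %||% 0)
}

.as_cleavage_model <- function(x) {
  if (inherits(x, "CleavageModel")) return(x)
  if (is.null(x)) return(cleavage_model())
  cleavage_model(offset = x$offset %||% 17L,
                 jitter_probs = unlist(x$jitter_probs %||%
                                         c(0.70, 0.20, 0.10)))
}

#' Combine replicate motif tables
#'
#' Sums stall and bypass counts (and read totals) across replicates of
#' one condition, e.g. for pooled pause-strength estimates.
#'
#' @param tabs List of `MotifTable`s of the same kind.
#' @return A pooled `MotifTable`.
#' @export
combine_motif_tables <- function(tabs) {
  stopifnot(length(tabs) >= 1L)
  kinds <- vapply(tabs, attr, character(1L), "kind")
  if (length(unique(kinds)) != 1L) stop("tables must share one motif kind")
  dt <- rbindlist(lapply(tabs, function(t) {
    as.data.table(t[, c("motif", "nP", "nB")])
  }))
  agg <- dt[, list(nP = sum(nP), nB = sum(nB)), by = "motif"]
  .motif_table(agg[, c("motif", "nP")], agg[, c("motif", "nB")], kinds[1L],
               sum(vapply(tabs, attr, numeric(1L), "n_total")))
}

#' Run the inverse-toeprinting analysis pipeline
#'
#' Executes, in order: simulation (for samples configured with a
#' `simulate` block), read processing, offset estimation (fixed or
#' automatic from UAG-stalled reads), per-replicate motif counting and,
#' when a comparison is configured, fold changes, pause strengths and
#' motif classification.  All tables are written as TSV and a versioned
#' JSON summary records the configuration hash, per-stage read counts
#' and thresholds; identical configuration and seed give identical
#' outputs.
#'
#' @param config A list, or path to a YAML/JSON file.  Recognised keys:
#'   `samples` (named list; each entry has either `fastq`, a vector of
#'   per-replicate FASTQ paths, or `simulate`, a [simulate_sample()]
#'   config), `offset` (`"auto"` or an integer), `compare` (list with
#'   `fg` and `bg` sample names), `kind` (`"aa3"`/`"codon3"`), and any
#'   element of [default_thresholds()].
#' @param seed Master seed for all randomness (default 1).
#' @param out_dir Output directory (default `config$out_dir` or a
#'   tempdir).
#' @return list with `summary` (also written as `summary.json`), paths of
#'   written tables, and the in-memory result objects.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  thr <- utils::modifyList(default_thresholds(),
                           config[intersect(names(config),
                                            names(default_thresholds()))])
  out_dir <- out_dir %||% config$out_dir %||% tempfile("invtoe_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  kind <- config$kind %||% "aa3"
  if (is.null(config$samples) || is.null(names(config$samples))) {
    stop("config$samples must be a named list")
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(.serialisable(config), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))

  # stage 1: obtain reads per sample/replicate
  fastqs <- list()
  for (s in names(config$samples)) {
    sc <- config$samples[[s]]
    if (!is.null(sc$fastq)) {
      fastqs[[s]] <- sc$fastq
    } else if (!is.null(sc$simulate)) {
      sim <- sc$simulate
      sim$name <- s
      sim$out_dir <- sim$out_dir %||% file.path(out_dir, "sim")
      sim$pause_model <- .as_pause_model(sim$pause_model)
      sim$cleavage <- .as_cleavage_model(sim$cleavage)
      res <- simulate_sample(sim, seed = derive_seed(seed, match(s, names(config$samples))))
      fastqs[[s]] <- res$fastq
    } else {
      stop("sample '", s, "': provide either fastq paths or a simulate block")
    }
  }

  # stage 2: process
  processed <- list(); reports <- list()
  for (s in names(fastqs)) {
    processed[[s]] <- lapply(fastqs[[s]], function(fq) {
      pr <- process_reads(read_fastq(fq),
                          flank5 = config$flank5 %||% FLANK5_DEFAULT,
                          flank3 = config$flank3 %||% FLANK3_DEFAULT,
                          max_mismatch = thr$max_mismatch,
                          quality_roi = thr$quality_roi, min_q = thr$min_q,
                          polya_count = thr$polya_count,
                          polya_window = thr$polya_window,
                          end_window = thr$end_window)
      pr
    })
    reports[[s]] <- lapply(processed[[s]], `[[`, "report")
  }

  # stage 3: offset
  offset_mode <- config$offset %||% "auto"
  if (identical(offset_mode, "auto")) {
    pooled <- do.call(rbind, unlist(lapply(processed, function(rs) {
      lapply(rs, `[[`, "reads")
    }), recursive = FALSE))
    off_est <- estimate_offset(pooled)
    offset <- off_est$offset
  } else {
    offset <- as.integer(offset_mode)
    off_est <- NULL
  }

  # stage 4: motif tables per replicate
  tables <- list()
  for (s in names(processed)) {
    tables[[s]] <- lapply(processed[[s]], function(x) {
      count_motifs(translate_protected(x$reads, offset), kind = kind)
    })
    for (r in seq_along(tables[[s]])) {
      f <- file.path(out_dir, sprintf("motifs_%s_rep%d.tsv", s, r))
      tab <- pause_strength(tables[[s]][[r]])
      write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # stage 5: comparison
  comparison <- NULL
  if (!is.null(config$compare)) {
    fg <- config$compare$fg; bg <- config$compare$bg
    if (is.null(tables[[fg]]) || is.null(tables[[bg]])) {
      stop("compare stage failed: unknown sample in compare block")
    }
    enr <- fold_change(tables[[fg]], tables[[bg]],
                       min_counts = thr$min_counts)
    ps_fg <- pause_strength(combine_motif_tables(tables[[fg]]))
    ps_bg <- pause_strength(combine_motif_tables(tables[[bg]]))
    cls <- classify_motifs(ps_fg, ps_bg, enr, ps_min = thr$ps_min,
                           ps_ratio = thr$ps_ratio,
                           log2fc_min = thr$log2fc_min)
    comparison <- merge(enr, cls[, c("motif", "class")], by = "motif",
                        all.x = TRUE)
    comparison <- comparison[order(comparison$motif), ]
    write.table(comparison, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  counts_summary <- lapply(reports, function(rs) {
    lapply(rs, function(rep) setNames(as.list(rep$n), rep$reason))
  })
  summary <- list(schema_version = PIPELINE_SCHEMA_VERSION,
                  package_version = as.character(utils::packageVersion("invtoe")),
                  seed = seed, config_md5 = cfg_hash,
                  thresholds = thr, offset = offset,
                  offset_mode = offset_mode,
                  read_counts = counts_summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(summary = summary, out_dir = out_dir, offset_estimate = off_est,
       tables = tables, comparison = comparison, reports = reports)
}

# Strip function/closure-bearing objects so the config can be hashed.
.serialisable <- function(x) {
  if (inherits(x, "PauseModel")) {
    y <- unclass(x)
    y$motif_pause <- as.list(y$motif_pause)  # keep names through YAML
    return(y)
  }
  if (inherits(x, "CleavageModel")) return(unclass(x))
  if (is.list(x)) return(lapply(x, .serialisable))
  x
}
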