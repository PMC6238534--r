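# Synthetic template libraries.
#
# A template is the mRNA region starting at the first nucleotide of the
# start codon: ATG, a variable coding region, a fixed four-codon spacer,
# two in-frame TGA stop codons and a downstream pad standing in for the
# restriction site / linker region that RNase R removes on non-stalled
# messages.  The pad gives the exonuclease room to cleave a fixed distance
# downstream of late P-site positions.

SPACER_NT <- "GGTTCTGGCAGC"           # Gly-Ser-Gly-Ser, no in-frame TAG
STOPS_NT  <- "TGATGA"                 # terminal stops (RF-2 absent)
PAD_NT    <- "GATATCCTGCAGGTCGACCATTCG"  # EcoRV-site-containing pad

#' Build a synthetic template library
#'
#' Three designs are supported.  `"nns15"` draws 15 degenerate NNS codons
#' (positions 1-2 uniform over A/C/G/T, position 3 uniform over G/C), the
#' degeneracy used for fully random arrest-peptide selections: it encodes
#' all 20 amino acids but, by construction, admits no in-frame UGA or UAA
#' stop in the variable region (UAG is possible and is handled by release
#' factor 1 / stop pausing downstream).  `"mutant_library"` mutates every
#' nucleotide of a supplied wild-type coding sequence (downstream of the
#' fixed ATG) independently at `mutation_rate` to a uniformly chosen
#' different base, emulating doped-oligonucleotide mutagenesis of a known
#' arrest peptide.  `"fixed"` replicates the wild-type sequence unchanged.
#'
#' Each template is `ATG + variable region + spacer + TGATGA + pad`, with
#' coordinates 1-based from the A of the ATG.
#'
#' @param design One of `"nns15"`, `"mutant_library"`, `"fixed"`.
#' @param n_templates Number of templates to draw (>= 1).
#' @param seed Integer seed; the library is deterministic given the seed.
#' @param wt Wild-type coding sequence starting with ATG (required for
#'   `mutant_library` and `fixed`); the spacer/stop/pad tail is appended.
#' @param mutation_rate Per-nucleotide substitution probability for
#'   `mutant_library` (default 0.07).
#' @param n_codons Number of variable NNS codons (default 15).
#' @param flank5,flank3 Flanking sequences recorded with the library and
#'   used when rendering reads.
#' @return An object of class `TemplateSet`: a list with elements
#'   `templates` (data.frame `id`, `nt_sequence`), `flank5`, `flank3`,
#'   `start_offset` (always 1: sequences begin at the ATG) and `design`.
#' @export
build_template_library <- function(design = c("nns15", "mutant_library", "fixed"),
                                   n_templates, seed = NULL,
                                   wt = NULL, mutation_rate = 0.07,
                                   n_codons = 15L,
                                   flank5 = FLANK5_DEFAULT,
                                   flank3 = FLANK3_DEFAULT) {
  design <- match.arg(design)
  if (n_templates < 1L) stop("n_templates must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  if (design == "nns15") {
    n_var <- n_templates * n_codons
    b12 <- sample(c("A", "C", "G", "T"), 2L * n_var, replace = TRUE)
    b3 <- sample(c("G", "C"), n_var, replace = TRUE)
    cod <- paste0(b12[seq(1L, 2L * n_var, by = 2L)],
                  b12[seq(2L, 2L * n_var, by = 2L)], b3)
    var_region <- do.call(paste0,
      as.data.frame(matrix(cod, nrow = n_templates, byrow = TRUE),
                    stringsAsFactors = FALSE))
    seqs <- paste0("ATG", var_region, SPACER_NT, STOPS_NT, PAD_NT)
  } else {
    if (is.null(wt) || !nzchar(wt)) {
      stop("design '", design, "' requires a non-empty wild-type sequence")
    }
    wt <- toupper(wt)
    if (substr(wt, 1, 3) != "ATG") stop("wild type must start with ATG")
    if (design == "mutant_library" &&
        (mutation_rate < 0 || mutation_rate > 1)) {
      stop("mutation_rate must lie in [0, 1]")
    }
    body <- substr(wt, 4L, nchar(wt))   # ATG is primer-fixed, not mutated
    L <- nchar(body)
    bases <- matrix(strsplit(body, "")[[1]], nrow = n_templates, ncol = L,
                    byrow = TRUE)
    if (design == "mutant_library" && mutation_rate > 0 && L > 0) {
      hit <- matrix(runif(n_templates * L) < mutation_rate, n_templates, L)
      idx <- which(hit)
      if (length(idx)) {
        # uniform over the three non-identical bases
        alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))
        orig <- bases[idx]
        pick <- sample.int(3L, length(idx), replace = TRUE)
        bases[idx] <- mapply(function(b, k) alt[[b]][k], orig, pick,
                             USE.NAMES = FALSE)
      }
    }
    body_seqs <- do.call(paste0, as.data.frame(bases, stringsAsFactors = FALSE))
    seqs <- paste0("ATG", body_seqs, SPACER_NT, STOPS_NT, PAD_NT)
  }

  structure(list(
    templates = data.frame(id = sprintf("tmpl_%06d", seq_len(n_templates)),
                           nt_sequence = seqs, stringsAsFactors = FALSE),
    flank5 = flank5, flank3 = flank3,
    start_offset = 1L, design = design
  ), class = "TemplateSet")
}

#' @export
print.TemplateSet <- function(x, ...) {
  cat("TemplateSet:", nrow(x$templates), "templates, design =", x$design, "\n")
  cat("  flank5:", x$flank5, "\n  flank3:", x$flank3, "\n")
  invisible(x)
}
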