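---
title: "Inverse toeprinting: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse toeprinting: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invtoe)
```

## The experiment this package models

In an inverse-toeprinting experiment, an mRNA library is translated in
vitro, translation is halted, and RNase R — a highly processive 3'→5'
exoribonuclease — degrades each message until it runs into the leading
ribosome. The surviving fragment therefore ends a fixed distance
downstream of the ribosomal P-site, while the *entire upstream coding
region* is preserved. After ligation of a 3' linker, reverse
transcription and a restriction digest that removes molecules on which
the ribosome reached the stop codon, the fragments are sequenced. Each
merged read is then a direct record of one stalled ribosome: where it
stopped (the 3' end) and everything it had translated up to that point
(the insert).

Two library designs are analysed. A degenerate NNS~15~ library (15
codons with any base at positions 1–2 and G or C at position 3) samples
all 20 amino acids while excluding in-frame UGA and UAA stops, and is
used to survey the tripeptide pausing landscape. A focused library, in
which every nucleotide of a known arrest-peptide ORF is mutated at a
fixed per-base rate (7% by default), is used to map which residues of a
specific arrest peptide matter.

## The core statistics

**P-site assignment.** Ribosomes pausing with a UAG codon in the A-site
provide an internal calibration: for a read with an in-frame UAG at
codon *q*, the candidate offset is `end_pos − 3(q − 1)`, the distance
from the last nucleotide of the putative P-site codon to the protected
3' end. The modal candidate over all UAG-bearing reads estimates the
cleavage offset (+17 nt under the package's anchor convention). Each
read's P-site codon is then `p = ceiling((end_pos − offset) / 3)`.

**Pause strength.** For a tripeptide motif X1X2(X3) — X2 in the P-site,
X3 in the A-site — the pause strength is

$$\mathrm{PS} = \frac{n_P}{n_P + n_B}$$

where \(n_P\) counts reads whose ribosome stalled *on* the motif
(terminal motif) and \(n_B\) counts reads whose ribosome translated
through it (the motif occurs at an interior position). PS = 1 means
ribosomes never bypass the motif; PS = 0.2 means 80% of encounters end
in bypass. Motif frequencies are \(F = n_P / n_\mathrm{total}\) with
\(n_\mathrm{total}\) the total processed reads, including reads that
contribute no terminal motif.

**Fold change and error propagation.** With two replicates per
condition, \(F = (F_1 + F_2)/2\) and \(\Delta F = |F_1 − F_2|\); the
fold change between a foreground and a background condition is
\(FC = F_\mathrm{fg}/F_\mathrm{bg}\) with propagated error

$$\Delta FC = \sqrt{\left(\frac{\Delta F_\mathrm{bg}}{F_\mathrm{bg}}\right)^2 +
\left(\frac{\Delta F_\mathrm{fg}}{F_\mathrm{fg}}\right)^2}\; FC.$$

**Counting-noise threshold.** If replicate-to-replicate scatter is pure
counting noise, a motif's reads split between two equal replicates like
a Binomial(total, ½) draw, so the SD of the replicate-1 fraction is
\(0.5/\sqrt{\mathrm{total}}\) — below 0.05 once the combined total
passes ≈150 reads. `partition_error_model()` compares this prediction
with the observed scatter; "well-measured" motifs (strictly more than
150 combined reads, counted over the stall counts of all compared
replicate tables) are the ones whose frequencies are trusted in
downstream classification.

**Motif classes.** A well-measured motif is *intrinsic* if its
background (no-drug) pause strength is ≥0.25; *drug-dependent* if its
foreground pause strength is ≥0.25, at least 1.5× the background value,
and its frequency log2 fold change is ≥0.5.

## What the simulator emulates

`build_template_library()`, `simulate_stalling()` and `render_reads()`
generate data with known ground truth:

* **Sequential stalling.** Each simulated ribosome walks its template
  codon by codon; at each step the stall probability is looked up from
  the current E/P/A-site tripeptide (`pause_model()`), with a separate
  probability for a UAG A-site (stop pausing is partial because release
  factor 1 is present) and a configurable fraction of ribosomes that
  never leave the start codon (initiation complexes). Ribosomes
  reaching a stop without stalling are "readthrough" and dropped,
  mirroring the restriction digest; a contamination fraction can retain
  them.
* **Cleavage geometry.** The protected 3' end lies `offset` nucleotides
  (default 17) downstream of the last nucleotide of the P-site codon,
  with jitter weights (0.70, 0.20, 0.10) over `offset`, `offset − 1`,
  `offset − 2`. The offset anchor (last nucleotide of the P-site codon,
  inclusive distance) is a package convention used consistently by the
  simulator and the analysis; the experimental anchor is not stated
  more precisely, so an absolute disagreement by a constant cannot be
  excluded, but all within-package round trips are exact. The jitter
  weights are plausible placeholders reproducing a dominant phase with
  minor shoulders — the true shoulder weights are not published.
* **Libraries.** NNS codons are drawn uniformly (N over A/C/G/T, S over
  G/C); mutant libraries substitute every base downstream of the
  primer-fixed ATG independently at the given rate, uniformly over the
  three other bases. Templates carry a fixed Gly-Ser-Gly-Ser spacer,
  two TGA stops and a downstream pad (containing an EcoRV site) that
  gives the exonuclease room to cleave beyond late P-sites; the spacer
  was chosen free of in-frame UAG so it cannot contaminate offset
  estimation.
* **Reads.** Each retained event becomes one pre-merged read:
  5' flank + template through the cleavage position + 3' linker flank,
  with constant Q37 qualities by default (a position-decaying model is
  available) and optional uniform substitution errors.
* **Replicates.** A sample's library is built once; each replicate is
  an independent translation of that pool. Sub-seeds derive from the
  master seed as `(seed × 48271 + r × 1009) mod (2^31 − 1)`, so runs
  are exactly reproducible and replicates are independent.

The simulator does *not* model tRNA-level kinetics, drug binding
thermodynamics, ligation or PCR bias, indels, or RNase R processivity
failures. Passing tests on simulated data therefore establish that the
analysis recovers the parameters of this generative model — offsets,
stall probabilities, planted drug-conditional motifs — not that every
bias of real sequencing data is handled.

## Numerical and design choices

* **Coordinates** are 1-based and inclusive, with nucleotide 1 the A of
  the start codon; region-of-interest windows constrain the fragment 3'
  end (`end_pos`), and the default 24–47 window corresponds to
  ribosomes that translated roughly 2–10 codons.
* **Flank matching** is substitution-only (Hamming) and anchored at the
  read ends, because the flanks are fixed-length primer-derived
  sequences; up to 2 mismatches per flank are tolerated.
* **Filter order** is fixed (poly-A, then start codon, then quality,
  then size window) and every read is attributed to its first failing
  filter, so rejection reports are deterministic; permuting the order
  changes attribution but never the pass set.
* **The ceiling rule** for P-site assignment absorbs the −1/−2 cleavage
  jitter, mapping all three jittered ends of one stall event to the
  same codon. Offset-estimation ties break towards the larger offset
  because jitter only shortens fragments. Offset candidates use codons
  q ≥ 3 so the upstream motif residue exists.
* **Bypass counting** is read-level by default (a read increments a
  motif's \(n_B\) at most once), following the definition of \(n_B\) as
  the *number of reads* that translated through the motif; an
  occurrence-level mode is available for sensitivity analysis.
* **Stop-terminal motifs** (UAG in the A-site, rendered '*') are
  tallied but flagged out of the 8000-member sense motif space: stop
  pausing is a calibration signal, not a peptide motif.
* **Fold changes for motifs absent from the background** are reported
  as undefined rather than pseudo-counted; an optional pseudo-count is
  off by default.
* **Variant windows containing a stop codon** are excluded as nonsense:
  they do not encode a full-length peptide variant of the wild type.
* **Position enrichment** (the in-package replacement for logo-server
  statistics) reports a log2 frequency ratio smoothed with
  ε = 1/(n_bg + 20) as the effect size, and a two-sided binomial
  p-value against a smoothed background frequency
  (count_bg + 0.5)/(n_bg + 1) as the evidence. Cells are canonically
  ranked by evidence (`top_enriched_cells()`): with tens of thousands
  of reads, a raw-ratio ranking is dominated by cells observed a
  handful of times in the foreground and never in the background,
  which are sampling artifacts rather than signal. The p-values are
  descriptive and uncorrected.
* **"Discriminating" variants** must be enriched at least `fc_min`-fold
  over the input library in exactly one condition (exclusive or) and
  carry at least 150 reads combined across the two selected samples;
  "not enriched in the other condition" is operationalised as falling
  below the same cutoff.

## Problem sizes used by the test-suite

The package's properties are verified at sizes chosen to keep sampling
error well below the tested effects while remaining quick to run:
offset recovery uses 10^4 reads per offset; pause-strength recovery
2 × 10^4 ribosome walks per stall probability; the pause-strength /
enrichment correlation 10^6 walks of an NNS~15~ library with 150
planted motifs; the end-to-end variant recovery 6 × 10^4 walks per
sample of a 7%-mutagenised 12-codon library; and the partition error
model 10^4 simulated motifs per bin.

## Known limitations

* The +17 nt offset convention may differ from other analyses by a
  constant, depending on which nucleotide of the P-site codon is taken
  as the anchor.
* Pause strengths are conditional on a read being captured: sequences
  that never stall leave no trace, so PS is undefined (not zero) for
  motifs without encounters. More subtly, a bypass event is only
  *observed* when the ribosome stalls again downstream inside the size
  window, so when overall stalling is sparse, \(n_B\) is undercounted
  and pause strengths are inflated relative to the per-encounter stall
  probability. Simulation-based calibration (a guaranteed downstream
  staller, as in the test-suite) removes this bias; real libraries rely
  on the pausing landscape being dense enough that bypassing ribosomes
  are usually recaptured.
* Fragments are modelled as cleanly cleaved; heterogeneous offsets
  (e.g. drug-dependent protection changes) are not modelled.
* The enrichment analysis uses fixed thresholds, not per-motif
  significance tests; the error model quantifies counting noise only.
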