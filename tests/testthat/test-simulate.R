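fixed_lib <- function(pep, n = 1) {
  wt <- nt_for_peptide(pep)
  build_template_library("fixed", n, wt = wt)
}

test_that("a certain-stall motif always stalls the ribosome at its P-site", {
  lib <- fixed_lib("MPPD")
  pm <- pause_model(motif_pause = c(PPD = 1.0))
  ev <- simulate_stalling(lib, pm, reads_per_template = 200, seed = 1)
  expect_true(all(ev$cause == "motif"))
  expect_true(all(ev$p_site_codon == 3))
})

test_that("with all pause probabilities zero every ribosome reads through", {
  lib <- fixed_lib("MAPKW")
  pm <- pause_model()
  ev <- simulate_stalling(lib, pm, reads_per_template = 100, seed = 2)
  expect_true(all(ev$cause == "readthrough"))
})

test_that("stall fraction at a single motif matches its Bernoulli probability", {
  # guaranteed downstream staller so every ribosome stalls somewhere
  lib <- fixed_lib("MTCDETTWWWTT")
  pm <- pause_model(motif_pause = c(CDE = 0.3, WWW = 1.0))
  n <- 20000
  ev <- simulate_stalling(lib, pm, reads_per_template = n, seed = 3)
  expect_true(all(ev$cause == "motif"))
  frac <- mean(ev$p_site_codon == 4)  # P-site on D of C-D-E
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("cleavage geometry places the 3' end offset nt past the P-site codon", {
  lib <- fixed_lib("MAAAAAAAADKAAAAA")  # stall with P-site codon 10 (D)
  pm <- pause_model(motif_pause = c(ADK = 1.0))
  ev <- simulate_stalling(lib, pm, reads_per_template = 5, seed = 4)
  expect_true(all(ev$p_site_codon == 10))
  rr <- render_reads(ev, lib, cleavage_model(17, c(1, 0, 0)), seed = 5)
  expect_true(all(rr$truth$cleavage_pos == 3 * 10 + 17))
})

test_that("without sequencing errors reads are exact flank/template sandwiches", {
  lib <- build_template_library("nns15", 20, seed = 6)
  pm <- pause_model(default_pause = 0.2, stop_pause = 1)
  ev <- simulate_stalling(lib, pm, seed = 7)
  rr <- render_reads(ev, lib, substitution_rate = 0, seed = 8)
  tmap <- setNames(lib$templates$nt_sequence, lib$templates$id)
  expected <- paste0(lib$flank5,
                     substr(tmap[rr$truth$template_id], 1,
                            rr$truth$cleavage_pos),
                     lib$flank3)
  expect_identical(rr$reads$seq, unname(expected))
})

test_that("single-phase cleavage keeps all 3' ends in one frame", {
  lib <- build_template_library("nns15", 300, seed = 9)
  pm <- pause_model(default_pause = 0.15, stop_pause = 1)
  ev <- simulate_stalling(lib, pm, seed = 10)
  rr <- render_reads(ev, lib, cleavage_model(17, c(1, 0, 0)), seed = 11)
  expect_length(unique(rr$truth$cleavage_pos %% 3), 1)
})

test_that("simulated samples are byte-identical for a repeated seed", {
  cfg <- list(design = "nns15", n_reads = 200, replicates = 2,
              pause_model = pause_model(default_pause = 0.1, stop_pause = 0.8),
              out_dir = tempfile("sim_a_"))
  a <- simulate_sample(cfg, seed = 99)
  cfg$out_dir <- tempfile("sim_b_")
  b <- simulate_sample(cfg, seed = 99)
  for (r in 1:2) {
    expect_identical(readLines(a$fastq[r]), readLines(b$fastq[r]))
    expect_identical(readLines(a$truth[r]), readLines(b$truth[r]))
  }
  # replicates of one sample differ (independent sub-seeds)
  expect_false(identical(readLines(a$fastq[1]), readLines(a$fastq[2])))
})

test_that("the initiation fraction controls initiation-complex contamination", {
  lib <- build_template_library("nns15", 4000, seed = 12)
  pm <- pause_model(default_pause = 0.1, stop_pause = 1,
                    initiation_fraction = 0.5)
  ev <- simulate_stalling(lib, pm, seed = 13)
  frac <- mean(ev$cause == "initiation")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("readthrough events are dropped unless contamination is configured", {
  lib <- fixed_lib("MAPKW", n = 50)
  ev <- simulate_stalling(lib, pause_model(), reads_per_template = 1, seed = 14)
  rr <- render_reads(ev, lib, seed = 15)
  expect_identical(nrow(rr$reads), 0L)
  rr2 <- render_reads(ev, lib, readthrough_keep_fraction = 1, seed = 16)
  expect_identical(nrow(rr2$reads), 50L)
  expect_true(all(rr2$truth$cause == "readthrough"))
})
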