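# A ProcessedRead whose protected region encodes `pep` with P-site on its
# last residue: end_pos = 3 * p + 17 exactly (no jitter).
read_for_peptide <- function(pep_with_asite) {
  p <- nchar(pep_with_asite) - 1L
  nt <- nt_for_peptide(pep_with_asite)
  pad <- strrep("G", 3L * p + 17L - nchar(nt))
  processed_df(paste0(nt, pad))
}

test_that("terminal and bypassed motifs are counted per the definition", {
  # peptide M-A-P with A-site P, P-site codon 3:
  # nP gains AP(P), nB gains MA(P)
  tp <- translate_protected(read_for_peptide("MAPP"))
  expect_identical(tp$p_site, 3L)
  expect_identical(tp$peptide, "MAPP")
  mt <- count_motifs(tp)
  expect_identical(mt$nP[mt$motif == "APP"], 1L)
  expect_identical(mt$nB[mt$motif == "MAP"], 1L)
  expect_identical(sum(mt$nP), 1L)
  expect_identical(sum(mt$nB), 1L)
})

test_that("read-level bypass counts each motif at most once per read", {
  # M-P-P-G-P-P with A-site D, p = 6: interior positions 2..5 give
  # bypass motifs MP(P), PP(G), PG(P), GP(P); terminal is PP(D)
  tp <- translate_protected(read_for_peptide("MPPGPPD"))
  mt <- count_motifs(tp)
  expect_identical(mt$nP[mt$motif == "PPD"], 1L)
  for (m in c("MPP", "PPG", "PGP", "GPP")) {
    expect_identical(mt$nB[mt$motif == m], 1L)
  }
  # occurrence mode counts repeats; with distinct interiors it agrees
  mt2 <- count_motifs(tp, bypass = "occurrence")
  expect_identical(sum(mt2$nB), 4L)
})

test_that("motif counting matches a brute-force enumeration oracle", {
  set.seed(51)
  aas <- setdiff(AA_ALPHABET, character(0))
  for (rep in 1:20) {
    p <- sample(3:9, 1)
    pep <- paste(sample(aas, p + 1, replace = TRUE), collapse = "")
    tp <- translate_protected(read_for_peptide(pep))
    mt <- count_motifs(tp)

    # oracle: direct string enumeration
    term <- substr(pep, p - 1, p + 1)
    byp <- unique(vapply(2:(p - 1), function(i) substr(pep, i - 1, i + 1),
                         character(1)))
    expect_identical(mt$nP[mt$motif == term], 1L)
    expect_identical(sort(mt$motif[mt$nB > 0]), sort(byp))
  }
})

test_that("frequency conservation holds on simulated data", {
  lib <- build_template_library("nns15", 2000, seed = 52)
  pm <- pause_model(default_pause = 0.1, stop_pause = 0.6)
  ev <- simulate_stalling(lib, pm, seed = 53)
  rr <- render_reads(ev, lib, seed = 54)
  pr <- process_reads(rr$reads)
  tp <- translate_protected(pr$reads)
  mt <- count_motifs(tp)
  countable <- sum(!tp$excluded & tp$p_site >= 2)
  expect_identical(sum(mt$nP), countable)
  expect_equal(sum(mt$F), countable / nrow(pr$reads))
  # stop-A-site motifs are flagged out of the sense space
  expect_identical(sum(mt$sense), nrow(mt) - sum(grepl("[*]", mt$motif)))
})

test_that("tricodon motif counting uses codon identities", {
  tp <- translate_protected(read_for_peptide("MAPP"))
  mt <- count_motifs(tp, kind = "codon3")
  # peptide MAPP encoded with first-listed codons: GCT CCT CCT after ATG
  expect_identical(mt$nP[mt$motif == "GCT.CCT.CCT"], 1L)
  expect_identical(mt$nB[mt$motif == "ATG.GCT.CCT"], 1L)
})

test_that("pause strength is the stall fraction among encounters", {
  mt <- data.frame(motif = c("AAA", "CCC", "DDD"),
                   nP = c(20L, 5L, 0L), nB = c(80L, 0L, 0L))
  ps <- pause_strength(mt)
  expect_equal(ps$PS, c(0.2, 1.0, NA_real_))
})

test_that("the partition error model matches the closed-form binomial SD", {
  set.seed(55)
  sdhat <- predicted_partition_sd(150, n_motifs = 20000, prob = 0.5)
  expect_lt(abs(sdhat - 0.5 / sqrt(150)), 0.002)

  # predicted SD decreases with bin total
  sds <- vapply(c(10, 50, 150, 500), predicted_partition_sd,
                numeric(1), n_motifs = 5000)
  expect_true(all(diff(sds) < 0))
})

test_that("identical-model replicates match the binomial partition prediction", {
  lib <- build_template_library("nns15", 20000, seed = 56)
  pm <- pause_model(default_pause = 0.1, stop_pause = 0.8)
  mk <- function(seed) {
    ev <- simulate_stalling(lib, pm, seed = seed)
    rr <- render_reads(ev, lib, seed = seed + 1)
    pr <- process_reads(rr$reads)
    count_motifs(translate_protected(pr$reads))
  }
  a <- mk(57); b <- mk(59)

  # conditional on a motif's combined total t, the replicate-1 count is
  # binomial(t, 1/2); compare observed and predicted SDs at exact totals
  m <- merge(a[, c("motif", "nP")], b[, c("motif", "nP")], by = "motif")
  tot <- m$nP.x + m$nP.y
  set.seed(60)
  for (t in 3:6) {
    sel <- tot == t
    expect_gt(sum(sel), 100)
    obs <- sd(m$nP.x[sel] / t)
    pred <- predicted_partition_sd(t, n_motifs = 50000, prob = 0.5)
    expect_lt(abs(obs - pred) / pred, 0.15)
  }

  # the binned curve decreases and is reported with its threshold
  pem <- partition_error_model(a, b, n_sim = 2000, seed = 61)
  expect_true(all(diff(pem$bins$sd_predicted) < 0))
})

test_that("the read-count threshold sits where predicted SD crosses 0.05", {
  set.seed(62)
  mk_tab <- function(nP) {
    tab <- data.frame(motif = sprintf("m%04d", seq_along(nP)), nP = nP,
                      nB = 0L, F = nP / 1e6, sense = TRUE)
    attr(tab, "kind") <- "aa3"; attr(tab, "n_total") <- 1e6
    class(tab) <- c("MotifTable", "data.frame")
    tab
  }
  totals <- rep(c(20, 60, 120, 180, 400, 800), each = 300)
  nA <- rbinom(length(totals), totals, 0.5)
  pem <- partition_error_model(mk_tab(nA), mk_tab(totals - nA),
                               n_sim = 5000, seed = 63)
  # 0.5/sqrt(t) < 0.05 first holds between t = 100 and t = 180
  expect_true(is.finite(pem$threshold))
  expect_gte(pem$threshold, 100)
  expect_lte(pem$threshold, 250)
})

test_that("fold changes and propagated errors follow the printed formula", {
  mk_tab <- function(nP, n_total) {
    tab <- data.frame(motif = c("AAA", "CCC"), nP = nP, nB = 0L,
                      F = nP / n_total, sense = TRUE)
    attr(tab, "kind") <- "aa3"; attr(tab, "n_total") <- n_total
    class(tab) <- c("MotifTable", "data.frame")
    tab
  }
  # equal replicates: FC exact, dFC zero
  fg <- list(mk_tab(c(20L, 10L), 1e5), mk_tab(c(20L, 10L), 1e5))
  bg <- list(mk_tab(c(10L, 10L), 1e5), mk_tab(c(10L, 10L), 1e5))
  fc <- fold_change(fg, bg, min_counts = 10)
  expect_equal(fc$FC[fc$motif == "AAA"], 2)
  expect_equal(fc$dFC[fc$motif == "AAA"], 0)
  expect_equal(fc$log2FC[fc$motif == "CCC"], 0)

  # background difference zero: dFC = (dF_fg / F_fg) * FC
  fg2 <- list(mk_tab(c(30L, 10L), 1e5), mk_tab(c(10L, 10L), 1e5))
  fc2 <- fold_change(fg2, bg, min_counts = 10)
  i <- fc2$motif == "AAA"
  expect_equal(fc2$dFC[i],
               (fc2$dF_fg[i] / fc2$F_fg[i]) * fc2$FC[i])

  # fg = bg gives FC = 1 everywhere
  fc3 <- fold_change(bg, bg, min_counts = 0)
  expect_true(all(fc3$FC == 1))
})

test_that("well-measured status uses strict combined stall counts", {
  mk_tab <- function(nP) {
    tab <- data.frame(motif = "AAA", nP = nP, nB = 0L, F = nP / 1e4,
                      sense = TRUE)
    attr(tab, "kind") <- "aa3"; attr(tab, "n_total") <- 1e4
    class(tab) <- c("MotifTable", "data.frame")
    tab
  }
  fc150 <- fold_change(list(mk_tab(40L), mk_tab(40L)),
                       list(mk_tab(40L), mk_tab(30L)))
  expect_false(fc150$well_measured)  # exactly 150 is not enough
  fc151 <- fold_change(list(mk_tab(40L), mk_tab(40L)),
                       list(mk_tab(40L), mk_tab(31L)))
  expect_true(fc151$well_measured)
})

test_that("motif classes follow the pause-strength and enrichment cutoffs", {
  mk_ps <- function(ps) data.frame(motif = "AAA", PS = ps)
  mk_en <- function(l2) {
    data.frame(motif = "AAA", log2FC = l2, well_measured = TRUE)
  }
  cls <- function(ps_fg, ps_bg, l2) {
    classify_motifs(mk_ps(ps_fg), mk_ps(ps_bg), mk_en(l2))$class
  }
  expect_identical(cls(0.30, 0.10, 0.6), "drug_dependent")
  expect_identical(cls(0.24, 0.10, 2.0), "none")
  expect_identical(cls(0.10, 0.40, 0.0), "intrinsic")
  expect_identical(cls(0.30, 0.25, 0.6), "intrinsic")   # bg already pausing
  expect_identical(cls(0.30, 0.25 / 1.5 + 0.06, 0.6), "none")  # ratio fails
})

test_that("usage correlation flags degenerate inputs and finds planted signal", {
  usage <- setNames(rep(1 / 61, 61),
                    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"])
  en <- data.frame(motif = c("ATG.GCT.CCT", "ATG.AAA.CCT", "ATG.TGC.CCT"),
                   log2FC = c(0.1, 0.5, 0.9), well_measured = TRUE)
  # constant usage: zero variance, r undefined
  uc <- usage_correlation(en, usage)
  expect_true(all(uc$zero_variance))
  expect_true(all(is.na(uc$r)))

  # log2FC equal to the usage of the middle codon: perfect correlation
  usage2 <- usage
  usage2[c("GCT", "AAA", "TGC")] <- c(0.1, 0.5, 0.9)
  en2 <- en
  en2$log2FC <- usage2[c("GCT", "AAA", "TGC")]
  uc2 <- usage_correlation(en2, usage2)
  expect_equal(uc2$r[uc2$position == 2], 1)

  expect_error(usage_correlation(en, usage[-1]), "missing")
})
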