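test_that("flank trimming tolerates up to the configured mismatches", {
  reads <- make_reads("ATGAAA")
  tr <- trim_flanks(reads)
  expect_identical(tr$status, "ok")
  expect_identical(tr$seq, "ATGAAA")
  expect_identical(tr$end_pos, 6L)

  # two substitutions in the 5' flank: accepted
  r2 <- reads
  r2$seq <- subst_at(r2$seq, c(2, 5), "CC")
  expect_identical(trim_flanks(r2)$status, "ok")

  # three substitutions: rejected on the 5' side
  r3 <- reads
  r3$seq <- subst_at(r3$seq, c(2, 5, 9), "CCC")
  expect_identical(trim_flanks(r3)$status, "flank5_mismatch")

  # three substitutions in the 3' flank
  r4 <- reads
  n <- nchar(r4$seq)
  r4$seq <- subst_at(r4$seq, c(n - 1, n - 4, n - 7), "AAA")
  expect_identical(trim_flanks(r4)$status, "flank3_mismatch")
})

test_that("quality, poly-A and start-codon filters fire at their thresholds", {
  # 18 'A' within the first 22 nt: rejected; 17: passes
  ins_poly <- paste0("ATG", strrep("A", 17), "GC", random_insert(30))
  ins_poly <- paste0(substr(ins_poly, 1, 22), substr(random_insert(40), 1, 18))
  ins_ok <- paste0("ATGGC", strrep("A", 16), "C", substr(random_insert(40), 1, 18))
  pr <- trim_flanks(make_reads(c(ins_poly, ins_ok)))
  st <- filter_reads(pr)
  expect_identical(st, c("polyA", "pass"))

  # missing start codon
  pr2 <- trim_flanks(make_reads(sub("^ATG", "TTG", ins_ok)))
  expect_identical(filter_reads(pr2), "no_start")

  # one Q29 base inside the quality window (min_q = 30): rejected;
  # Q29 outside the window: ignored
  ins <- random_insert(40)
  q_in <- paste0(strrep(qchar(37), nchar(F5)),
                 subst_at(strrep(qchar(37), 40), 30, qchar(29)),
                 strrep(qchar(37), nchar(F3)))
  q_out <- paste0(strrep(qchar(37), nchar(F5)),
                  subst_at(strrep(qchar(37), 40), 10, qchar(29)),
                  strrep(qchar(37), nchar(F3)))
  pr3 <- trim_flanks(make_reads(c(ins, ins), qual = c(q_in, q_out)))
  expect_identical(filter_reads(pr3), c("low_quality", "pass"))
})

test_that("the 3'-end window is inclusive on both boundaries", {
  expect_identical(select_roi(c(23L, 24L, 47L, 48L)),
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("rejection reasons and passes sum to the number of input reads", {
  set.seed(21)
  lib <- build_template_library("nns15", 500, seed = 22)
  pm <- pause_model(default_pause = 0.08, stop_pause = 0.7,
                    initiation_fraction = 0.2)
  ev <- simulate_stalling(lib, pm, seed = 23)
  rr <- render_reads(ev, lib, substitution_rate = 0.01, seed = 24)
  res <- process_reads(rr$reads)
  expect_identical(sum(res$report$n), nrow(rr$reads))
  expect_identical(res$report$n[res$report$reason == "pass"],
                   nrow(res$reads))
})

test_that("permuting the filter order changes attribution but not the pass set", {
  set.seed(25)
  inserts <- vapply(1:60, function(i) random_insert(sample(20:50, 1)),
                    character(1))
  # salt in failures of each kind
  inserts[1:10] <- paste0("ATG", strrep("A", 19),
                          substr(random_insert(30), 1, 20))
  inserts[11:20] <- sub("^ATG", "CCC", inserts[11:20])
  quals <- strrep(qchar(37), nchar(inserts) + nchar(F5) + nchar(F3))
  quals[seq(5, 60, by = 3)] <- vapply(which(seq_along(inserts) %in%
                                              seq(5, 60, by = 3)), function(i) {
    subst_at(quals[i], nchar(F5) + 25, qchar(20))
  }, character(1))
  pr <- trim_flanks(make_reads(inserts, qual = quals))
  pr <- pr[pr$status == "ok", ]

  st <- filter_reads(pr)
  # independent re-derivation of each predicate
  head22 <- substr(pr$seq, 1, 22)
  fail_poly <- (nchar(head22) -
                  nchar(gsub("A", "", head22, fixed = TRUE))) >= 18
  fail_start <- substr(pr$seq, 1, 3) != "ATG"
  minq <- vapply(seq_len(nrow(pr)), function(i) {
    q <- utf8ToInt(substr(pr$qual[i], 24, min(47, nchar(pr$qual[i])))) - 33
    if (length(q)) min(q) else Inf
  }, numeric(1))
  fail_q <- minq < 30
  expect_identical(st == "pass", !(fail_poly | fail_start | fail_q))
})

test_that("simulator bookkeeping is exact when no filter can fire", {
  lib <- build_template_library("nns15", 300, seed = 26)
  pm <- pause_model(default_pause = 0.1, stop_pause = 0.9,
                    initiation_fraction = 0.1)
  ev <- simulate_stalling(lib, pm, seed = 27)
  rr <- render_reads(ev, lib, substitution_rate = 0, seed = 28)
  res <- process_reads(rr$reads, end_window = NULL)
  # error-free reads with intact flanks: everything emitted passes
  expect_identical(res$report$n[res$report$reason == "pass"], nrow(rr$reads))
})
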