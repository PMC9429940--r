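test_that("frame detection recovers strand and offset on constructed reads", {
  com <- small_community(seed = 60, aa_length = 80)
  panel <- com$gene$protein
  cds <- com$gene$coding_seq
  fr <- detect_frame(cds, panel)
  expect_equal(fr$strand, "+"); expect_equal(fr$offset, 0)
  fr_rev <- detect_frame(revcomp(cds), panel)
  expect_equal(fr_rev$strand, "-"); expect_equal(fr_rev$offset, 0)
  shifted <- paste0("GC", cds)
  fr_sh <- detect_frame(shifted, panel)
  expect_equal(fr_sh$strand, "+"); expect_equal(fr_sh$offset, 2)
  expect_error(detect_frame(cds, character(0)), "panel")
})

test_that("random sequences score far below genuine reads in frame detection", {
  com <- small_community(seed = 61, aa_length = 80)
  panel <- com$gene$protein
  true_score <- detect_frame(com$gene$coding_seq, panel)$score
  set.seed(62)
  null_scores <- vapply(random_dna(100, 240), function(s)
    detect_frame(s, panel)$score, numeric(1))
  expect_true(mean(null_scores < true_score / 2) >= 0.95)
})

test_that("stop partition is exhaustive and unforgiving of terminal stops", {
  prots <- c("MKLL", "MK*L", "MKLL*", "*MKL", "MMMM")
  part <- partition_by_stop(prots)
  expect_equal(part$stop_free, c("MKLL", "MMMM"))
  expect_equal(part$containing_stop, c("MK*L", "MKLL*", "*MKL"))
  expect_equal(length(part$stop_free) + length(part$containing_stop),
               length(prots))
})

test_that("length gate uses an inclusive tolerance", {
  cfg <- qc_config("g", 300, "M", aa_len_tolerance = 0)
  expect_equal(gate_by_length(strrep("A", 100), cfg), "expected")
  expect_equal(gate_by_length(strrep("A", 95), cfg), "anomalous")
  cfg5 <- qc_config("g", 300, "M", aa_len_tolerance = 5)
  expect_equal(gate_by_length(strrep("A", 95), cfg5), "expected")
  expect_equal(gate_by_length(strrep("A", 94), cfg5), "anomalous")
})

test_that("alignment verification accepts fragments and rejects shuffles", {
  com <- small_community(seed = 63, aa_length = 100)
  prot <- com$gene$protein
  cfg <- qc_config(com$gene$name, 300, prot)
  frag <- substring(prot, 11, 90)
  v <- verify_by_alignment(frag, cfg)
  expect_true(v$pass)
  expect_equal(v$best_identity, 1.0)
  set.seed(64)
  fails <- vapply(1:300, function(i) {
    shuf <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
    !verify_by_alignment(shuf, cfg)$pass
  }, logical(1))
  expect_true(mean(fails) >= 0.99)
})

test_that("the QC decision tree assigns one status per feature and conserves reads", {
  com <- small_community(seed = 65, aa_length = 70, n_taxa = 7,
                         target_identity = 0.95)
  cfg <- qc_config(com$gene$name, 210, com$gene$protein)
  clean <- com$taxa$sequence
  bad <- c(vapply(1:2, function(i) plant_frameshift(clean[i], seed = 100 + i),
                  character(1)),
           plant_stop(clean[3], seed = 103))
  tab <- tibble::tibble(
    feature_id = sprintf("F%02d", 1:10),
    sequence = c(clean, bad),
    s1 = c(rep(100L, 7), 5L, 5L, 5L),
    s2 = c(rep(80L, 7), 2L, 2L, 2L)
  )
  res <- qc_feature_set(tab, cfg)
  expect_equal(nrow(res$verdicts), 10)
  expect_true(all(table(res$verdicts$feature_id) == 1))
  expect_equal(sum(res$verdicts$status %in%
                     c("pass_expected_length", "pass_verified")), 7)
  expect_equal(res$verdicts$status[10], "fail_stop_codon")
  # conservation: curated column sums drop by exactly the failed counts
  expect_equal(sum(res$curated$s1), 700)
  expect_equal(sum(res$curated$s2), 560)
  # all-clean input passes through identically
  res2 <- qc_feature_set(tab[1:7, ], cfg)
  expect_identical(res2$curated, tab[1:7, ])
  # all-fail input raises a diagnostic error
  expect_error(qc_feature_set(tab[8:10, ], cfg), "all features failed")
})

test_that("length gating alone cannot separate errors that verification can", {
  com <- small_community(seed = 66, aa_length = 70, n_taxa = 4,
                         target_identity = 0.97)
  cfg <- qc_config(com$gene$name, 210, com$gene$protein)
  clean <- com$taxa$sequence[1]
  # in-frame codon deletion: anomalous length but a genuine protein
  codon_del <- paste0(substring(clean, 1, 90), substring(clean, 94, 210))
  # frameshift with a compensating trim to the same nucleotide length
  shifted <- substring(plant_frameshift(clean, seed = 70), 1, 207)
  tab <- tibble::tibble(feature_id = c("del", "shift"),
                        sequence = c(codon_del, shifted),
                        s1 = c(10L, 10L))
  res <- qc_feature_set(tab, cfg)
  st <- setNames(res$verdicts$status, res$verdicts$feature_id)
  lens <- setNames(nchar(res$verdicts$protein), res$verdicts$feature_id)
  expect_equal(unname(st["del"]), "pass_verified")
  expect_true(st["shift"] %in% c("fail_unverified", "fail_stop_codon"))
  # both proteins sit below the expected length: the gate cannot tell them apart
  expect_true(all(lens < cfg$expected_aa_len))
})

test_that("QC summaries report wrong-feature and retained-read percentages", {
  verdicts <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    strand = "+", frame = 0L,
    protein = c(strrep("M", 50), strrep("M", 50), strrep("M", 33),
                strrep("M", 61)),
    status = c("pass_expected_length", "pass_verified",
               "fail_stop_codon", "fail_unverified"),
    best_ref_identity = NA_real_
  )
  tab <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        sequence = "N", s1 = c(495L, 495L, 5L, 5L))
  s <- qc_summary(verdicts, tab)
  expect_equal(s$pct_wrong_features, 50)
  expect_equal(s$pct_reads_retained, 99)
  expect_equal(sum(s$size_histogram$n_features), 4)
  p <- plot_qc_sizes(s)
  expect_s3_class(p, "ggplot")
})
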