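mk_reads <- function(seqs, samples) {
  tibble::tibble(sample = samples, sequence = seqs)
}

test_that("quality trimming truncates at the first failing window", {
  good <- tibble::tibble(sequence = strrep("A", 150),
                         qual = strrep("F", 150))       # Q37
  expect_equal(trim_reads(good)$sequence, strrep("A", 150))
  bad <- tibble::tibble(sequence = strrep("A", 150),
                        qual = strrep("#", 150))        # Q2
  expect_equal(nrow(trim_reads(bad)), 0)
  mixed <- tibble::tibble(sequence = strrep("A", 150),
                          qual = paste0(strrep("F", 100), strrep("#", 50)))
  out <- trim_reads(mixed)
  kept <- nchar(out$sequence)
  expect_true(kept >= 100 - 15 && kept <= 100 + 15)
  expect_error(trim_reads(tibble::tibble(sequence = "ACGT",
                                         qual = strrep(" ", 4))),
               "malformed")
})

test_that("pair merging reconstructs amplicons and applies the quality rule", {
  amp <- random_dna(1, 180)
  fwd <- substring(amp, 1, 115)
  rev <- revcomp(substring(amp, 66, 180))   # 50 bp true overlap
  pairs <- tibble::tibble(fwd_seq = fwd, fwd_qual = strrep("F", 115),
                          rev_seq = rev, rev_qual = strrep("F", 115))
  out <- merge_pairs(pairs)
  expect_equal(out$sequence, amp)
  # true overlap 10 < min_overlap 20: discarded
  fwd10 <- substring(amp, 1, 95)
  rev10 <- revcomp(substring(amp, 86, 180))
  short <- tibble::tibble(fwd_seq = fwd10, fwd_qual = strrep("F", 95),
                          rev_seq = rev10, rev_qual = strrep("F", 95))
  out2 <- merge_pairs(short, min_overlap = 20)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "n_discarded"), 1)
  # overlap mismatch resolved toward the higher-quality base
  fwd_mut <- fwd
  substring(fwd_mut, 100, 100) <- if (substring(fwd, 100, 100) == "A") "C" else "A"
  hiq_rev <- tibble::tibble(fwd_seq = fwd_mut,
                            fwd_qual = paste0(strrep("F", 99), "+",
                                              strrep("F", 15)),  # Q10 at mut
                            rev_seq = rev, rev_qual = strrep("F", 115))
  expect_equal(merge_pairs(hiq_rev)$sequence, amp)
})

test_that("dereplication counts, orders and conserves reads", {
  u <- dereplicate(mk_reads(c("AAA", "AAA", "CCC"), c("s1", "s1", "s2")))
  expect_equal(u$sequence, c("AAA", "CCC"))
  expect_equal(u$abundance, c(2, 1))
  expect_equal(u$s1, c(2, 0)); expect_equal(u$s2, c(0, 1))
  expect_equal(sum(u$abundance), 3)
  # abundance ties resolve lexicographically, reproducibly
  u2 <- dereplicate(mk_reads(c("TTT", "GGG"), c("s1", "s1")))
  expect_equal(u2$sequence, c("GGG", "TTT"))
  expect_equal(discard_singletons(u)$sequence, "AAA")
  expect_equal(discard_singletons(u, min_abund = 1), u)
})

test_that("greedy clustering respects thresholds and its centroid invariant", {
  base <- random_dna(1, 100)
  x <- strsplit(base, "")[[1]]
  set.seed(80)
  pos <- sample(100, 8)
  for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
  var92 <- paste(x, collapse = "")      # 92% identity to base
  uniques <- dereplicate(mk_reads(c(rep(base, 5), rep(var92, 3)),
                                  rep("s1", 8)))
  expect_equal(length(greedy_cluster(uniques, 0.97)$centroids), 2)
  expect_equal(length(greedy_cluster(uniques, 0.90)$centroids), 1)
  dup <- dereplicate(mk_reads(rep(base, 4), rep("s1", 4)))
  expect_equal(length(greedy_cluster(dup, 0.97)$centroids), 1)
  # replayable invariant on a richer fixture
  com <- small_community(seed = 81, n_taxa = 10, target_identity = 0.9)
  sim <- simulate_amplicons(com$design, 400, error_model(0.005, 0, 0),
                            seed = 82)
  u <- discard_singletons(dereplicate(sim$reads))
  cs <- greedy_cluster(u, 0.95)
  replay <- vapply(seq_len(nrow(cs$members)), function(i)
    pairwise_identity(cs$members$sequence[i], cs$members$centroid[i]),
    numeric(1))
  expect_true(all(replay >= 0.95 - 1e-12))
  expect_true(all(cs$centroids %in% cs$members$sequence))
})

test_that("the abundance-skew denoiser follows its merge rule exactly", {
  parent <- random_dna(1, 100)
  child <- sub("^.", if (substring(parent, 1, 1) == "A") "C" else "A", parent)
  u <- tibble::tibble(sequence = c(parent, child),
                      abundance = c(1000, 1),
                      s1 = c(1000L, 1L))
  v <- denoise(u, min_abund = 1)
  expect_equal(nrow(v$variants), 1)
  expect_equal(v$variants$abundance, 1001)    # conservation
  u2 <- tibble::tibble(sequence = c(parent, child),
                       abundance = c(500, 500), s1 = c(500L, 500L))
  v2 <- denoise(u2, min_abund = 1)
  expect_equal(nrow(v2$variants), 2)          # 500/500 > 2^-3
  # boundary: ratio exactly 2^-(alpha*d+1) merges
  u3 <- tibble::tibble(sequence = c(parent, child),
                       abundance = c(800, 100), s1 = c(800L, 100L))
  expect_equal(nrow(denoise(u3, min_abund = 1)$variants), 1)
})

test_that("denoising resolves abundant single-nucleotide variants", {
  com <- small_community(seed = 83, n_taxa = 1, target_identity = 1)
  base <- com$taxa$sequence[1]
  snv <- paste0(substring(base, 1, 89),
                if (substring(base, 90, 90) == "G") "T" else "G",
                substring(base, 91, nchar(base)))
  reads <- mk_reads(c(rep(base, 300), rep(snv, 200)), rep("s1", 500))
  v <- denoise(dereplicate(reads))
  expect_equal(sort(v$variants$sequence), sort(c(base, snv)))
})

test_that("de novo bimera flagging finds planted chimeras, spares parents", {
  panel <- make_reference_panel(1, 80, seed = 84)
  p1 <- derive_taxa(panel[1, ], 1, 0.95, seed = 85)$sequence
  p2 <- derive_taxa(panel[1, ], 1, 0.85, seed = 86)$sequence
  bp <- 120
  chim <- paste0(substring(p1, 1, bp), substring(p2, bp + 1, 240))
  u <- tibble::tibble(sequence = c(p1, p2, chim),
                      abundance = c(500, 400, 20),
                      s1 = c(500L, 400L, 20L))
  flags <- flag_chimeras_denovo(u)
  expect_equal(flags, c(FALSE, FALSE, TRUE))
  # chimera-free fixture: no false flags at defaults
  com <- small_community(seed = 87, n_taxa = 6, target_identity = 0.9)
  sim <- simulate_amplicons(com$design, 500, error_model(0.003, 0, 0),
                            seed = 88)
  u2 <- discard_singletons(dereplicate(sim$reads))
  expect_true(mean(flag_chimeras_denovo(u2)) <= 0.02)
})

test_that("feature tables map reads, conserve totals and report unassigned", {
  com <- small_community(seed = 89, n_taxa = 5, target_identity = 0.92)
  sim <- simulate_amplicons(com$design, 300, error_model(0, 0, 0), seed = 90)
  u <- dereplicate(sim$reads)
  cs <- greedy_cluster(u, 0.97)
  tab <- build_feature_table(cs, sim$reads)
  counts <- tab[, setdiff(names(tab), c("feature_id", "sequence"))]
  expect_equal(sum(counts) + attr(tab, "n_unassigned"), nrow(sim$reads))
  expect_equal(attr(tab, "n_unassigned"), 0)
  # error-free reads: per-sample totals equal the multinomial draws
  expect_equal(unname(colSums(counts)),
               unname(as.vector(table(sim$reads$sample))))
  # a read identical to a centroid maps to that centroid
  one <- mk_reads(cs$centroids[1], "s_new")
  tab1 <- build_feature_table(cs, one)
  expect_equal(tab1$s_new[tab1$sequence == cs$centroids[1]], 1L)
})
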