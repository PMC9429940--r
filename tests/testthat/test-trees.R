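test_that("neighbor joining recovers small additive cases exactly", {
  # 3 taxa: closed-form star branch lengths
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  cd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(cd, D, tolerance = 1e-12)
  # additive 4-taxon matrix from a known tree
  t4 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:3):1);")
  D4 <- ape::cophenetic.phylo(t4)
  tr4 <- nj_tree(D4)
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-9)
  expect_equal(robinson_foulds(tr4, ape::unroot(t4))$rf, 0)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|three")
})

test_that("neighbor joining agrees with ape's reference implementation", {
  set.seed(100)
  for (i in 1:10) {
    tr0 <- ape::rtree(sample(5:9, 1), rooted = FALSE)
    D <- ape::cophenetic.phylo(tr0)
    mine <- nj_tree(D)
    ref <- ape::nj(D)
    expect_equal(robinson_foulds(mine, ref)$rf, 0)
    expect_equal(ape::cophenetic.phylo(mine)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("tip label order does not change the NJ topology", {
  set.seed(101)
  tr0 <- ape::rtree(7, rooted = FALSE)
  D <- ape::cophenetic.phylo(tr0)
  perm <- sample(rownames(D))
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(robinson_foulds(t1, t2)$rf, 0)
})

test_that("UniFrac handles the degenerate closed-form cases", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  ca <- c(a = 5, b = 5, c = 0, d = 0)
  cb <- c(a = 0, b = 0, c = 3, d = 7)
  expect_equal(unifrac(star, ca, cb, weighted = FALSE), 1)
  expect_equal(unifrac(star, ca, cb, weighted = TRUE), 1)
  expect_equal(unifrac(star, ca, ca, weighted = FALSE), 0)
  expect_equal(unifrac(star, ca, ca, weighted = TRUE), 0)
  expect_error(unifrac(star, c(z = 1), ca), "absent")
})

test_that("UniFrac matches the brute-force branch enumeration oracle", {
  set.seed(102)
  for (i in 1:12) {
    tr <- ape::rtree(8)
    ca <- random_counts(tr); cb <- random_counts(tr)
    for (w in c(FALSE, TRUE)) {
      expect_equal(unifrac(tr, ca, cb, weighted = w),
                   oracle_unifrac(tr, ca, cb, weighted = w),
                   tolerance = 1e-12)
    }
    expect_equal(unifrac(tr, ca, cb, weighted = TRUE, normalized = FALSE),
                 oracle_unifrac(tr, ca, cb, weighted = TRUE,
                                normalized = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("UniFrac agrees with phyloseq on a shared example", {
  skip_if_not_installed("phyloseq")
  set.seed(103)
  tr <- ape::rtree(10)
  counts <- cbind(sA = rpois(10, 8), sB = rpois(10, 8)) + 1
  rownames(counts) <- tr$tip.label
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(counts, taxa_are_rows = TRUE), tr)
  ref_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))["sA", "sB"]
  ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                       normalized = TRUE))["sA", "sB"]
  expect_equal(unifrac(tr, counts[, 1], counts[, 2]), ref_u,
               tolerance = 1e-10)
  expect_equal(unifrac(tr, counts[, 1], counts[, 2], weighted = TRUE),
               ref_w, tolerance = 1e-10)
})

test_that("Robinson-Foulds distances behave on canonical cases", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(robinson_foulds(t1, t1)$rf, 0)
  r <- robinson_foulds(t1, t2)
  expect_equal(r$rf_norm, 1)
  expect_equal(r$rf, robinson_foulds(t2, t1)$rf)
  expect_error(robinson_foulds(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "identical tip")
  # prune-to-shared keeps the shared-tip induced topologies
  t3 <- ape::read.tree(text = "(((a,b),x),((c,y),d));")
  expect_equal(robinson_foulds(t1, t3, mode = "prune-to-shared")$rf, 0)
})

test_that("bipartitions match phangorn and the subset-enumeration oracle", {
  skip_if_not_installed("phangorn")
  set.seed(104)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    t1 <- ape::rtree(n, rooted = FALSE)
    t2 <- ape::rtree(n, rooted = FALSE)
    t2$tip.label <- t1$tip.label
    mine <- robinson_foulds(t1, t2)
    expect_equal(mine$rf, phangorn::RF.dist(t1, t2))
    orc <- oracle_rf(t1, t2)
    expect_equal(mine$rf, orc$rf)
    expect_true(mine$rf_norm >= 0 && mine$rf_norm <= 1)
  }
})

test_that("incremental congruence is zero for identical inputs and caps length", {
  panel <- make_reference_panel(1, 60, seed = 105)
  refs <- setNames(derive_taxa(panel[1, ], 5, 0.85, seed = 106,
                               frame_preserving = FALSE)$sequence,
                   paste0("ref", 1:5))
  feats <- tibble::tibble(
    feature_id = paste0("f", 1:8),
    sequence = derive_taxa(panel[1, ], 8, 0.95, seed = 107)$sequence,
    abundance = 8:1)
  cur <- incremental_congruence(feats, feats, refs)
  expect_equal(nrow(cur), 8)
  expect_equal(cur$rf_norm, rep(0, 8))
  # curve length = min(|A|, |B|, max_iter)
  cur2 <- incremental_congruence(feats, feats[1:3, ], refs)
  expect_equal(nrow(cur2), 3)
  cur3 <- incremental_congruence(feats, feats, refs, max_iter = 2)
  expect_equal(nrow(cur3), 2)
  # reference input order is irrelevant
  cur4 <- incremental_congruence(feats, feats[1:3, ], refs[c(3, 1, 5, 2, 4)])
  expect_equal(cur4$rf_norm, cur2$rf_norm)
  expect_error(incremental_congruence(feats, feats, refs[1:3]), "4 reference")
})

test_that("log-curve fits recover noiseless coefficients exactly", {
  n <- c(1, 2, 4, 8, 16, 32)
  curve <- tibble::tibble(n_added = n, rf_norm = 0.1 * log(n) + 0.05)
  fit <- fit_log_curve(curve)
  expect_equal(fit$a, 0.1, tolerance = 1e-9)
  expect_equal(fit$b, 0.05, tolerance = 1e-9)
  expect_true(fit$rmse < 1e-12)
  flat <- tibble::tibble(n_added = n, rf_norm = 0.4)
  fit2 <- fit_log_curve(flat)
  expect_equal(fit2$a, 0, tolerance = 1e-12)
  expect_equal(fit2$b, 0.4, tolerance = 1e-12)
  expect_error(fit_log_curve(tibble::tibble(n_added = c(3, 3),
                                            rf_norm = c(0, 1))),
               "distinct")
  # noisy recovery stays within sampling error
  set.seed(108)
  ok <- vapply(1:50, function(i) {
    nn <- 2:40
    y <- 0.07 * log(nn) + 0.02 + rnorm(length(nn), 0, 0.01)
    f <- fit_log_curve(tibble::tibble(n_added = nn, rf_norm = y))
    se <- 0.01 / sqrt(sum((log(nn) - mean(log(nn)))^2))
    abs(f$a - 0.07) <= 3 * se
  }, logical(1))
  expect_true(mean(ok) >= 0.9)
})
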