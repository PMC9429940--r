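test_that("reference databases validate their lineages", {
  expect_error(reference_db("a", "ACGT", "Bacteria;Phylum"), "7 ranks")
  expect_error(reference_db(c("a", "a"), c("ACGT", "ACGT"),
                            rep("d;p;c;o;f;g;s", 2)), "unique")
  db <- reference_db("a", "ACGT", "d;p;c;o;f;g;s")
  expect_equal(db$species, "s")
})

test_that("synthetic databases are seed-stable with a nearer near-DB", {
  panel <- make_reference_panel(1, 80, seed = 1)
  dbs <- build_synthetic_db(panel[1, ], n_genera = 3,
                            n_species_per_genus = 3, seed = 2)
  expect_equal(nrow(dbs$db_near), 3 * 3 * 2)
  expect_equal(length(unique(paste(dbs$db_near$genus,
                                   dbs$db_near$species))), 9)
  dbs_b <- build_synthetic_db(panel[1, ], n_genera = 3,
                              n_species_per_genus = 3, seed = 2)
  expect_identical(dbs$db_near$sequence, dbs_b$db_near$sequence)
  q <- derive_taxa(panel[1, ], 5, 0.98, seed = 3)$sequence
  near_best <- vapply(q, function(s)
    max(identity_to_refs(s, dbs$db_near$sequence)), numeric(1))
  far_best <- vapply(q, function(s)
    max(identity_to_refs(s, dbs$db_far$sequence)), numeric(1))
  expect_true(mean(near_best) > mean(far_best))
})

test_that("NBC assigns exact members with certainty, deterministically", {
  panel <- make_reference_panel(1, 80, seed = 4)
  dbs <- build_synthetic_db(panel[1, ], seed = 5)
  db <- dbs$db_near
  q <- db$sequence[1]        # exact member of genus1/species1
  a <- nbc_classify(q, db, seed = 6)
  expect_equal(a$assignment$taxon[7], db$species[1])
  expect_equal(a$assignment$confidence[7], 1.0)
  expect_identical(nbc_classify(q, db, seed = 6)$assignment, a$assignment)
  expect_error(nbc_classify(q, db[0, ]), "empty")
})

test_that("NBC confidence never drops when the assigned species is duplicated", {
  panel <- make_reference_panel(1, 80, seed = 7)
  dbs <- build_synthetic_db(panel[1, ], seed = 8)
  db <- dbs$db_near
  q <- derive_taxa(panel[1, ], 1, 0.97, seed = 9)$sequence
  a1 <- nbc_classify(q, db, seed = 10)
  sp <- a1$assignment$taxon[7]
  dup_rows <- db[db$species == sp, ]
  dup_rows$id <- paste0(dup_rows$id, "_dup")
  db2 <- dplyr::bind_rows(db, dup_rows)
  class(db2) <- class(db)
  a2 <- nbc_classify(q, db2, seed = 10)
  expect_true(a2$assignment$confidence[7] >= a1$assignment$confidence[7] - 1e-12)
  expect_equal(a2$assignment$taxon[7], sp)
})

test_that("the two Nitrosomonas LCA scenarios resolve as described", {
  db <- nitrosomonas_db()
  # query matching two N. europaea references -> the species itself
  q_eur <- db$sequence[db$id == "eur1"]
  a <- blca_classify(q_eur, db, seed = 11)
  expect_equal(a$assignment$taxon[7], "Nitrosomonas europaea")
  # query equidistant from N. europaea and N. oligotropha -> genus only
  eur <- db$sequence[db$id == "eur1"]
  oli <- db$sequence[db$id == "oli1"]
  # build a midpoint query: take oli's bases at half the differing sites
  xe <- strsplit(eur, "")[[1]]; xo <- strsplit(oli, "")[[1]]
  diffs <- which(xe != xo)
  half <- diffs[seq_along(diffs) %% 2 == 0]
  xm <- xe; xm[half] <- xo[half]
  q_mid <- paste(xm, collapse = "")
  b <- blca_classify(q_mid, db, seed = 12)
  expect_equal(b$assignment$taxon[6], "Nitrosomonas")
  expect_equal(b$assignment$taxon[7], "UNASSIGNED")
})

test_that("BLCA with one perfect hit assigns the full lineage; none, nothing", {
  db <- nitrosomonas_db()
  solo <- db[db$id == "out1", ]
  class(solo) <- class(db)
  a <- blca_classify(solo$sequence[1], solo, seed = 13)
  expect_equal(a$assignment$taxon[7], "Nitrosococcus oceani")
  expect_equal(a$assignment$confidence, rep(1, 7))
  none <- blca_classify(paste(rep("ACGT", 30), collapse = ""), solo,
                        seed = 14)
  expect_true(all(none$assignment$taxon == "UNASSIGNED"))
  expect_error(blca_classify("ACGT", solo), "50")
})

test_that("confidence is monotone down ranks and UNASSIGNED propagates", {
  panel <- make_reference_panel(1, 80, seed = 15)
  dbs <- build_synthetic_db(panel[1, ], seed = 16)
  qs <- derive_taxa(panel[1, ], 6, 0.95, seed = 17)$sequence
  for (i in seq_along(qs)) {
    for (fn in list(nbc_classify, blca_classify)) {
      a <- fn(qs[i], dbs$db_near, seed = 18 + i)$assignment
      expect_true(all(diff(a$confidence) <= 1e-12))
      un <- a$taxon == "UNASSIGNED"
      if (any(un)) expect_true(all(un[which(un)[1]:7]))
    }
  }
})

test_that("unassigned percentages are plain arithmetic", {
  db <- nitrosomonas_db()
  a1 <- blca_classify(db$sequence[1], db, seed = 19)
  a2 <- blca_classify(paste(rep("ACGT", 30), collapse = ""),
                      db[db$id == "out1", ] |>
                        (\(x) { class(x) <- class(db); x })(), seed = 20)
  expect_equal(summarize_unassigned(list(a1, a1)), 0)
  expect_equal(summarize_unassigned(list(a1, a2)), 50)
  expect_equal(summarize_unassigned(list(a2, a2)), 100)
})
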