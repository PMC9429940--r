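# Taxonomy assignment by the two classifier families under comparison:
# an RDP-style naive Bayesian k-mer classifier (NBC) with bootstrap
# confidence, and a BLCA-style alignment + lowest-common-ancestor
# classifier with per-rank confidence. A synthetic hierarchical reference
# database builder provides the "near" vs "distant" database contrast.

RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Build a reference database tibble
#'
#' @param ids unique entry ids.
#' @param sequences nucleotide strings.
#' @param lineages character vector of 7 semicolon-delimited ranks
#'   (domain;phylum;class;order;family;genus;species).
#' @return tibble of class `reference_db` with `id`, `sequence`, one column
#'   per rank.
#' @export
reference_db <- function(ids, sequences, lineages) {
  parts <- strsplit(lineages, ";", fixed = TRUE)
  if (any(lengths(parts) != 7L)) abort("every lineage needs exactly 7 ranks")
  if (anyDuplicated(ids)) abort("ids must be unique")
  ranks <- do.call(rbind, parts)
  colnames(ranks) <- RANKS
  out <- tibble(id = ids, sequence = sequences)
  out <- dplyr::bind_cols(out, as_tibble(ranks))
  class(out) <- c("reference_db", class(out))
  out
}

#' Build paired near/distant synthetic reference databases
#'
#' Hierarchical lineages with within-species < within-genus < between-genus
#' divergence, derived from one gene model. The "near" database diverges
#' from the gene (and hence from queries derived from it) by
#' `divergence_near`; the "distant" database by the larger
#' `divergence_far`, emulating a reference set dominated by sequences
#' unlike those retrieved from the studied environment.
#'
#' @param gene one row of [make_reference_panel()].
#' @param n_genera,n_species_per_genus lineage layout.
#' @param divergence_near,divergence_far fractions of sites substituted for
#'   the two databases (near < far).
#' @param n_per_species reference entries per species (default 2).
#' @param seed integer seed.
#' @return list with `db_near` and `db_far` (both `reference_db`).
#' @export
build_synthetic_db <- function(gene, n_genera = 3, n_species_per_genus = 3,
                               divergence_near = 0.05, divergence_far = 0.3,
                               n_per_species = 2, seed = 1) {
  stopifnot(n_genera >= 1, n_species_per_genus >= 1,
            divergence_near < divergence_far)
  build_one <- function(divergence, tag, seed_offset) {
    # genus 1 / species 1 sits exactly at `divergence` from the reference
    # gene; further species and genera are staggered a full `divergence`
    # step apart so query-generating taxa always have one clearly nearest
    # lineage. Entries within a species carry only light noise.
    entry_div <- min(0.005, divergence / 10)
    rows <- list()
    for (gi in seq_len(n_genera)) {
      genus_div <- divergence * (1 + 0.75 * (gi - 1))
      ganc <- derive_taxa(gene, 1, 1 - genus_div,
                          seed = seed + seed_offset + 13 * gi,
                          frame_preserving = FALSE)$sequence
      ggene <- tibble(name = gene$name, coding_seq = ganc)
      for (si in seq_len(n_species_per_genus)) {
        species_div <- (si - 1) * divergence
        sanc <- if (si == 1) ganc else
          derive_taxa(ggene, 1, 1 - species_div,
                      seed = seed + seed_offset + 13 * gi + 131 * si,
                      frame_preserving = FALSE)$sequence
        sgene <- tibble(name = gene$name, coding_seq = sanc)
        entries <- derive_taxa(sgene, n_per_species, 1 - entry_div,
                               seed = seed + seed_offset + 13 * gi + 131 * si + 7,
                               frame_preserving = FALSE)
        for (ei in seq_len(n_per_species)) {
          rows[[length(rows) + 1]] <- tibble(
            id = sprintf("%s_g%d_s%d_e%d", tag, gi, si, ei),
            sequence = entries$sequence[ei],
            lineage = sprintf(
              "Bacteria;Phylum1;Class1;Order1;Family%d;Genus%d_%s;Genus%d_%s species%d",
              gi, gi, tag, gi, tag, si)
          )
        }
      }
    }
    df <- bind_rows(rows)
    reference_db(df$id, df$sequence, df$lineage)
  }
  list(db_near = build_one(divergence_near, "near", 0),
       db_far = build_one(divergence_far, "far", 10000))
}

db_lineage_strings <- function(db) {
  apply(as.matrix(db[, RANKS]), 1, paste, collapse = ";")
}

kmer_set <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  unique(substring(seq, seq_len(n), seq_len(n) + k - 1L))
}

empty_assignment <- function(method) {
  structure(
    list(assignment = tibble(rank = RANKS, taxon = "UNASSIGNED",
                             confidence = 0),
         method = method),
    class = "taxonomy_assignment"
  )
}

#' @export
print.taxonomy_assignment <- function(x, ...) {
  deepest <- rev(which(x$assignment$taxon != "UNASSIGNED"))
  lab <- if (length(deepest) == 0) "fully UNASSIGNED" else
    sprintf("%s = %s (conf %.2f)", x$assignment$rank[deepest[1]],
            x$assignment$taxon[deepest[1]],
            x$assignment$confidence[deepest[1]])
  cat(sprintf("<taxonomy_assignment:%s> %s\n", x$method, lab))
  invisible(x)
}

# turn per-bootstrap winning lineages into a per-rank assignment:
# candidate = modal species lineage; confidence at rank r = fraction of
# bootstrap winners agreeing with the candidate at rank r (monotone
# non-increasing with depth since lineages are nested paths)
consensus_from_bootstraps <- function(win_lineages, conf_cutoff, method,
                                      weights = NULL) {
  if (length(win_lineages) == 0) return(empty_assignment(method))
  weights <- weights %||% rep(1, length(win_lineages))
  agg <- tapply(weights, win_lineages, sum)
  candidate <- names(agg)[order(-agg, names(agg))][1]
  cand_ranks <- strsplit(candidate, ";", fixed = TRUE)[[1]]
  win_ranks <- strsplit(win_lineages, ";", fixed = TRUE)
  wsum <- sum(weights)
  taxon <- character(7); conf <- numeric(7)
  blocked <- FALSE
  for (r in seq_len(7)) {
    agree <- vapply(win_ranks, function(x) identical(x[r], cand_ranks[r]),
                    logical(1))
    conf[r] <- sum(weights[agree]) / wsum
    if (!blocked && conf[r] >= conf_cutoff) {
      taxon[r] <- cand_ranks[r]
    } else {
      taxon[r] <- "UNASSIGNED"
      conf[r] <- if (blocked) 0 else conf[r]
      blocked <- TRUE
    }
  }
  structure(
    list(assignment = tibble(rank = RANKS, taxon = taxon, confidence = conf),
         method = method),
    class = "taxonomy_assignment"
  )
}

#' Naive Bayesian k-mer classifier with bootstrap confidence
#'
#' RDP-style scheme. Word priors over the database,
#' `P(w) = (n(w) + 0.5) / (N + 1)`; species conditionals
#' `P(w|s) = (m(w, s) + P(w)) / (M_s + 1)`. Each bootstrap samples
#' `ceiling(V / 8)` of the query's V distinct words with replacement and
#' scores every species by `sum log P(w|s)`; per-rank confidence is the
#' fraction of bootstraps whose winning lineage agrees at that rank. The
#' deepest rank reaching `conf_cutoff` is assigned; deeper ranks are
#' UNASSIGNED.
#'
#' @param query nucleotide string (longer than `k`).
#' @param db a `reference_db`.
#' @param k word size (default 8).
#' @param n_boot bootstrap replicates (default 100).
#' @param conf_cutoff assignment confidence cutoff (default 0.8).
#' @param seed integer seed.
#' @return `taxonomy_assignment` (method `"nbc"`).
#' @export
nbc_classify <- function(query, db, k = 8, n_boot = 100, conf_cutoff = 0.8,
                         seed = 1) {
  if (nrow(db) == 0) abort("empty reference database")
  if (nchar(query) <= k) abort("query shorter than word size")
  lineage <- db_lineage_strings(db)
  # duplicate (lineage, sequence) entries carry no information and would
  # perturb the word priors, so the model is built on the unique set
  keep <- !duplicated(paste(lineage, db$sequence))
  db <- db[keep, , drop = FALSE]
  lineage <- lineage[keep]
  words_by_entry <- map(db$sequence, kmer_set, k = k)
  vocab <- unique(unlist(words_by_entry))
  N <- nrow(db)
  n_w <- table(factor(unlist(map(words_by_entry, unique)), levels = vocab))
  prior <- (as.numeric(n_w) + 0.5) / (N + 1)
  names(prior) <- vocab
  species <- unique(lineage)
  # m(w, s): entries of species s containing word w
  logp <- matrix(0, nrow = length(vocab), ncol = length(species),
                 dimnames = list(vocab, species))
  for (si in seq_along(species)) {
    entries <- which(lineage == species[si])
    m_ws <- table(factor(unlist(words_by_entry[entries]), levels = vocab))
    logp[, si] <- log((as.numeric(m_ws) + prior) / (length(entries) + 1))
  }
  qwords <- kmer_set(query, k)
  known <- qwords[qwords %in% vocab]
  # unseen words contribute log(P(w) / (M_s + 1)); approximate with the
  # smallest prior so they penalise every species equally
  V <- length(qwords)
  if (length(known) == 0) return(empty_assignment("nbc"))
  set.seed(seed)
  n_draw <- ceiling(V / 8)
  winners <- character(n_boot)
  for (bi in seq_len(n_boot)) {
    draw <- sample(known, n_draw, replace = TRUE)
    sc <- colSums(logp[draw, , drop = FALSE])
    winners[bi] <- species[order(-sc, species)[1]]
  }
  consensus_from_bootstraps(winners, conf_cutoff, "nbc")
}

#' Alignment + lowest-common-ancestor classifier with confidence
#'
#' BLCA-style scheme. Hits are database entries whose global-alignment
#' identity to the query is at least `min_identity` and within `top_margin`
#' of the best hit. Each bootstrap resamples query positions of the
#' alignments, re-scores every hit by its resampled identity, and
#' distributes one unit of weight over hits proportionally to score;
#' per-rank confidence is the mean weight carried by the modal taxon. The
#' modal taxon is assigned at every rank where confidence reaches
#' `conf_cutoff`; with no hits the query is fully UNASSIGNED.
#'
#' @param query nucleotide string (>= 50 nt).
#' @param db a `reference_db`.
#' @param min_identity minimum hit identity (default 0.80).
#' @param top_margin identity margin below the best hit (default 0.02).
#' @param n_boot bootstrap replicates (default 100).
#' @param conf_cutoff assignment confidence cutoff (default 0.80).
#' @param seed integer seed.
#' @return `taxonomy_assignment` (method `"blca"`).
#' @export
blca_classify <- function(query, db, min_identity = 0.80, top_margin = 0.02,
                          n_boot = 100, conf_cutoff = 0.80, seed = 1) {
  if (nrow(db) == 0) abort("empty reference database")
  if (nchar(query) < 50) abort("query shorter than 50 nt")
  ids <- identity_to_refs(query, db$sequence)
  best <- max(ids)
  hit <- which(ids >= min_identity & ids >= best - top_margin)
  if (length(hit) == 0) return(empty_assignment("blca"))
  lineage <- db_lineage_strings(db)[hit]
  profiles <- match_profiles(query, db$sequence[hit])
  L <- nchar(query)
  set.seed(seed)
  win <- character(0); wts <- numeric(0)
  for (bi in seq_len(n_boot)) {
    pos <- sample.int(L, L, replace = TRUE)
    sc <- map_dbl(profiles, function(pr) sum(pr[pos]) / L)
    if (sum(sc) == 0) sc <- rep(1, length(sc))
    w <- sc / sum(sc)
    win <- c(win, lineage)
    wts <- c(wts, w / n_boot)
  }
  consensus_from_bootstraps(win, conf_cutoff, "blca")
}

#' Percentage of queries unassigned at a rank
#'
#' @param assignments list of `taxonomy_assignment` objects.
#' @param rank one of domain...species (default `"species"`).
#' @return percentage in \[0, 100\].
#' @export
summarize_unassigned <- function(assignments, rank = "species") {
  stopifnot(length(assignments) >= 1, rank %in% RANKS)
  unassigned <- map_lgl(assignments, function(a) {
    a$assignment$taxon[a$assignment$rank == rank] == "UNASSIGNED"
  })
  100 * mean(unassigned)
}

#' Contrast NBC and BLCA over near and distant reference databases
#'
#' Classifies every query with both methods against both databases and
#' tabulates the percentage unassigned at each rank. On a distant database
#' the LCA route typically loses species resolution first (no qualifying
#' alignment hits), while the k-mer route can still commit to the nearest
#' species.
#'
#' @param queries character vector of nucleotide queries.
#' @param db_near,db_far `reference_db` objects (e.g. from
#'   [build_synthetic_db()]).
#' @param seed integer seed.
#' @param ... passed to the classifiers.
#' @return tibble: method, db, rank, pct_unassigned.
#' @export
compare_classifiers <- function(queries, db_near, db_far, seed = 1, ...) {
  dbs <- list(near = db_near, far = db_far)
  out <- list()
  for (dbn in names(dbs)) {
    for (method in c("nbc", "blca")) {
      fn <- if (method == "nbc") nbc_classify else blca_classify
      asg <- map(seq_along(queries), function(i)
        fn(queries[i], dbs[[dbn]], seed = seed + i, ...))
      for (r in RANKS) {
        out[[length(out) + 1]] <- tibble(
          method = method, db = dbn, rank = r,
          pct_unassigned = summarize_unassigned(asg, r))
      }
    }
  }
  bind_rows(out)
}
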