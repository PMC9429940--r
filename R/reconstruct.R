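# Read-to-feature reconstruction along the two routes under comparison:
# greedy identity-threshold clustering (the OTU route) and an abundance-skew
# exact-variant denoiser honouring the single-nucleotide-resolution contract
# of the ASV route. Shared preprocessing: quality trimming, pair merging,
# dereplication, singleton discard, and de novo bimera flagging.

#' Quality-trim reads with a 3'-scanning sliding window
#'
#' A window of width `max(1, round(0.1 * read length))` slides along the
#' read; the read is truncated just before the first window whose mean
#' Phred quality falls below `q_threshold`. Reads shorter than `min_len`
#' after trimming are dropped.
#'
#' @param reads tibble with `sequence` and `qual` columns (Phred+33), plus
#'   any id columns, which are preserved.
#' @param q_threshold mean-quality threshold (default 20).
#' @param min_len minimum retained length in bp (default 10).
#' @return tibble of surviving reads with trimmed `sequence`/`qual`.
#' @export
trim_reads <- function(reads, q_threshold = 20, min_len = 10) {
  stopifnot(all(c("sequence", "qual") %in% names(reads)))
  cut_at <- map_int(seq_len(nrow(reads)), function(i) {
    q <- phred_values(reads$qual[i])
    if (any(q < 0 | q > 60)) abort("malformed quality string")
    L <- length(q)
    w <- max(1L, as.integer(round(0.1 * L)))
    if (L < w) return(L)
    cs <- cumsum(c(0, q))
    means <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
    bad <- which(means < q_threshold)
    if (length(bad) == 0) L else bad[1] - 1L
  })
  out <- reads
  out$sequence <- substring(out$sequence, 1, cut_at)
  out$qual <- substring(out$qual, 1, cut_at)
  out[cut_at >= min_len, , drop = FALSE]
}

#' Merge overlapping read pairs
#'
#' Finds the best ungapped overlap of at least `min_overlap` bp between the
#' forward read and the reverse-complemented reverse read by match -
#' mismatch score. Overlap mismatches are resolved in favour of the
#' higher-quality base. Pairs with no overlap of sufficient length and
#' identity (>= 0.75 over the overlap) are discarded; the number discarded
#' is recorded in the `n_discarded` attribute.
#'
#' @param pairs tibble with `fwd_seq`, `fwd_qual`, `rev_seq`, `rev_qual`
#'   (reverse read as sequenced, i.e. reverse-complement orientation).
#' @param min_overlap minimum overlap in bp (default 20; some genes need 4).
#' @return tibble of merged reads (`sequence` plus preserved id columns).
#' @export
merge_pairs <- function(pairs, min_overlap = 20) {
  stopifnot(all(c("fwd_seq", "fwd_qual", "rev_seq", "rev_qual") %in% names(pairs)))
  merged <- map(seq_len(nrow(pairs)), function(i) {
    f <- strsplit(pairs$fwd_seq[i], "", fixed = TRUE)[[1]]
    fq <- phred_values(pairs$fwd_qual[i])
    r <- strsplit(revcomp(pairs$rev_seq[i]), "", fixed = TRUE)[[1]]
    rq <- rev(phred_values(pairs$rev_qual[i]))
    lf <- length(f); lr <- length(r)
    best <- NULL; best_score <- -Inf
    for (o in seq.int(min_overlap, min(lf, lr))) {
      ft <- f[(lf - o + 1):lf]; rh <- r[1:o]
      m <- sum(ft == rh)
      score <- m - (o - m)
      if (score > best_score) {
        best_score <- score; best <- list(o = o, matches = m)
      }
    }
    if (is.null(best) || best$matches / best$o < 0.75) return(NULL)
    o <- best$o
    ov_f <- (lf - o + 1):lf
    ov <- ifelse(f[ov_f] == r[1:o], f[ov_f],
                 ifelse(fq[ov_f] >= rq[1:o], f[ov_f], r[1:o]))
    paste(c(f[seq_len(lf - o)], ov, r[seq.int(o + 1, length.out = lr - o)]),
          collapse = "")
  })
  keep <- !vapply(merged, is.null, logical(1))
  out <- pairs[keep, setdiff(names(pairs),
                             c("fwd_seq", "fwd_qual", "rev_seq", "rev_qual")),
               drop = FALSE]
  out$sequence <- unlist(merged[keep])
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Dereplicate reads into unique sequences with per-sample abundances
#'
#' Exact-string dereplication pooled across samples. Output is sorted by
#' decreasing total abundance with ties broken lexicographically by
#' sequence, so the order is deterministic.
#'
#' @param reads tibble with `sample` and `sequence` columns.
#' @return tibble: `sequence`, `abundance`, one count column per sample.
#' @export
dereplicate <- function(reads) {
  stopifnot(all(c("sample", "sequence") %in% names(reads)))
  wide <- reads |>
    count(.data$sequence, .data$sample) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "n",
                       values_fill = 0L)
  sample_cols <- setdiff(names(wide), "sequence")
  wide$abundance <- rowSums(wide[, sample_cols, drop = FALSE])
  wide <- wide[, c("sequence", "abundance", sort(sample_cols))]
  wide[order(-wide$abundance, wide$sequence), , drop = FALSE]
}

#' Discard low-abundance unique sequences
#'
#' @param uniques tibble from [dereplicate()].
#' @param min_abund keep sequences with total abundance >= this (default 2,
#'   i.e. singletons are discarded).
#' @return filtered tibble, order preserved.
#' @export
discard_singletons <- function(uniques, min_abund = 2) {
  uniques[uniques$abundance >= min_abund, , drop = FALSE]
}

# 5-mer count matrix used to prescreen alignment candidates (the same
# trick threshold-clustering tools use to avoid all-vs-all alignment)
kmer_counts <- function(seqs, k = 5) {
  Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                       width = k)
}

#' Greedy centroid clustering at an identity threshold
#'
#' Scans unique sequences in decreasing-abundance order. A sequence founds
#' a new centroid exactly when its identity to every earlier-founded
#' centroid is below `t`; otherwise it is assigned to the eligible centroid
#' of maximal identity (ties: earliest centroid). Identity is
#' [pairwise_identity()]. Centroid discovery is
#' exact; the maximal-identity assignment considers the `screen_top`
#' closest centroids by shared 5-mer count (plus the centroid that proved
#' the sequence clusterable), which is exact whenever a sequence has at
#' most `screen_top` eligible centroids.
#'
#' @param uniques tibble from [dereplicate()] (must be sorted by decreasing
#'   abundance, as dereplicate returns).
#' @param t identity threshold in (0, 1].
#' @param screen_top candidate centroids examined per sequence (default 4).
#' @return object of class `cluster_set`: list with `threshold`,
#'   `centroids` (character), `members` (tibble: sequence, centroid,
#'   identity).
#' @export
greedy_cluster <- function(uniques, t, screen_top = 4) {
  stopifnot(t > 0, t <= 1)
  seqs <- uniques$sequence
  n <- length(seqs)
  # phase 1: centroid discovery in scan order. Equivalent to the
  # sequential definition: a sequence founds a centroid iff it is < t to
  # all centroids founded from earlier sequences.
  centroid_at <- integer(0)          # scan positions of centroids
  cover <- integer(n)                # first centroid proving id >= t
  cover_id <- numeric(n)
  uncov <- seq_len(n)
  while (length(uncov) > 0) {
    ci <- uncov[1]
    centroid_at <- c(centroid_at, ci)
    cover[ci] <- length(centroid_at); cover_id[ci] <- 1
    rest <- uncov[-1]
    if (length(rest) == 0) break
    ids <- identity_to_refs(seqs[ci], seqs[rest])
    hit <- ids >= t
    cover[rest[hit]] <- length(centroid_at)
    cover_id[rest[hit]] <- ids[hit]
    uncov <- rest[!hit]
  }
  m <- length(centroid_at)
  assign_to <- cover
  ident <- cover_id
  # phase 2: re-assign members to the best eligible centroid among k-mer
  # screened candidates (a centroid is eligible if founded from an earlier
  # scan position)
  if (m > 1) {
    K <- kmer_counts(seqs)
    sims <- K %*% t(K[centroid_at, , drop = FALSE])
    todo_by_centroid <- vector("list", m)
    for (i in setdiff(seq_len(n), centroid_at)) {
      elig <- which(centroid_at < i)
      cand <- elig[order(-sims[i, elig])]
      cand <- union(head(cand, screen_top), cover[i])
      for (j in cand) {
        todo_by_centroid[[j]] <- c(todo_by_centroid[[j]], i)
      }
    }
    id_cache <- new.env(parent = emptyenv())
    for (j in seq_len(m)) {
      qs <- todo_by_centroid[[j]]
      if (length(qs) == 0) next
      ids <- identity_to_refs(seqs[centroid_at[j]], seqs[qs])
      for (u in seq_along(qs)) {
        key <- as.character(qs[u])
        cur <- id_cache[[key]] %||% numeric(0)
        cur[as.character(j)] <- ids[u]
        id_cache[[key]] <- cur
      }
    }
    for (i in setdiff(seq_len(n), centroid_at)) {
      cur <- id_cache[[as.character(i)]]
      js <- as.integer(names(cur))
      ok <- cur >= t
      if (any(ok)) {
        best_id <- max(cur[ok])
        best_j <- min(js[ok & cur >= best_id - 1e-12])  # earliest on ties
        assign_to[i] <- best_j; ident[i] <- cur[as.character(best_j)]
      }
    }
  }
  centroids <- seqs[centroid_at]
  structure(
    list(threshold = t, centroids = centroids,
         members = tibble(sequence = seqs, centroid = centroids[assign_to],
                          identity = ident)),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> t = %.2f: %d members in %d clusters\n",
              x$threshold, nrow(x$members), length(x$centroids)))
  invisible(x)
}

#' Abundance-skew denoising to exact sequence variants
#'
#' A threshold-free variant caller honouring the exact-variant contract
#' (sequences differing by a single nucleotide are resolved whenever both
#' are abundant). Scanning uniques in decreasing-abundance order, a
#' candidate at edit distance d >= 1 from an accepted variant is absorbed
#' into the nearest variant when its abundance ratio satisfies
#' `abundance(c) / abundance(v) <= 2^-(alpha * d + 1)` (an UNOISE-style
#' skew rule); otherwise it becomes a new variant. Absorbed abundances are
#' added to the absorbing variant, so total abundance is conserved.
#'
#' @param uniques tibble from [dereplicate()], sorted by decreasing
#'   abundance.
#' @param alpha skew steepness (default 2).
#' @param min_abund minimum input abundance considered (default 2).
#' @return list of class `variant_set`: `variants` tibble (sequence,
#'   abundance and per-sample counts, including absorbed mass) and
#'   `members` tibble (sequence, variant).
#' @export
denoise <- function(uniques, alpha = 2, min_abund = 2) {
  uniques <- uniques[uniques$abundance >= min_abund, , drop = FALSE]
  seqs <- uniques$sequence
  ab <- uniques$abundance
  sample_cols <- setdiff(names(uniques), c("sequence", "abundance"))
  counts <- as.matrix(uniques[, sample_cols, drop = FALSE])
  variant_idx <- integer(0)       # indices into uniques that became variants
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    if (length(variant_idx) > 0) {
      # only variants skewed enough to absorb at d = 1 can absorb at all
      pre <- which(ab[i] / ab[variant_idx] <= 2^-(alpha + 1))
      if (length(pre) > 0) {
        d <- as.vector(adist(seqs[i], seqs[variant_idx[pre]]))
        ratio_ok <- ab[i] / ab[variant_idx[pre]] <= 2^-(alpha * d + 1)
        elig <- which(d >= 1 & ratio_ok)
        if (length(elig) > 0) {
          best <- pre[elig[which.min(d[elig])]]
          assign_to[i] <- best
          next
        }
      }
    }
    variant_idx <- c(variant_idx, i)
    assign_to[i] <- length(variant_idx)
  }
  v_ab <- numeric(length(variant_idx))
  v_counts <- matrix(0L, nrow = length(variant_idx), ncol = ncol(counts))
  for (i in seq_along(seqs)) {
    j <- assign_to[i]
    v_ab[j] <- v_ab[j] + ab[i]
    v_counts[j, ] <- v_counts[j, ] + counts[i, ]
  }
  variants <- tibble(sequence = seqs[variant_idx], abundance = v_ab)
  variants[sample_cols] <- as.data.frame(v_counts)
  structure(
    list(variants = variants,
         members = tibble(sequence = seqs,
                          variant = seqs[variant_idx][assign_to])),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d uniques denoised to %d variants\n",
              nrow(x$members), nrow(x$variants)))
  invisible(x)
}

#' Flag de novo bimeras among unique sequences
#'
#' For each candidate (scanned in decreasing-abundance order), potential
#' parents are uniques at least `abskew` times more abundant. Over all
#' parent pairs and single breakpoints the best two-segment chimeric model
#' identity is computed; the candidate is flagged when that model reaches
#' `min_model_id` identity and exceeds the best single-parent identity by
#' at least `min_gain`.
#'
#' @param uniques tibble from [dereplicate()], sorted by decreasing
#'   abundance.
#' @param min_model_id minimum chimeric-model identity (default 0.99).
#' @param min_gain required improvement over the best single parent
#'   (default 0.02).
#' @param abskew parent/candidate abundance ratio (default 2).
#' @return logical vector, one flag per unique sequence.
#' @export
flag_chimeras_denovo <- function(uniques, min_model_id = 0.99,
                                 min_gain = 0.02, abskew = 2) {
  seqs <- uniques$sequence
  ab <- uniques$abundance
  n <- length(seqs)
  flags <- logical(n)
  for (i in seq_len(n)) {
    parents <- which(ab >= abskew * ab[i])
    parents <- setdiff(parents, i)
    if (length(parents) < 2) next
    L <- nchar(seqs[i])
    # per-parent match profile over candidate coordinates
    prof <- match_profiles(seqs[i], seqs[parents])
    pre <- do.call(rbind, map(prof, cumsum))          # parents x L
    tot <- pre[, L]
    suf <- sweep(-pre, 1, tot, "+")                   # matches after pos k
    single_best <- max(tot) / L
    best_pre <- apply(pre, 2, max)
    best_suf <- apply(suf, 2, max)
    model_best <- max(best_pre + best_suf) / L
    if (model_best >= min_model_id &&
        model_best - single_best >= min_gain) {
      flags[i] <- TRUE
    }
  }
  flags
}

# per-position match indicators of `query` against each of `refs`, over
# query coordinates (global alignment; query positions in terminal gaps,
# at mismatches, or aligned against a ref gap score 0).
# One batched alignment call; the slow aligned-string path is used only
# for alignments that contain gaps.
match_profiles <- function(query, refs) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(refs),
    subject = Biostrings::DNAString(query),
    substitutionMatrix = nt_submat(),
    gapOpening = 5, gapExtension = 2, type = "global"
  )
  L <- nchar(query)
  ind <- Biostrings::nindel(pa)
  n_gap <- Biostrings::insertion(ind)[, "WidthSum"] +
    Biostrings::deletion(ind)[, "WidthSum"]
  starts <- Biostrings::start(Biostrings::subject(pa))
  ends <- Biostrings::end(Biostrings::subject(pa))
  mm <- Biostrings::mismatchTable(pa)
  out <- vector("list", length(refs))
  for (i in seq_along(refs)) {
    prof <- integer(L)
    if (n_gap[i] == 0) {
      prof[seq.int(starts[i], ends[i])] <- 1L
      prof[mm$SubjectStart[mm$PatternId == i]] <- 0L
    } else {
      p <- strsplit(as.character(Biostrings::alignedPattern(pa[i])), "")[[1]]
      s <- strsplit(as.character(Biostrings::alignedSubject(pa[i])), "")[[1]]
      qpos <- s != "-"
      prof[seq.int(starts[i], ends[i])] <- as.integer((p == s)[qpos])
    }
    out[[i]] <- prof
  }
  out
}

match_profile <- function(query, ref) match_profiles(query, ref)[[1]]

#' Build a feature table by mapping reads onto features
#'
#' In `"cluster"` mode each read is assigned to the best-identity centroid
#' provided that identity is >= `t`; in `"variant"` mode reads map to their
#' absorbing variant via exact membership (or exact sequence match).
#' Unassigned reads are counted in the `n_unassigned` attribute.
#'
#' @param features a `cluster_set` or `variant_set`.
#' @param reads tibble with `sample` and `sequence` columns (all reads, so
#'   table totals reflect read mass, not unique mass).
#' @param mode `"cluster"` or `"variant"` (defaults to the class of
#'   `features`).
#' @param t assignment identity threshold for cluster mode (defaults to the
#'   clustering threshold).
#' @param prefix feature-id prefix (default derived from mode).
#' @return feature-table tibble: `feature_id`, `sequence`, one integer
#'   count column per sample.
#' @export
build_feature_table <- function(features, reads, mode = NULL, t = NULL,
                                prefix = NULL) {
  mode <- mode %||% if (inherits(features, "variant_set")) "variant" else "cluster"
  reps <- if (mode == "variant") features$variants$sequence else features$centroids
  prefix <- prefix %||% if (mode == "variant") "ASV" else
    sprintf("OTU%02d", round(100 * features$threshold))
  member_map <- if (mode == "variant") {
    setNames(features$members$variant, features$members$sequence)
  } else {
    setNames(features$members$centroid, features$members$sequence)
  }
  uniq <- unique(reads$sequence)
  target <- member_map[uniq]
  todo <- which(is.na(target))
  if (mode == "cluster" && length(todo) > 0) {
    t <- t %||% features$threshold
    screen_top <- min(4L, length(reps))
    Kq <- kmer_counts(uniq[todo])
    Kr <- kmer_counts(reps)
    sims <- Kq %*% t(Kr)
    cand <- map(seq_along(todo), function(u)
      head(order(-sims[u, ]), screen_top))
    ids_best <- rep(-1, length(todo))
    ids_bestj <- rep(NA_integer_, length(todo))
    for (j in seq_along(reps)) {
      qs <- which(map_lgl(cand, function(x) j %in% x))
      if (length(qs) == 0) next
      ids <- identity_to_refs(reps[j], uniq[todo[qs]])
      upd <- ids > ids_best[qs] + 1e-12
      ids_best[qs[upd]] <- ids[upd]
      ids_bestj[qs[upd]] <- j
    }
    hit <- ids_best >= t
    target[todo[hit]] <- reps[ids_bestj[hit]]
  } else {
    # variant mode: unseen sequences stay unassigned (exact-match contract)
  }
  names(target) <- uniq
  assigned <- target[reads$sequence]
  n_unassigned <- sum(is.na(assigned))
  ids <- setNames(sprintf("%s_%04d", prefix, seq_along(reps)), reps)
  tab <- tibble(sample = reads$sample, feature = assigned) |>
    filter(!is.na(.data$feature)) |>
    count(.data$feature, .data$sample) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "n",
                       values_fill = 0L)
  # keep every feature (even zero-count) and representative order
  out <- tibble(feature_id = unname(ids), sequence = reps)
  out <- left_join(out, tab |> rename(sequence = "feature"),
                   by = "sequence")
  sample_cols <- setdiff(names(out), c("feature_id", "sequence"))
  for (sc in sample_cols) out[[sc]][is.na(out[[sc]])] <- 0L
  missing_samples <- setdiff(unique(reads$sample), sample_cols)
  for (sc in missing_samples) out[[sc]] <- 0L
  out <- out[, c("feature_id", "sequence",
                 sort(c(sample_cols, missing_samples)))]
  attr(out, "n_unassigned") <- n_unassigned
  out
}
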