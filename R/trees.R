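# Phylogenetic machinery: a deterministic neighbor-joining implementation,
# UniFrac (unweighted / weighted, optionally normalized), Robinson-Foulds
# bipartition distances, and the incremental tree-congruence procedure that
# compares two reconstruction methods on reference-anchored trees.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining with two determinism guarantees:
#' ties in the Q criterion are broken by label order (smallest row, then
#' column, in the input ordering), and negative branch estimates are
#' clamped to zero with the deficit transferred to the sibling branch so
#' the pair's path length is preserved. Additive matrices are recovered
#' exactly (topology and branch lengths).
#'
#' @param D symmetric zero-diagonal distance matrix with >= 3 labelled
#'   rows/columns.
#' @return unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) abort("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) abort("need at least three labels")
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  # working set: Newick fragment and pending branch length for each node
  node <- labs
  D <- unname(D)
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # deterministic tie-break: among minimal Q, smallest row then column
    ut <- which(upper.tri(Q), arr.ind = TRUE)
    qv <- Q[ut]
    cand <- ut[qv <= min(qv) + 1e-12, , drop = FALSE]
    ord <- order(cand[, 1], cand[, 2])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    merged <- sprintf("(%s:%.15g,%s:%.15g)", node[i], bi, node[j], bj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], merged)
    D <- D2
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- D[1, 2] - b1
  b3 <- D[1, 3] - b1
  b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 node[1], b1, node[2], b2, node[3], b3)
  ape::read.tree(text = nwk)
}

# per-edge descendant tip index sets, via one postorder pass
edge_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  list(tree = tree, sets = sets)
}

#' UniFrac distance between two samples on a tree
#'
#' Unweighted UniFrac is the fraction of branch length unique to one
#' sample among branch length covered by either. Weighted UniFrac is
#' `sum_b l_b |A_b - B_b|` with `A_b` the fraction of sample a's reads
#' descending from branch b; the normalized form divides by
#' `sum_b l_b (A_b + B_b)` so results lie in \[0, 1\]. Computed on the
#' rooted representation of the `phylo` object.
#'
#' @param tree `ape::phylo` whose tips cover every feature with positive
#'   counts.
#' @param counts_a,counts_b named count vectors (names = tip labels).
#' @param weighted abundance-weighted variant (default `FALSE`).
#' @param normalized divide the weighted form by its maximum (default
#'   `TRUE`; ignored for unweighted).
#' @return single distance.
#' @export
unifrac <- function(tree, counts_a, counts_b, weighted = FALSE,
                    normalized = TRUE) {
  for (cnt in list(counts_a, counts_b)) {
    missing <- setdiff(names(cnt)[cnt > 0], tree$tip.label)
    if (length(missing) > 0) {
      abort(sprintf("features absent from tree: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  et <- edge_tip_sets(tree)
  tr <- et$tree
  a <- setNames(rep(0, length(tr$tip.label)), tr$tip.label)
  b <- a
  a[names(counts_a)] <- counts_a
  b[names(counts_b)] <- counts_b
  ta <- sum(a); tb <- sum(b)
  if (ta <= 0 || tb <= 0) abort("each sample needs positive total count")
  lens <- tr$edge.length
  A <- map_dbl(seq_len(nrow(tr$edge)), function(k)
    sum(a[et$sets[[tr$edge[k, 2]]]]) / ta)
  B <- map_dbl(seq_len(nrow(tr$edge)), function(k)
    sum(b[et$sets[[tr$edge[k, 2]]]]) / tb)
  if (!weighted) {
    in_a <- A > 0; in_b <- B > 0
    denom <- sum(lens[in_a | in_b])
    if (denom == 0) return(0)
    sum(lens[xor(in_a, in_b)]) / denom
  } else {
    raw <- sum(lens * abs(A - B))
    if (!normalized) return(raw)
    denom <- sum(lens * (A + B))
    if (denom == 0) return(0)
    raw / denom
  }
}

#' UniFrac distance matrix over all samples of a feature table
#'
#' @param table feature table tibble; features are matched to tree tips by
#'   `feature_id`.
#' @param tree `ape::phylo` over the feature ids.
#' @inheritParams unifrac
#' @return symmetric zero-diagonal matrix over samples.
#' @export
unifrac_matrix <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  m <- feature_counts(table)
  samples <- colnames(m)
  D <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (i in seq_along(samples)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- unifrac(tree, m[, i], m[, j],
                                    weighted = weighted,
                                    normalized = normalized)
    }
  }
  D
}

# non-trivial bipartitions of an unrooted tree, canonically keyed:
# each split is represented by the side not containing the reference tip
# (lexicographically smallest label), sorted and pasted
tree_splits <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  et <- edge_tip_sets(tree)
  tr <- et$tree
  n_tip <- length(labs)
  keys <- character(0)
  for (k in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[k, 2]
    if (ch <= n_tip) next                    # trivial: single tip
    side <- tr$tip.label[et$sets[[ch]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n_tip - 2) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric difference of the trees' non-trivial bipartitions, with
#' the normalized form dividing by the total number of non-trivial
#' bipartitions in both trees (in \[0, 1\] for any input, binary or not).
#' `"strict"` mode requires identical tip sets; `"prune-to-shared"` first
#' restricts both trees to their shared tips (>= 4 required).
#'
#' @param t1,t2 `ape::phylo` trees.
#' @param mode `"strict"` or `"prune-to-shared"`.
#' @return list with `rf` (integer) and `rf_norm`.
#' @export
robinson_foulds <- function(t1, t2, mode = c("strict", "prune-to-shared")) {
  mode <- match.arg(mode)
  if (mode == "strict") {
    if (!setequal(t1$tip.label, t2$tip.label)) {
      abort("strict mode requires identical tip label sets")
    }
  } else {
    shared <- intersect(t1$tip.label, t2$tip.label)
    if (length(shared) < 4) abort("fewer than 4 shared tips")
    t1 <- ape::keep.tip(t1, shared)
    t2 <- ape::keep.tip(t2, shared)
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  denom <- length(s1) + length(s2)
  list(rf = rf, rf_norm = if (denom == 0) 0 else rf / denom)
}

#' Incremental congruence curve between two feature sets
#'
#' Reproduces the incremental comparison procedure: at step i, a
#' neighbor-joining tree is built over the reference sequences plus the
#' top-i most-abundant features of each method; the two trees are then
#' compared by normalized Robinson-Foulds distance on the shared reference
#' tips (added features are pruned, since feature labels differ between
#' methods). The curve stops at `min(|A|, |B|, max_iter)` - mirroring the
#' cap set by the smaller abundance table.
#'
#' @param features_a,features_b tibbles with `feature_id`, `sequence`,
#'   `abundance`, sorted by decreasing abundance.
#' @param reference_seqs named character vector (>= 4) of anchor sequences.
#' @param max_iter iteration cap (default `Inf`).
#' @return tibble of class `congruence_curve`: `n_added`, `rf_norm`.
#' @export
incremental_congruence <- function(features_a, features_b, reference_seqs,
                                   max_iter = Inf) {
  if (length(reference_seqs) < 4) abort("need at least 4 reference sequences")
  n_steps <- min(nrow(features_a), nrow(features_b), max_iter)
  ref_names <- names(reference_seqs)
  seqs_a <- c(reference_seqs,
              setNames(features_a$sequence[seq_len(n_steps)],
                       paste0("A_", features_a$feature_id[seq_len(n_steps)])))
  seqs_b <- c(reference_seqs,
              setNames(features_b$sequence[seq_len(n_steps)],
                       paste0("B_", features_b$feature_id[seq_len(n_steps)])))
  Da <- nt_distance_matrix(seqs_a)
  Db <- nt_distance_matrix(seqs_b)
  curve <- map(seq_len(n_steps), function(i) {
    ia <- c(ref_names, names(seqs_a)[length(ref_names) + seq_len(i)])
    ib <- c(ref_names, names(seqs_b)[length(ref_names) + seq_len(i)])
    ta <- nj_tree(Da[ia, ia])
    tb <- nj_tree(Db[ib, ib])
    # shared tips are exactly the references (feature labels differ by method)
    tibble(n_added = i,
           rf_norm = robinson_foulds(ta, tb,
                                     mode = "prune-to-shared")$rf_norm)
  })
  out <- bind_rows(curve)
  class(out) <- c("congruence_curve", class(out))
  out
}

#' Fit a logarithmic trend to a congruence curve
#'
#' Ordinary least squares of `rf_norm` on `ln(n_added)`:
#' `rf = a ln(n) + b`.
#'
#' @param curve tibble with `n_added` and `rf_norm` (>= 2 distinct n).
#' @return object of class `log_fit` with `a`, `b`, `rmse`.
#' @export
fit_log_curve <- function(curve) {
  if (length(unique(curve$n_added)) < 2) {
    abort("need at least two distinct n_added values")
  }
  fit <- lm(rf_norm ~ log(n_added), data = curve)
  res <- stats::residuals(fit)
  structure(
    list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
         rmse = sqrt(mean(res^2)), n_points = nrow(curve)),
    class = "log_fit"
  )
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("<log_fit> rf = %.4f ln(n) + %.4f (rmse %.4g, %d points)\n",
              x$a, x$b, x$rmse, x$n_points))
  invisible(x)
}
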