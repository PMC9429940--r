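# Alpha diversity with rarefaction and the distance matrices feeding the
# beta-diversity layer. Rarefaction draws and the analytic richness
# expectation are delegated to vegan (rrarefy / rarefy); Shannon and
# Gini-Simpson to vegan::diversity; Bray-Curtis to vegan::vegdist.

#' Rarefy sample counts to a fixed depth
#'
#' One multivariate-hypergeometric draw (subsampling without replacement)
#' per sample, summing exactly to `depth`. Samples with fewer than `depth`
#' reads are not an error: they are flagged excluded and dropped from the
#' rarefied table.
#'
#' @param table feature table tibble (`feature_id`, `sequence`, sample
#'   count columns).
#' @param depth rarefaction depth (default 10000).
#' @param seed integer seed for the draw.
#' @return list with `rarefied` (feature table at depth) and `excluded`
#'   (character vector of sample ids under depth).
#' @export
rarefy_counts <- function(table, depth = 10000, seed = 1) {
  stopifnot(depth >= 1)
  m <- t(feature_counts(table))          # samples x features for vegan
  totals <- rowSums(m)
  excluded <- rownames(m)[totals < depth]
  kept <- rownames(m)[totals >= depth]
  set.seed(seed)
  out <- table[, c("feature_id", "sequence")]
  for (s in kept) {
    # explicit 1 x n_features shape: rrarefy treats rows as samples
    row <- matrix(m[s, ], nrow = 1)
    out[[s]] <- as.integer(suppressWarnings(vegan::rrarefy(row, depth))[1, ])
  }
  list(rarefied = out, excluded = excluded)
}

#' Analytic expected richness under rarefaction
#'
#' The hypergeometric expectation
#' `E[S] = sum_i (1 - choose(N - N_i, d) / choose(N, d))`, computed by
#' `vegan::rarefy`; monotone non-decreasing in depth.
#'
#' @param counts non-negative integer count vector for one sample.
#' @param depth subsample depth `d <= N`.
#' @return expected number of features observed in a depth-`d` subsample.
#' @export
expected_richness <- function(counts, depth) {
  N <- sum(counts)
  if (depth > N) abort("depth exceeds sample total")
  as.numeric(suppressWarnings(vegan::rarefy(counts, depth)))
}

#' Shannon entropy (nats) of a count vector
#'
#' `H = -sum p_i ln p_i` with `0 ln 0 := 0`.
#' @param counts count vector with at least one positive entry.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) abort("all-zero sample")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Gini-Simpson diversity of a count vector
#'
#' `1 - sum p_i^2`, in \[0, 1\].
#' @param counts count vector with at least one positive entry.
#' @export
simpson <- function(counts) {
  if (sum(counts) <= 0) abort("all-zero sample")
  as.numeric(vegan::diversity(counts, index = "simpson"))
}

#' Alpha-diversity table for all samples
#'
#' Richness is the analytic rarefaction expectation at `depth` (capped at
#' the sample total); Shannon and Gini-Simpson are computed on one seeded
#' rarefied draw at `depth` (samples under depth are excluded).
#'
#' @param table feature table tibble.
#' @param depth rarefaction depth (default 10000).
#' @param seed seed for the Shannon/Simpson rarefied draw.
#' @return tibble: sample, richness, shannon, simpson.
#' @export
alpha_diversity <- function(table, depth = 10000, seed = 1) {
  rar <- rarefy_counts(table, depth, seed)
  m <- feature_counts(rar$rarefied)
  tibble(
    sample = colnames(m),
    richness = map_dbl(seq_len(ncol(m)), function(j)
      expected_richness(m[, j], min(depth, sum(m[, j])))),
    shannon = map_dbl(seq_len(ncol(m)), function(j) shannon(m[, j])),
    simpson = map_dbl(seq_len(ncol(m)), function(j) simpson(m[, j]))
  )
}

#' Rarefaction curve of expected richness over a depth grid
#'
#' Computes [expected_richness()] at each grid depth. When `groups` is
#' given, per-group curves are computed on the group-averaged table
#' (mean abundance of each feature across the group's samples).
#'
#' @param table feature table tibble.
#' @param depths integer vector of depths.
#' @param groups optional named vector mapping sample id to group.
#' @return tibble: group (or sample), depth, expected_richness.
#' @export
rarefaction_curve <- function(table, depths, groups = NULL) {
  m <- feature_counts(table)
  units <- if (is.null(groups)) {
    setNames(map(colnames(m), function(s) m[, s]), colnames(m))
  } else {
    gs <- split(colnames(m), groups[colnames(m)])
    map(gs, function(ss) round(rowMeans(m[, ss, drop = FALSE])))
  }
  bind_rows(imap(units, function(cnt, nm) {
    d <- depths[depths <= sum(cnt)]
    tibble(group = nm, depth = d,
           expected_richness = map_dbl(d, function(x) expected_richness(cnt, x)))
  }))
}

#' Bray-Curtis distance matrix between samples
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, via `vegan::vegdist`.
#'
#' @param table feature table tibble (>= 2 samples).
#' @return symmetric zero-diagonal matrix with sample labels.
#' @export
bray_curtis <- function(table) {
  m <- t(feature_counts(table))
  if (nrow(m) < 2) abort("need at least two samples")
  if (any(rowSums(m) == 0)) abort("all-zero sample: Bray-Curtis undefined")
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Jukes-Cantor distance matrix between sequences
#'
#' p-distances come from [pairwise_identity()] (global alignment, terminal
#' gaps excluded); the JC69 correction `d = -(3/4) ln(1 - 4p/3)` is applied,
#' with p >= 0.749 capped at `max_dist`.
#'
#' @param seqs named character vector of nucleotide sequences (>= 3).
#' @param max_dist distance assigned to saturated pairs (default 5).
#' @return symmetric zero-diagonal matrix over sequence names.
#' @export
nt_distance_matrix <- function(seqs, max_dist = 5) {
  n <- length(seqs)
  if (n < 3) abort("need at least three sequences")
  labs <- names(seqs) %||% paste0("s", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    ids <- identity_to_refs(seqs[i], seqs[(i + 1):n])
    p <- 1 - ids
    d <- ifelse(p >= 0.749, max_dist, -0.75 * log(1 - 4 * p / 3))
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  D
}
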