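# Shared fixtures and independent oracles. Oracles are deliberately written
# with different mechanisms than the package code they check.

random_dna <- function(n, len = 60) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
}

# --- independent affine-gap global alignment score (three-state DP) -------
# match +2, mismatch -3, gap of length L costs open + L * extend, terminal
# gaps penalised (true global). Score is unique even when alignments tie.
oracle_global_score <- function(a, b, match = 2, mismatch = -3,
                                open = 5, extend = 2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in y (x consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in x (y consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- literal diversity formulas ------------------------------------------
oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}
oracle_simpson <- function(counts) {
  p <- counts / sum(counts)
  1 - sum(p^2)
}
oracle_expected_richness <- function(counts, d) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
}

# --- brute-force UniFrac via per-branch descendant enumeration ------------
# walks root-to-tip node paths (ape::nodepath) instead of the package's
# postorder accumulation
oracle_unifrac <- function(tree, ca, cb, weighted = FALSE,
                           normalized = TRUE) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  a <- setNames(rep(0, n_tip), tree$tip.label); a[names(ca)] <- ca
  b <- setNames(rep(0, n_tip), tree$tip.label); b[names(cb)] <- cb
  desc <- lapply(seq_len(nrow(tree$edge)), function(k) {
    child <- tree$edge[k, 2]
    tips <- which(vapply(seq_len(n_tip), function(tp) {
      child %in% ape::nodepath(tree, root, tp)
    }, logical(1)))
    tree$tip.label[tips]
  })
  lens <- tree$edge.length
  A <- vapply(desc, function(d) sum(a[d]) / sum(a), numeric(1))
  B <- vapply(desc, function(d) sum(b[d]) / sum(b), numeric(1))
  if (!weighted) {
    shared <- (A > 0) | (B > 0)
    sum(lens[xor(A > 0, B > 0)]) / sum(lens[shared])
  } else {
    raw <- sum(lens * abs(A - B))
    if (!normalized) raw else raw / sum(lens * (A + B))
  }
}

# --- subset-enumeration Robinson-Foulds oracle ----------------------------
# a tip subset S is a bipartition iff every path from S to its complement
# shares at least one common edge
oracle_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  tipno <- match(labs, tree$tip.label)
  edge_key <- function(np) {       # node path -> edge id strings
    vapply(seq_len(length(np) - 1L), function(i)
      paste(sort(c(np[i], np[i + 1])), collapse = "-"), character(1))
  }
  out <- character(0)
  for (mask in 1:(2^n - 2)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) < 2 || length(S) > n - 2) next
    if (!(1 %in% S)) next          # canonical: side without first label
    Sc <- setdiff(seq_len(n), S)
    common <- NULL
    ok <- TRUE
    for (i in S) {
      for (j in Sc) {
        ek <- edge_key(ape::nodepath(tree, tipno[i], tipno[j]))
        common <- if (is.null(common)) ek else intersect(common, ek)
        if (length(common) == 0) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) out <- c(out, paste(labs[Sc], collapse = "|"))
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  list(rf = rf, denom = length(s1) + length(s2))
}

# --- small community fixtures --------------------------------------------
# one gene + taxa + a two-group design with a planted effect
small_community <- function(seed = 1, n_taxa = 8, aa_length = 60,
                            target_identity = 0.93, effect_fold = 4,
                            effect_frac = 0.25, n_replicates = 3) {
  panel <- make_reference_panel(1, aa_length, seed = seed)
  taxa <- derive_taxa(panel[1, ], n_taxa, target_identity, seed = seed + 1)
  design <- assign_abundances(taxa, 2, n_replicates, effect_fold,
                              effect_frac, seed = seed + 2)
  list(panel = panel, gene = panel[1, ], taxa = taxa, design = design)
}

# plant a single-base indel in the middle 20% of a sequence (frameshift);
# "del" keeps the translated length away from the expected value, so the
# planted truth stays unambiguous for the QC decision tree
plant_frameshift <- function(seq, seed = 1, type = c("either", "del", "ins")) {
  type <- match.arg(type)
  set.seed(seed)
  x <- strsplit(seq, "")[[1]]
  p <- sample(seq.int(floor(0.4 * length(x)), ceiling(0.6 * length(x))), 1)
  del <- switch(type, del = TRUE, ins = FALSE, either = runif(1) < 0.5)
  if (del) x <- x[-p] else
    x <- append(x, sample(c("A", "C", "G", "T"), 1), after = p)
  paste(x, collapse = "")
}

# frameshift by two single-base deletions, one per half, so that no
# reading frame retains a verifiable enzyme fragment (the planted truth
# stays unambiguous even under lenient identity/coverage cutoffs)
plant_double_del <- function(seq, seed = 1) {
  set.seed(seed)
  L <- nchar(seq)
  p1 <- sample(seq.int(floor(0.30 * L), ceiling(0.40 * L)), 1)
  p2 <- sample(seq.int(floor(0.60 * L), ceiling(0.70 * L)), 1)
  x <- strsplit(seq, "")[[1]][-c(p1, p2)]
  paste(x, collapse = "")
}

# mutate one codon (within the middle of the ORF) into a stop codon
plant_stop <- function(seq, seed = 1) {
  set.seed(seed)
  n_codon <- nchar(seq) %/% 3L
  ci <- sample(seq.int(ceiling(0.3 * n_codon), floor(0.7 * n_codon)), 1)
  paste0(substring(seq, 1, 3 * (ci - 1)), "TAA",
         substring(seq, 3 * ci + 1, nchar(seq)))
}

# reference DB for the lowest-common-ancestor worked examples
nitrosomonas_db <- function(seed = 42) {
  set.seed(seed)
  base <- random_dna(1, 120)
  mut <- function(s, k) {
    x <- strsplit(s, "")[[1]]
    pos <- sample(length(x), k)
    for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
    paste(x, collapse = "")
  }
  lin <- function(sp) sprintf(
    "Bacteria;Proteobacteria;Betaproteobacteria;Nitrosomonadales;Nitrosomonadaceae;Nitrosomonas;%s", sp)
  reference_db(
    ids = c("eur1", "eur2", "oli1", "out1"),
    sequences = c(mut(base, 1), mut(base, 2), mut(base, 8), mut(base, 40)),
    lineages = c(lin("Nitrosomonas europaea"), lin("Nitrosomonas europaea"),
                 lin("Nitrosomonas oligotropha"),
                 "Bacteria;Proteobacteria;Gammaproteobacteria;Chromatiales;Ectothiorhodospiraceae;Nitrosococcus;Nitrosococcus oceani")
  )
}

# random tip abundances (with zeros) for UniFrac checks
random_counts <- function(tree, zero_frac = 0.3) {
  n <- length(tree$tip.label)
  v <- rpois(n, 10) + 1
  v[runif(n) < zero_frac] <- 0
  if (all(v == 0)) v[1] <- 5
  setNames(v, tree$tip.label)
}

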