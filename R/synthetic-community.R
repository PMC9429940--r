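# Synthetic functional-gene amplicon communities with known ground truth.
# The generator emulates a two-group (e.g. ridge vs runnel sediment) design:
# coding reference genes, taxa derived at controlled identity, a planted
# fold-change on a subset of taxa in group 2, per-base substitution/indel
# errors, single-breakpoint chimeras, and optionally paired reads with
# Phred+33 quality strings.

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))

#' Build a panel of synthetic coding gene models
#'
#' Each gene is a stop-free coding sequence of `3 * aa_length` nt in frame 0,
#' with random primer sequences attached as metadata. Stands in for a set of
#' real functional-gene amplicons (e.g. the nitrogen-cycle genes amoA, nxrB,
#' nirS, nirK, nrfA).
#'
#' @param n_genes number of gene models (>= 1).
#' @param aa_length protein length in residues (>= 10).
#' @param seed integer seed; the panel is byte-identical for equal seeds.
#' @return tibble with columns `name`, `coding_seq`, `frame_offset`,
#'   `primer_fwd`, `primer_rev`, `amplicon_len_nt`, `protein`.
#' @export
make_reference_panel <- function(n_genes, aa_length, seed) {
  if (n_genes < 1 || aa_length < 10) {
    abort("need n_genes >= 1 and aa_length >= 10")
  }
  set.seed(seed)
  genes <- map(seq_len(n_genes), function(i) {
    cds <- paste(sample(NON_STOP_CODONS, aa_length, replace = TRUE),
                 collapse = "")
    tibble(
      name = sprintf("gene%02d", i),
      coding_seq = cds,
      frame_offset = 0L,
      primer_fwd = paste(sample(c("A", "C", "G", "T"), 19, TRUE), collapse = ""),
      primer_rev = paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
      amplicon_len_nt = 3L * aa_length,
      protein = translate_frame(cds)
    )
  })
  bind_rows(genes)
}

#' Derive taxa from a reference gene at a target identity
#'
#' Substitution-only divergence. In frame-preserving mode substitutions are
#' placed at third codon positions and never create a stop codon, so every
#' taxon translates cleanly; in frame-breaking mode positions are uniform and
#' stops may arise. Realised identity to the reference is exactly
#' `1 - round((1 - target_identity) * L) / L` (no indels), hence within 0.01
#' of the target for any amplicon length >= 100 nt.
#'
#' @param gene one row of [make_reference_panel()].
#' @param n_taxa number of taxa to derive.
#' @param target_identity in (0, 1].
#' @param seed integer seed.
#' @param frame_preserving place substitutions at third codon positions and
#'   forbid stop-creating changes (default `TRUE`).
#' @return tibble with columns `taxon_id`, `sequence`.
#' @export
derive_taxa <- function(gene, n_taxa, target_identity, seed,
                        frame_preserving = TRUE) {
  stopifnot(target_identity > 0, target_identity <= 1, n_taxa >= 1)
  cds <- gene$coding_seq[[1]]
  L <- nchar(cds)
  n_sub <- round((1 - target_identity) * L)
  sites_pool <- if (frame_preserving) seq(3L, L, by = 3L) else seq_len(L)
  if (n_sub > length(sites_pool)) {
    abort(sprintf("target identity %.3f unreachable: needs %d substitutions but only %d eligible sites",
                  target_identity, n_sub, length(sites_pool)))
  }
  set.seed(seed)
  base <- strsplit(cds, "", fixed = TRUE)[[1]]
  taxa <- map_chr(seq_len(n_taxa), function(i) {
    x <- base
    if (n_sub > 0) {
      sites <- sample(sites_pool, n_sub)
      for (p in sites) {
        alts <- setdiff(c("A", "C", "G", "T"), x[p])
        if (frame_preserving) {
          cstart <- p - (p - 1L) %% 3L
          ok <- vapply(alts, function(a) {
            cd <- x[cstart:(cstart + 2L)]
            cd[p - cstart + 1L] <- a
            !(paste(cd, collapse = "") %in% STOP_CODONS)
          }, logical(1))
          alts <- alts[ok]
        }
        x[p] <- sample(alts, 1L)
      }
    }
    paste(x, collapse = "")
  })
  tibble(
    taxon_id = sprintf("%s_t%03d", gene$name[[1]], seq_len(n_taxa)),
    sequence = taxa
  )
}

#' Plant a two-group abundance design over a set of taxa
#'
#' A lognormal base profile is drawn and normalised; in group 2 a random
#' fraction `effect_frac` of taxa is multiplied by `effect_fold` and the
#' profile renormalised. Groups beyond 2 reuse the base profile.
#'
#' @param taxa tibble from [derive_taxa()] (columns `taxon_id`, `sequence`).
#' @param n_groups,n_replicates experimental layout (samples = groups x reps).
#' @param effect_fold fold change planted in group 2 (> 0; 1 = no effect).
#' @param effect_frac fraction of taxa carrying the effect, in \[0, 1\].
#' @param lognormal_sigma sd of the log-abundance draw (default 1).
#' @param seed integer seed.
#' @return object of class `community_design`: list with `taxa`, `profiles`
#'   (taxa x groups matrix, columns summing to 1), `effect_taxa`,
#'   `effect_fold`, `n_groups`, `n_replicates`.
#' @export
assign_abundances <- function(taxa, n_groups = 2, n_replicates = 3,
                              effect_fold = 1, effect_frac = 0,
                              lognormal_sigma = 1, seed = 1) {
  stopifnot(effect_fold > 0, effect_frac >= 0, effect_frac <= 1)
  set.seed(seed)
  k <- nrow(taxa)
  base <- rlnorm(k, 0, lognormal_sigma)
  base <- base / sum(base)
  n_eff <- ceiling(effect_frac * k)
  effect_taxa <- if (n_eff > 0) sort(sample(k, n_eff)) else integer(0)
  profiles <- matrix(base, nrow = k, ncol = n_groups)
  if (n_groups >= 2 && length(effect_taxa) > 0) {
    g2 <- base
    g2[effect_taxa] <- g2[effect_taxa] * effect_fold
    profiles[, 2] <- g2 / sum(g2)
  }
  rownames(profiles) <- taxa$taxon_id
  colnames(profiles) <- paste0("g", seq_len(n_groups))
  structure(
    list(taxa = taxa, profiles = profiles,
         effect_taxa = taxa$taxon_id[effect_taxa],
         effect_fold = effect_fold,
         n_groups = n_groups, n_replicates = n_replicates),
    class = "community_design"
  )
}

#' @export
print.community_design <- function(x, ...) {
  cat(sprintf("<community_design> %d taxa, %d groups x %d replicates, effect %gx on %d taxa\n",
              nrow(x$taxa), x$n_groups, x$n_replicates, x$effect_fold,
              length(x$effect_taxa)))
  invisible(x)
}

#' Error model for amplicon simulation
#'
#' @param sub_rate,indel_rate per-base probabilities in \[0, 1\].
#' @param chimera_fraction per-read probability of a single-breakpoint
#'   chimera, in \[0, 1\].
#' @export
error_model <- function(sub_rate = 0, indel_rate = 0, chimera_fraction = 0) {
  rates <- c(sub_rate, indel_rate, chimera_fraction)
  if (any(rates < 0 | rates > 1)) abort("all rates must be in [0, 1]")
  list(sub_rate = sub_rate, indel_rate = indel_rate,
       chimera_fraction = chimera_fraction)
}

mutate_read <- function(seq, sub_rate, indel_rate) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(x)
  n_sub <- stats::rbinom(1, L, sub_rate)
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub)
    x[pos] <- vapply(x[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
  }
  n_indel <- stats::rbinom(1, L, indel_rate)
  shift <- 0L
  if (n_indel > 0) {
    for (j in seq_len(n_indel)) {
      p <- sample.int(length(x), 1)
      if (runif(1) < 0.5) {
        x <- append(x, sample(c("A", "C", "G", "T"), 1), after = p)
        shift <- shift + 1L
      } else {
        x <- x[-p]
        shift <- shift - 1L
      }
    }
  }
  list(seq = paste(x, collapse = ""), n_sub = n_sub, n_indel = n_indel,
       shift = shift)
}

#' Simulate amplicon reads from a community design
#'
#' Reads are drawn multinomially per sample from that sample's group profile;
#' per-base substitutions and single-base indels are applied; with
#' probability `chimera_fraction` a read is instead a single-breakpoint join
#' of two profile-sampled parents (breakpoint uniform in the middle 60% of
#' the amplicon). Paired mode emits overlapping forward/reverse reads with
#' Phred+33 quality strings (constant Q37 with an optional linear 3' decay).
#'
#' @param design a `community_design`.
#' @param n_reads_per_sample reads per sample (>= 1).
#' @param err an [error_model()].
#' @param seed integer seed.
#' @param paired emit forward/reverse pairs instead of full amplicons.
#' @param read_len paired-read length; default gives ~50 bp overlap.
#' @param qual_decay drop in Phred score from 5' to 3' end (default 0).
#' @return list with `reads` (tibble: sample, group, read_id, sequence and,
#'   if paired, fwd/rev sequence + quality) and `truth` (one row per read:
#'   source taxon or chimera parents + breakpoint, error counts, frame flag).
#' @export
simulate_amplicons <- function(design, n_reads_per_sample, err = error_model(),
                               seed = 1, paired = FALSE, read_len = NULL,
                               qual_decay = 0) {
  stopifnot(inherits(design, "community_design"), n_reads_per_sample >= 1)
  if (nrow(design$taxa) == 0) abort("empty community design")
  set.seed(seed)
  taxa <- design$taxa
  L <- nchar(taxa$sequence[[1]])
  samples <- expand.grid(rep = seq_len(design$n_replicates),
                         group = seq_len(design$n_groups))
  out_reads <- vector("list", nrow(samples))
  out_truth <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    g <- samples$group[si]
    sample_id <- sprintf("g%d_r%d", g, samples$rep[si])
    prof <- design$profiles[, g]
    counts <- as.vector(rmultinom(1, n_reads_per_sample, prof))
    src <- rep(seq_len(nrow(taxa)), counts)
    n <- length(src)
    is_chim <- runif(n) < err$chimera_fraction
    rec <- vector("list", n)
    for (i in seq_len(n)) {
      if (is_chim[i]) {
        parents <- sample(seq_len(nrow(taxa)), 2, replace = FALSE, prob = prof)
        bp <- sample(seq.int(as.integer(0.2 * L), as.integer(0.8 * L)), 1)
        raw <- paste0(substring(taxa$sequence[parents[1]], 1, bp),
                      substring(taxa$sequence[parents[2]], bp + 1, L))
        m <- mutate_read(raw, err$sub_rate, err$indel_rate)
        rec[[i]] <- list(seq = m$seq, taxon = NA_character_,
                         parent1 = taxa$taxon_id[parents[1]],
                         parent2 = taxa$taxon_id[parents[2]],
                         breakpoint = bp, n_sub = m$n_sub,
                         n_indel = m$n_indel, shift = m$shift,
                         chimera = TRUE)
      } else {
        m <- mutate_read(taxa$sequence[src[i]], err$sub_rate, err$indel_rate)
        rec[[i]] <- list(seq = m$seq, taxon = taxa$taxon_id[src[i]],
                         parent1 = NA_character_, parent2 = NA_character_,
                         breakpoint = NA_integer_, n_sub = m$n_sub,
                         n_indel = m$n_indel, shift = m$shift,
                         chimera = FALSE)
      }
    }
    seqs <- map_chr(rec, "seq")
    read_id <- sprintf("%s_read%05d", sample_id, seq_len(n))
    reads <- tibble(sample = sample_id, group = paste0("g", g),
                    read_id = read_id, sequence = seqs)
    if (paired) {
      rl <- read_len %||% (floor(L / 2) + 25L)
      lens <- nchar(seqs)
      rl_i <- pmin(rl, lens)
      q <- map_chr(rl_i, function(k) phred_string(k, 37, qual_decay))
      reads$fwd_seq <- substring(seqs, 1, rl_i)
      reads$fwd_qual <- q
      reads$rev_seq <- revcomp(substring(seqs, pmax(1, lens - rl_i + 1), lens))
      reads$rev_qual <- q
    }
    out_reads[[si]] <- reads
    out_truth[[si]] <- tibble(
      sample = sample_id, read_id = read_id,
      taxon = map_chr(rec, "taxon"),
      parent1 = map_chr(rec, "parent1"), parent2 = map_chr(rec, "parent2"),
      breakpoint = map_int(rec, "breakpoint"),
      n_sub = map_int(rec, "n_sub"), n_indel = map_int(rec, "n_indel"),
      chimera = map_lgl(rec, "chimera"),
      frame_intact = !map_lgl(rec, "chimera") &
        map_int(rec, "shift") %% 3L == 0L
    )
  }
  list(reads = bind_rows(out_reads), truth = bind_rows(out_truth))
}

phred_string <- function(len, q0 = 37, decay = 0) {
  q <- pmax(2, round(q0 - decay * (seq_len(len) - 1) / max(1, len - 1)))
  intToUtf8(q + 33L)
}

phred_values <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' Write a simulated data set to disk as plain-text fixture files
#'
#' One FASTA (or FASTQ pair, in paired mode) per sample, a TSV truth table
#' and a JSON design file. [read_fixture()] round-trips the result.
#'
#' @param sim result of [simulate_amplicons()].
#' @param design the `community_design` used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paired <- "fwd_seq" %in% names(sim$reads)
  for (s in unique(sim$reads$sample)) {
    rs <- sim$reads[sim$reads$sample == s, ]
    if (paired) {
      write_fastq(rs$read_id, rs$fwd_seq, rs$fwd_qual,
                  file.path(dir, paste0(s, "_R1.fastq")))
      write_fastq(rs$read_id, rs$rev_seq, rs$rev_qual,
                  file.path(dir, paste0(s, "_R2.fastq")))
    } else {
      write_fasta(rs$read_id, rs$sequence, file.path(dir, paste0(s, ".fasta")))
    }
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(
    list(taxa = design$taxa, profiles = as.data.frame(design$profiles),
         effect_taxa = design$effect_taxa, effect_fold = design$effect_fold,
         n_groups = design$n_groups, n_replicates = design$n_replicates),
    file.path(dir, "design.json"), digits = NA
  )
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `reads`, `truth`, `design` (taxa + profile tables).
#' @export
read_fixture <- function(dir) {
  fastas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  fastqs <- list.files(dir, pattern = "_R1\\.fastq$", full.names = TRUE)
  reads <- if (length(fastas) > 0) {
    bind_rows(map(fastas, function(f) {
      x <- Biostrings::readDNAStringSet(f)
      tibble(sample = sub("\\.fasta$", "", basename(f)),
             read_id = names(x), sequence = unname(as.character(x)))
    }))
  } else {
    bind_rows(map(fastqs, function(f1) {
      f2 <- sub("_R1\\.fastq$", "_R2.fastq", f1)
      x1 <- read_fastq(f1); x2 <- read_fastq(f2)
      tibble(sample = sub("_R1\\.fastq$", "", basename(f1)),
             read_id = x1$id, fwd_seq = x1$seq, fwd_qual = x1$qual,
             rev_seq = x2$seq, rev_qual = x2$qual)
    }))
  }
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE)
  design <- jsonlite::read_json(file.path(dir, "design.json"),
                                simplifyVector = TRUE)
  list(reads = reads, truth = truth, design = design)
}

write_fasta <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 20000L)
}

write_fastq <- function(ids, seqs, quals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
}

read_fastq <- function(path) {
  ln <- readLines(path)
  stopifnot(length(ln) %% 4L == 0L)
  i <- seq(1, length(ln), by = 4)
  list(id = sub("^@", "", ln[i]), seq = ln[i + 1], qual = ln[i + 3])
}
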