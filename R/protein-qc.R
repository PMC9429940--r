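# Protein-translation quality check for functional-gene features.
#
# Every OTU/ASV representative of a protein-coding amplicon must translate to
# a fragment of the target enzyme. The decision tree implemented here:
#   1. detect the best reading frame (6 frames, local alignment vs a
#      reference protein panel);
#   2. translate; any stop codon anywhere fails the feature (the amplicon is
#      internal to the ORF, so no terminal-stop exception applies);
#   3. stop-free proteins of exactly the expected length pass;
#   4. length-anomalous proteins pass only if they still align to the
#      reference enzyme panel at >= min_identity over >= min_coverage.
# Curated tables retain only passing features.

#' Quality-check configuration for one gene
#'
#' @param gene_name label.
#' @param expected_nt_len expected amplicon length in nt after primer
#'   removal; the expected protein length is `floor(expected_nt_len / 3)`.
#' @param reference_protein_panel character vector of reference protein
#'   sequences for the target enzyme.
#' @param aa_len_tolerance inclusive tolerance (residues) around the
#'   expected protein length (default 0: exact length only).
#' @param min_identity,min_coverage local-alignment verification cutoffs
#'   (defaults 0.5 and 0.7).
#' @return object of class `qc_config`.
#' @export
qc_config <- function(gene_name, expected_nt_len, reference_protein_panel,
                      aa_len_tolerance = 0, min_identity = 0.5,
                      min_coverage = 0.7) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  expected_aa_len <- expected_nt_len %/% 3L
  if (expected_aa_len < 1) abort("expected_nt_len too short")
  if (length(reference_protein_panel) == 0) {
    abort("reference_protein_panel must be non-empty")
  }
  structure(
    list(gene_name = gene_name, expected_nt_len = expected_nt_len,
         expected_aa_len = expected_aa_len,
         aa_len_tolerance = aa_len_tolerance,
         min_identity = min_identity, min_coverage = min_coverage,
         reference_protein_panel = reference_protein_panel),
    class = "qc_config"
  )
}

#' @export
print.qc_config <- function(x, ...) {
  cat(sprintf("<qc_config> %s: %d nt -> %d aa (tol %d), verify >= %.2f identity over >= %.2f coverage, panel of %d\n",
              x$gene_name, x$expected_nt_len, x$expected_aa_len,
              x$aa_len_tolerance, x$min_identity, x$min_coverage,
              length(x$reference_protein_panel)))
  invisible(x)
}

#' Detect the reading frame of a nucleotide feature
#'
#' Translates all six frames (3 offsets x 2 strands) and returns the frame
#' whose translation scores best in local alignment (BLOSUM62) against the
#' reference protein panel. Ties are broken by fewest stop codons, then the
#' forward strand, then the smallest offset.
#'
#' @param nt single nucleotide string (length >= 3).
#' @param panel character vector of reference proteins.
#' @return list with `strand` (`"+"`/`"-"`), `offset` (0-2), `score`.
#' @export
detect_frame <- function(nt, panel) {
  if (length(panel) == 0) abort("empty reference protein panel")
  stopifnot(nchar(nt) >= 3)
  frames <- expand.grid(offset = 0:2, strand = c("+", "-"),
                        stringsAsFactors = FALSE)
  prot <- map_chr(seq_len(nrow(frames)),
                  function(i) translate_frame(nt, frames$strand[i],
                                              frames$offset[i]))
  score <- map_dbl(prot, function(p) {
    if (!nzchar(p)) return(-Inf)
    max(protein_panel_scores(p, panel))
  })
  stops <- map_int(prot, function(p) {
    lengths(regmatches(p, gregexpr("*", p, fixed = TRUE)))
  })
  ord <- order(-score, stops, frames$strand != "+", frames$offset)
  best <- ord[1]
  list(strand = frames$strand[best], offset = frames$offset[best],
       score = score[best], protein = prot[best])
}

#' Split translated proteins into stop-free and stop-containing sets
#'
#' A `*` anywhere in the translated amplicon disqualifies it: the amplicon
#' is internal to the open reading frame, so even a final-position stop
#' marks a corrupt sequence.
#'
#' @param proteins character vector of amino-acid strings.
#' @return list with `stop_free` and `containing_stop` character vectors
#'   (exhaustive, disjoint partition of the input).
#' @export
partition_by_stop <- function(proteins) {
  has_stop <- grepl("*", proteins, fixed = TRUE)
  list(stop_free = proteins[!has_stop], containing_stop = proteins[has_stop])
}

#' Gate stop-free proteins by expected length
#'
#' @param protein character vector of stop-free proteins.
#' @param cfg a [qc_config()].
#' @return character vector, `"expected"` or `"anomalous"` per protein
#'   (inclusive tolerance).
#' @export
gate_by_length <- function(protein, cfg) {
  ifelse(abs(nchar(protein) - cfg$expected_aa_len) <= cfg$aa_len_tolerance,
         "expected", "anomalous")
}

#' Verify a protein against the reference enzyme panel
#'
#' Smith-Waterman (BLOSUM62, gap open 11 / extend 1) against each panel
#' member; the protein passes if its best alignment reaches
#' `cfg$min_identity` identity while covering at least `cfg$min_coverage`
#' of the query. This stands in for a BLASTp check that the feature still
#' encodes the expected enzyme.
#'
#' @param protein single stop-free protein string.
#' @param cfg a [qc_config()].
#' @return list with `pass` (logical) and `best_identity` (best identity
#'   among coverage-qualifying alignments; best overall if none qualify).
#' @export
verify_by_alignment <- function(protein, cfg) {
  if (length(cfg$reference_protein_panel) == 0) {
    abort("empty reference protein panel")
  }
  al <- protein_panel_align(protein, cfg$reference_protein_panel)
  ok_cov <- al$coverage >= cfg$min_coverage
  best <- if (any(ok_cov)) max(al$identity[ok_cov]) else max(al$identity)
  list(pass = any(ok_cov) && best >= cfg$min_identity, best_identity = best)
}

#' Run the full protein quality check over a feature table
#'
#' Applies the decision tree to every feature: frame detection, translation,
#' stop-codon screen, length gate, and alignment verification for
#' length-anomalous proteins. Statuses are `fail_stop_codon`,
#' `pass_expected_length`, `pass_verified` and `fail_unverified`; the
#' curated table keeps only `pass_*` features, so per-sample totals drop by
#' exactly the removed features' counts.
#'
#' @param table feature table tibble: `feature_id`, `sequence`, one count
#'   column per sample (see [build_feature_table()]).
#' @param cfg a [qc_config()].
#' @return list with `verdicts` (tibble: feature_id, strand, frame, protein,
#'   status, best_ref_identity) and `curated` (filtered feature table).
#' @export
qc_feature_set <- function(table, cfg) {
  stopifnot(all(c("feature_id", "sequence") %in% names(table)))
  verdicts <- map(seq_len(nrow(table)), function(i) {
    fr <- detect_frame(table$sequence[i], cfg$reference_protein_panel)
    prot <- fr$protein
    if (grepl("*", prot, fixed = TRUE)) {
      status <- "fail_stop_codon"; best_id <- NA_real_
    } else if (gate_by_length(prot, cfg) == "expected") {
      status <- "pass_expected_length"; best_id <- NA_real_
    } else {
      v <- verify_by_alignment(prot, cfg)
      status <- if (v$pass) "pass_verified" else "fail_unverified"
      best_id <- v$best_identity
    }
    tibble(feature_id = table$feature_id[i], strand = fr$strand,
           frame = fr$offset, protein = prot, status = status,
           best_ref_identity = best_id)
  })
  verdicts <- bind_rows(verdicts)
  keep <- verdicts$status %in% c("pass_expected_length", "pass_verified")
  if (!any(keep)) {
    abort(c("all features failed the protein quality check",
            sprintf("stop codon: %d, unverified: %d",
                    sum(verdicts$status == "fail_stop_codon"),
                    sum(verdicts$status == "fail_unverified"))))
  }
  list(verdicts = verdicts, curated = table[keep, , drop = FALSE])
}

#' Summarise a protein quality check
#'
#' Reports the percentage of failed ("wrong") features, the percentage of
#' reads retained after curation, and a protein-size histogram in 10-residue
#' bins split by pass/fail.
#'
#' @param verdicts verdict tibble from [qc_feature_set()].
#' @param table the original (uncurated) feature table.
#' @return list of class `qc_summary` with `pct_wrong_features`,
#'   `pct_reads_retained`, `size_histogram`.
#' @export
qc_summary <- function(verdicts, table) {
  counts <- feature_counts(table)
  passed <- verdicts$status %in% c("pass_expected_length", "pass_verified")
  total_reads <- sum(counts)
  retained <- sum(counts[match(verdicts$feature_id[passed],
                               table$feature_id), , drop = FALSE])
  hist <- verdicts |>
    mutate(bin = 10L * (nchar(.data$protein) %/% 10L),
           outcome = ifelse(passed, "pass", "fail")) |>
    count(.data$bin, .data$outcome, name = "n_features")
  structure(
    list(pct_wrong_features = 100 * mean(!passed),
         pct_reads_retained = if (total_reads > 0) 100 * retained / total_reads else NA_real_,
         size_histogram = hist),
    class = "qc_summary"
  )
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("<qc_summary> %.2f%% wrong features, %.2f%% reads retained\n",
              x$pct_wrong_features, x$pct_reads_retained))
  invisible(x)
}

# counts matrix (features x samples) from a feature-table tibble
feature_counts <- function(table) {
  sample_cols <- setdiff(names(table), c("feature_id", "sequence"))
  m <- as.matrix(table[, sample_cols, drop = FALSE])
  rownames(m) <- table$feature_id
  m
}
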