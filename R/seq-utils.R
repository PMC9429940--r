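# Low-level sequence operations shared by every module: reverse complement,
# frame-wise translation under the standard genetic code, and the fixed-score
# pairwise alignments that define "identity" throughout the package.

codon_table <- function() {
  if (is.null(.nitramp_env$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .nitramp_env$codons <- setNames(as.character(gc), names(gc))
  }
  .nitramp_env$codons
}

nt_submat <- function() {
  if (is.null(.nitramp_env$nt_mat)) {
    .nitramp_env$nt_mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE
    )
  }
  .nitramp_env$nt_mat
}

aa_submat <- function() {
  if (is.null(.nitramp_env$aa_mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .nitramp_env$aa_mat <- e$BLOSUM62
  }
  .nitramp_env$aa_mat
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a nucleotide sequence in a given strand and frame
#'
#' Standard genetic code; stop codons are written as `*`, codons containing
#' `N` as `X`, and a trailing partial codon is dropped. The reverse strand is
#' translated on the reverse complement with the offset counted from its own
#' 5' end.
#'
#' @param nt single nucleotide string (A/C/G/T/N only).
#' @param strand `"+"` or `"-"`.
#' @param offset frame offset, 0, 1 or 2.
#' @return single amino-acid string.
#' @examples
#' translate_frame("ATGAAATAG")         # "MK*"
#' translate_frame("ATGAA")             # "M" (partial codon dropped)
#' @export
translate_frame <- function(nt, strand = "+", offset = 0) {
  stopifnot(length(nt) == 1L, offset %in% 0:2, strand %in% c("+", "-"))
  nt <- toupper(nt)
  if (grepl("[^ACGTN]", nt)) {
    abort("sequence contains symbols other than A/C/G/T/N")
  }
  if (strand == "-") nt <- revcomp(nt)
  s <- substring(nt, offset + 1L)
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Alignment identity between two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with match +2, mismatch -3, gap open
#' 5 / extend 2 (a gap of length L costs open + L * extend). Identity is
#' the fraction of matching columns among alignment columns excluding
#' terminal gaps (internal gap columns count as non-matching). Symmetric.
#'
#' @param seq1,seq2 single nucleotide strings.
#' @return identity in \[0, 1\].
#' @export
pairwise_identity <- function(seq1, seq2) {
  stopifnot(nzchar(seq1), nzchar(seq2))
  identity_to_refs(seq1, seq2)
}

#' Identities of one query against many references
#'
#' Vectorised over `refs`; same alignment and identity definition as
#' [pairwise_identity()].
#'
#' @param query single nucleotide string.
#' @param refs character vector of nucleotide strings.
#' @return numeric vector, one identity per reference.
#' @export
identity_to_refs <- function(query, refs) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(refs),
    subject = Biostrings::DNAString(query),
    substitutionMatrix = nt_submat(),
    gapOpening = 5, gapExtension = 2, type = "global"
  )
  # matches / (matches + mismatches + internal gap columns)
  out <- Biostrings::pid(pa, type = "PID1") / 100
  out[is.nan(out)] <- 0
  out
}

# Local protein alignment scores of one query against a panel (cheap path
# for frame detection, where only the best score matters).
protein_panel_scores <- function(query, panel) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(panel),
    subject = Biostrings::AAString(query),
    substitutionMatrix = aa_submat(),
    gapOpening = 11, gapExtension = 1, type = "local",
    scoreOnly = TRUE
  )
}

# Local protein alignment of one query against a panel (Smith-Waterman,
# BLOSUM62, gap open 11 / extend 1). Returns per-panel score, identity over
# the local alignment columns, and coverage of the query.
protein_panel_align <- function(query, panel) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(panel),
    subject = Biostrings::AAString(query),
    substitutionMatrix = aa_submat(),
    gapOpening = 11, gapExtension = 1, type = "local"
  )
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  nq <- nchar(query)
  res <- vapply(seq_along(p), function(i) {
    pc <- strsplit(p[i], "", fixed = TRUE)[[1]]
    sc <- strsplit(s[i], "", fixed = TRUE)[[1]]
    ncol_i <- length(pc)
    if (ncol_i == 0L) return(c(0, 0))
    ident <- sum(pc == sc & pc != "-") / ncol_i
    cov <- sum(sc != "-") / nq
    c(ident, cov)
  }, numeric(2))
  tibble(
    score = Biostrings::score(pa),
    identity = res[1, ],
    coverage = res[2, ]
  )
}
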