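## Paralog-pair calling from global alignment under explicit
## coverage / similarity criteria.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA21, AA21]
    }
    cache
  }
})

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal end-to-end alignment under a substitution matrix with affine gap
#' costs (a gap of length L costs `gap_open + (L - 1) * gap_extend`).
#' Traceback ties prefer match/mismatch over gaps, then gap in `a`, so the
#' result is deterministic.
#'
#' @param a,b non-empty amino-acid sequences (strings).
#' @param matrix substitution matrix name (`"BLOSUM62"`) or a numeric matrix
#'   with residue dimnames.
#' @param gap_open,gap_extend gap penalties (positive; defaults 10 and 0.5).
#' @return list of class `alignment_result`: `score`, `alignment_length`,
#'   `aligned_pair_count` (columns where both sequences have a residue),
#'   `identity_count`, `positive_count` (substitution score > 0), and the
#'   gapped `aligned_a` / `aligned_b` strings.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  a <- aa_check(a, "sequence a"); b <- aa_check(b, "sequence b")
  S <- if (is.character(matrix)) {
    if (matrix != "BLOSUM62") stop("unknown matrix: ", matrix)
    blosum62_matrix()
  } else matrix
  ea <- aa_encode(a); eb <- aa_encode(b)
  C <- S[ea, eb, drop = FALSE]
  res <- pairdp_cpp(C, gap_open, gap_extend, FALSE)
  summarize_alignment(res, aa_chars(a), aa_chars(b), S)
}

summarize_alignment <- function(res, ca, cb, S) {
  ai <- res$ai; bi <- res$bi
  both <- ai > 0 & bi > 0
  ra <- ifelse(ai > 0, ca[pmax(ai, 1)], "-")
  rb <- ifelse(bi > 0, cb[pmax(bi, 1)], "-")
  idc <- sum(both & ra == rb)
  pos <- if (any(both)) sum(S[cbind(ra[both], rb[both])] > 0) else 0L
  structure(list(score = res$score,
                 alignment_length = length(ai),
                 aligned_pair_count = sum(both),
                 identity_count = idc,
                 positive_count = pos,
                 aligned_a = paste(ra, collapse = ""),
                 aligned_b = paste(rb, collapse = "")),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("alignment: score", round(x$score, 1), "| length", x$alignment_length,
      "| aligned pairs", x$aligned_pair_count,
      "| identities", x$identity_count, "| positives", x$positive_count, "\n")
  invisible(x)
}

#' Evaluate one candidate duplicate pair
#'
#' A pair is a duplication when (1) the alignable region covers more than
#' `coverage` of the longer protein, and (2) the similarity of the aligned
#' region exceeds `similarity` - both strict inequalities. Coverage is
#' `aligned_pair_count / max(length a, length b)`; similarity is
#' `positive_count / aligned_pair_count` (`mode = "positives"`, the default)
#' or `identity_count / aligned_pair_count` (`mode = "identity"`).
#'
#' @param a,b sequences (strings) or one-row [protein_records()] tables.
#' @param coverage,similarity thresholds (defaults 0.8 and 0.7).
#' @param mode similarity definition.
#' @param ... passed to [global_align()].
#' @return list with `coverage`, `similarity` and `pass`; of class
#'   `pair_evaluation`.
#' @export
evaluate_pair <- function(a, b, coverage = 0.8, similarity = 0.7,
                          mode = c("positives", "identity"), ...) {
  mode <- match.arg(mode)
  sa <- if (is.character(a)) a else as_record(a)$sequence
  sb <- if (is.character(b)) b else as_record(b)$sequence
  aln <- global_align(sa, sb, ...)
  cov <- aln$aligned_pair_count / max(nchar(sa), nchar(sb))
  sim <- if (aln$aligned_pair_count == 0) 0 else
    (if (mode == "positives") aln$positive_count else aln$identity_count) /
    aln$aligned_pair_count
  structure(list(coverage = cov, similarity = sim,
                 pass = cov > coverage && sim > similarity,
                 alignment = aln),
            class = "pair_evaluation")
}

#' Call duplicated gene pairs across a family
#'
#' Evaluates every unordered member pair under the coverage / similarity
#' criteria and annotates surviving pairs as `tandem` (same chromosome) or
#' `segmental` (different chromosomes). A gene may participate in several
#' pairs.
#'
#' @param members a [protein_records()] table.
#' @param loci locus table covering every member id.
#' @param coverage,similarity,mode as in [evaluate_pair()].
#' @param ... passed to [global_align()].
#' @return data.frame with columns `id_a`, `id_b`, `coverage`, `similarity`,
#'   `event`; zero rows when no pair qualifies.
#' @export
find_duplicate_pairs <- function(members, loci, coverage = 0.8, similarity = 0.7,
                                 mode = "positives", ...) {
  miss <- setdiff(members$id, loci$gene_id)
  if (length(miss) > 0)
    stop("missing locus for member(s): ", paste(miss, collapse = ", "))
  out <- data.frame(id_a = character(0), id_b = character(0),
                    coverage = numeric(0), similarity = numeric(0),
                    event = character(0), stringsAsFactors = FALSE)
  n <- nrow(members)
  if (n < 2) return(out)
  chrom <- setNames(loci$chromosome[match(members$id, loci$gene_id)], members$id)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ev <- evaluate_pair(members$sequence[i], members$sequence[j],
                          coverage = coverage, similarity = similarity,
                          mode = mode, ...)
      if (!ev$pass) next
      ida <- members$id[i]; idb <- members$id[j]
      out <- rbind(out, data.frame(
        id_a = ida, id_b = idb,
        coverage = ev$coverage, similarity = ev$similarity,
        event = if (chrom[ida] == chrom[idb]) "tandem" else "segmental",
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
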