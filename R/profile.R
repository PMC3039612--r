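#' Build a position-specific scoring profile from aligned sequences
#'
#' Column log-odds are `log2(((count + pseudocount * bg) / (N + pseudocount)) / bg)`
#' against a fixed background composition, where `N` is the number of non-gap
#' residues in the column. Columns in which gaps are the majority are dropped.
#' The ambiguity code X always scores 0 (background).
#'
#' @param aligned character vector of >= 2 equal-length aligned sequences
#'   (gap character `-`).
#' @param pseudocount positive smoothing pseudocount (default 1).
#' @param background named residue frequency vector (default Swiss-Prot
#'   average composition).
#' @param source provenance text stored on the profile.
#' @return an object of class `scoring_profile` with elements `log_odds`
#'   (columns x 21 matrix, X last), `background`, `source`,
#'   `consensus_score` (sum of column maxima) and `length`.
#' @export
build_profile <- function(aligned, pseudocount = 1,
                          background = AA_BACKGROUND, source = "alignment") {
  if (length(aligned) < 2) stop("need at least 2 aligned sequences")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  aligned <- toupper(aligned)
  L <- unique(nchar(aligned))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  if (L == 0) stop("empty alignment")
  background <- background[AA20] / sum(background[AA20])
  mat <- do.call(rbind, strsplit(aligned, ""))
  keep <- colSums(mat == "-") <= nrow(mat) / 2
  if (!any(keep)) stop("all columns are gap-majority")
  mat <- mat[, keep, drop = FALSE]
  lo <- matrix(0, ncol(mat), 21, dimnames = list(NULL, AA21))
  for (k in seq_len(ncol(mat))) {
    col <- mat[, k]
    col <- col[col %in% AA20]
    n <- length(col)
    counts <- table(factor(col, levels = AA20))
    p <- (as.numeric(counts) + pseudocount * background) / (n + pseudocount)
    lo[k, AA20] <- log2(p / background)
  }
  new_profile(lo, background, source)
}

#' Build a profile from a single consensus string
#'
#' Models each column as emitting the consensus residue with probability
#' `match_prob` and the remaining mass spread over the other residues in
#' proportion to the background. This is how the bundled DBD consensus is
#' turned into the pipeline's default scanning profile.
#'
#' @param consensus residue string (no gaps).
#' @param match_prob probability mass on the consensus residue per column.
#' @param background,source as in [build_profile()].
#' @return a `scoring_profile`.
#' @export
consensus_profile <- function(consensus, match_prob = 0.5,
                              background = AA_BACKGROUND, source = "consensus") {
  consensus <- aa_check(consensus, "consensus")
  if (match_prob <= 0 || match_prob >= 1) stop("match_prob must be in (0,1)")
  chars <- aa_chars(consensus)
  if (any(chars == "X")) stop("consensus must not contain X")
  background <- background[AA20] / sum(background[AA20])
  lo <- matrix(0, length(chars), 21, dimnames = list(NULL, AA21))
  for (k in seq_along(chars)) {
    res <- chars[k]
    q <- background * (1 - match_prob) / (1 - background[res])
    q[res] <- match_prob
    lo[k, AA20] <- log2(q / background)
  }
  new_profile(lo, background, source)
}

new_profile <- function(lo, background, source) {
  structure(list(log_odds = lo, background = background, source = source,
                 length = nrow(lo),
                 consensus_score = sum(apply(lo[, AA20, drop = FALSE], 1, max))),
            class = "scoring_profile")
}

#' @export
print.scoring_profile <- function(x, ...) {
  cat("scoring_profile:", x$length, "columns, consensus score",
      round(x$consensus_score, 2), "bits (", x$source, ")\n")
  invisible(x)
}

#' Default DBD scanning profile
#'
#' The extended DBD template (see [hsf_dbd_template()]) as a
#' [consensus_profile()].
#'
#' @param match_prob per-column consensus emission probability.
#' @return a `scoring_profile`.
#' @export
hsf_dbd_profile <- function(match_prob = 0.5) {
  consensus_profile(hsf_dbd_template(), match_prob = match_prob,
                    source = "Hsf DBD template")
}

#' Scan a protein for the best-scoring profile window
#'
#' Scores every ungapped window of the sequence against the profile and
#' reports the best window if it reaches the threshold; ties are broken by
#' the leftmost start. Sequences shorter than the profile yield no hit (with
#' a message, not an error).
#'
#' @param record one-row [protein_records()] table, or a list/vector with
#'   `id` and `sequence`.
#' @param profile a `scoring_profile`.
#' @param threshold score threshold; default 0.6 x the profile's consensus
#'   self-score (the profile's own consensus always scores above any other
#'   equal-length sequence, so this is a relative identity floor).
#' @return a list of class `domain_hit` (`interval`, `score`, `profile_id`)
#'   or `NULL` if no window reaches the threshold.
#' @export
scan_profile <- function(record, profile, threshold = NULL) {
  if (!inherits(profile, "scoring_profile")) stop("profile must be a scoring_profile")
  if (profile$length == 0) stop("empty profile")
  if (is.null(threshold)) threshold <- 0.6 * profile$consensus_score
  rec <- as_record(record)
  enc <- aa_encode(rec$sequence)
  if (length(enc) < profile$length) {
    message("sequence '", rec$id, "' shorter than profile; no hit")
    return(NULL)
  }
  scores <- profile_scan_cpp(enc, profile$log_odds)
  best <- which.max(scores) # leftmost maximum
  if (scores[best] < threshold) return(NULL)
  structure(list(interval = interval(best, best + profile$length - 1L),
                 score = unname(scores[best]),
                 profile_id = profile$source, id = rec$id),
            class = "domain_hit")
}

# Accept a one-row protein_records table, a list, or a named character.
as_record <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1) stop("expected exactly one record")
    list(id = record$id, sequence = record$sequence)
  } else if (is.list(record)) {
    list(id = record$id, sequence = record$sequence)
  } else if (is.character(record) && length(record) == 1) {
    list(id = if (is.null(names(record))) "seq" else names(record),
         sequence = unname(record))
  } else stop("cannot interpret record")
}
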