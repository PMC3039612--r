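#' Delimit the HR-A/B oligomerization region by heptad-repeat scanning
#'
#' Scans C-terminal of `search_start` for coiled-coil-like heptad blocks:
#' a heptad is a 7-residue unit whose `a` and `d` positions are hydrophobic
#' (L/I/V/M/F). Maximal chains of in-register heptads (step 7) in which every
#' heptad has a/d occupancy of at least `heptad_min` (default 1: both
#' positions hydrophobic, which keeps short hydrophobic motifs such as an
#' NES from masquerading as an extra coiled-coil block) and whose overall
#' occupancy reaches `occupancy_floor` become candidate blocks; blocks need
#' at least `min_heptads` heptads. The best-scoring ordered block pair
#' separated by at most `max_insertion` residues becomes HR-A and HR-B with
#' `insertion_length` equal to the gap; a lone block is a continuous HR-A/B
#' region (insertion 0). Larger gaps are never treated as an insertion: only
#' the better block is kept.
#'
#' @param record protein record (see [scan_profile()] for accepted forms).
#' @param search_start 1-based position at which the scan starts (typically
#'   DBD end + 1).
#' @param min_heptads minimum heptads per block (default 2).
#' @param occupancy_floor minimum mean hydrophobic occupancy of a/d positions
#'   over a block (default 0.6).
#' @param heptad_min minimum a/d occupancy for a single heptad to join a
#'   chain (1 = both, 0.5 = either).
#' @param max_insertion largest HR-A to HR-B gap treated as an insertion
#'   (default 30; the largest biological insertion in this family is 21).
#' @return a list of class `hrab_region` with `hra`, `hrb`, `total` intervals,
#'   `insertion_length`, `heptad_score` (mean a/d occupancy) and `n_heptads`,
#'   or `NULL` when no block reaches the floor.
#' @export
find_hrab <- function(record, search_start = 1, min_heptads = 2,
                      occupancy_floor = 0.6, max_insertion = 30,
                      heptad_min = 1) {
  rec <- as_record(record)
  chars <- aa_chars(aa_check(rec$sequence))
  n <- length(chars)
  if (search_start < 1) stop("search_start must be >= 1")
  if (search_start > n) stop("search_start beyond sequence end")
  hyd <- chars %in% HEPTAD_HYDRO
  last_start <- n - 6L
  if (last_start < search_start) return(NULL)
  starts <- search_start:last_start
  occ <- (hyd[starts] + hyd[starts + 3L]) / 2 # a/d occupancy per heptad start
  present <- occ >= heptad_min

  # Maximal in-register chains: start where no heptad 7 positions upstream.
  blocks <- list()
  for (s in starts[present]) {
    if (s - 7L >= search_start && present[s - 7L - search_start + 1L]) next
    ks <- s
    while (ks + 7L <= last_start && present[ks + 7L - search_start + 1L]) ks <- ks + 7L
    hepts <- seq(s, ks, by = 7L)
    k <- length(hepts)
    occupancy <- mean(occ[hepts - search_start + 1L])
    if (k >= min_heptads && occupancy >= occupancy_floor) {
      blocks[[length(blocks) + 1L]] <-
        list(start = s, end = s + 7L * k - 1L, k = k, occupancy = occupancy,
             score = k * occupancy)
    }
  }
  if (length(blocks) == 0) return(NULL)

  ord <- order(vapply(blocks, `[[`, numeric(1), "start"))
  blocks <- blocks[ord]

  # Best compatible ordered pair (gap 0..max_insertion), then best lone block.
  best <- NULL; best_score <- -Inf
  if (length(blocks) >= 2) {
    for (i in seq_len(length(blocks) - 1L)) {
      for (j in (i + 1L):length(blocks)) {
        gap <- blocks[[j]]$start - blocks[[i]]$end - 1L
        if (gap < 0 || gap > max_insertion) next
        sc <- blocks[[i]]$score + blocks[[j]]$score
        if (sc > best_score) { best_score <- sc; best <- c(i, j) }
      }
    }
  }
  if (!is.null(best)) {
    b1 <- blocks[[best[1]]]; b2 <- blocks[[best[2]]]
    gap <- b2$start - b1$end - 1L
    if (gap > 0) {
      return(new_hrab(interval(b1$start, b1$end), interval(b2$start, b2$end),
                      gap, (b1$occupancy * b1$k + b2$occupancy * b2$k) / (b1$k + b2$k),
                      b1$k + b2$k))
    }
    # adjacent blocks: continuous region
    return(split_continuous(b1$start, b2$end, b1$k + b2$k,
                            (b1$occupancy * b1$k + b2$occupancy * b2$k) / (b1$k + b2$k)))
  }
  scores <- vapply(blocks, `[[`, numeric(1), "score")
  b <- blocks[[which.max(scores)]]
  split_continuous(b$start, b$end, b$k, b$occupancy)
}

new_hrab <- function(hra, hrb, insertion, occupancy, n_heptads) {
  structure(list(hra = hra, hrb = hrb,
                 insertion_length = as.integer(insertion),
                 total = interval(hra["start"], hrb["end"]),
                 heptad_score = occupancy, n_heptads = as.integer(n_heptads)),
            class = "hrab_region")
}

# A continuous heptad block carries no insertion; split it into nominal
# HR-A (first half, rounded up) and HR-B parts so the region bookkeeping
# (total = HR-A + insertion + HR-B) stays exact.
split_continuous <- function(start, end, k, occupancy) {
  ka <- ceiling(k / 2)
  hra <- interval(start, start + 7L * ka - 1L)
  hrb <- interval(start + 7L * ka, end)
  new_hrab(hra, hrb, 0L, occupancy, k)
}

#' Drop redundant proteins mapping to the same chromosome location
#'
#' Among records sharing a (chromosome, start) locus, keeps the longest
#' protein; exact length ties are broken by lexicographically smallest id.
#'
#' @param records a [protein_records()] table.
#' @param loci locus table from [read_locus_table()] covering every record id.
#' @return the filtered records table (original row order preserved).
#' @export
deduplicate_by_locus <- function(records, loci) {
  miss <- setdiff(records$id, loci$gene_id)
  if (length(miss) > 0)
    stop("missing locus for record(s): ", paste(miss, collapse = ", "))
  m <- match(records$id, loci$gene_id)
  key <- paste(loci$chromosome[m], loci$start[m], sep = ":")
  keep <- rep(FALSE, nrow(records))
  for (k in unique(key)) {
    idx <- which(key == k)
    lens <- nchar(records$sequence[idx])
    cand <- idx[lens == max(lens)]
    keep[cand[order(records$id[cand])][1]] <- TRUE
  }
  records[keep, , drop = FALSE]
}

#' Identify Hsf family members from a candidate proteome
#'
#' The mining pipeline: DBD profile scan (keep records with a hit), same-locus
#' deduplication, then heptad scan for the HR-A/B coiled-coil (drop records
#' without one). Per-stage drop counts are reported via `message()` and
#' returned.
#'
#' @param records candidate [protein_records()].
#' @param loci locus table covering every record id.
#' @param profile `scoring_profile` (default [hsf_dbd_profile()]).
#' @param threshold profile score threshold (default 0.6 x consensus score).
#' @param ... passed to [find_hrab()].
#' @return list of class `hsf_candidates`: `members` (records table of
#'   survivors), `domain_hits` and `hrab` (named lists by id), and
#'   `drop_counts` per stage.
#' @export
identify_candidates <- function(records, loci, profile = hsf_dbd_profile(),
                                threshold = NULL, ...) {
  n0 <- nrow(records)
  if (n0 == 0) {
    return(structure(list(members = records, domain_hits = list(), hrab = list(),
                          drop_counts = c(no_dbd = 0L, same_locus = 0L, no_coiled_coil = 0L)),
                     class = "hsf_candidates"))
  }
  hits <- lapply(seq_len(n0), function(i)
    suppressMessages(scan_profile(records[i, ], profile, threshold)))
  names(hits) <- records$id
  with_dbd <- records[!vapply(hits, is.null, logical(1)), , drop = FALSE]
  n_dbd_drop <- n0 - nrow(with_dbd)

  deduped <- deduplicate_by_locus(with_dbd, loci)
  n_locus_drop <- nrow(with_dbd) - nrow(deduped)

  hrab <- lapply(deduped$id, function(id) {
    dbd_end <- hits[[id]]$interval["end"]
    find_hrab(deduped[deduped$id == id, ], search_start = dbd_end + 1L, ...)
  })
  names(hrab) <- deduped$id
  ok <- !vapply(hrab, is.null, logical(1))
  members <- deduped[ok, , drop = FALSE]
  n_cc_drop <- nrow(deduped) - nrow(members)

  message("identify_candidates: ", n0, " candidates; dropped ", n_dbd_drop,
          " (no DBD), ", n_locus_drop, " (same locus), ", n_cc_drop,
          " (no coiled-coil); ", nrow(members), " members")
  structure(list(members = members,
                 domain_hits = hits[members$id],
                 hrab = hrab[members$id],
                 drop_counts = c(no_dbd = n_dbd_drop, same_locus = n_locus_drop,
                                 no_coiled_coil = n_cc_drop)),
            class = "hsf_candidates")
}
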