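#' Linker length between the DBD and the HR-A/B region
#'
#' The linker is the stretch strictly between the DBD end and the HR-A/B
#' start: `hrab_total_start - dbd_end - 1`. Adjacent domains give 0.
#'
#' @param dbd DBD [interval()].
#' @param hrab_total HR-A/B total [interval()]; must start after the DBD ends.
#' @return integer residue count.
#' @export
measure_linker <- function(dbd, hrab_total) {
  if (hrab_total["start"] <= dbd["end"])
    stop("HR-A/B region overlaps the DBD (starts at ", hrab_total["start"],
         ", DBD ends at ", dbd["end"], ")")
  unname(as.integer(hrab_total["start"] - dbd["end"] - 1L))
}

#' Assign Hsf class from the HR-A/B insertion length
#'
#' Class is a pure function of the insertion between HR-A and HR-B: an
#' insertion of 21 residues (within `tol`) is class A, 7 is class C, and no
#' insertion (at most `tol`) is class B; anything else is unclassified. The
#' linker length is checked against the class-typical ranges (A: 9-39,
#' B: 50-78, C: 14-49) but is advisory only - it never overrides the
#' insertion rule.
#'
#' @param insertion_length non-negative residue count.
#' @param linker_length linker residue count (may be `NA`).
#' @param tol classification tolerance in residues (default 2, so that a
#'   single-heptad phase error cannot flip the class).
#' @return list of class `hsf_classification`: `class_label` (A/B/C/
#'   unclassified), `insertion_length`, `linker_length`, `linker_consistent`,
#'   `od_length` (filled by [annotate_member()]).
#' @export
assign_class <- function(insertion_length, linker_length = NA, tol = 2) {
  if (is.na(insertion_length) || insertion_length < 0)
    stop("insertion_length must be >= 0")
  label <- if (abs(insertion_length - CLASS_INSERTION["A"]) <= tol) "A"
  else if (abs(insertion_length - CLASS_INSERTION["C"]) <= tol) "C"
  else if (insertion_length <= tol) "B"
  else "unclassified"
  consistent <- if (label %in% names(LINKER_RANGE) && !is.na(linker_length)) {
    r <- LINKER_RANGE[[label]]
    linker_length >= r[1] && linker_length <= r[2]
  } else NA
  structure(list(class_label = label,
                 insertion_length = as.integer(insertion_length),
                 linker_length = if (is.na(linker_length)) NA_integer_ else as.integer(linker_length),
                 linker_consistent = consistent, od_length = NA_integer_),
            class = "hsf_classification")
}

#' @export
print.hsf_classification <- function(x, ...) {
  cat("class", x$class_label, "(insertion", x$insertion_length,
      "aa, linker", x$linker_length, "aa,",
      if (isTRUE(x$linker_consistent)) "linker consistent)" else "linker atypical)", "\n")
  invisible(x)
}

empty_motif_hits <- function() {
  data.frame(kind = character(0), position = integer(0), text = character(0),
             notation = character(0), score = numeric(0), primary = logical(0),
             stringsAsFactors = FALSE)
}

# Basic (K/R) clusters: maximal groups of basic residues in which consecutive
# basics are at most 3 positions apart. Returns start/end/counts.
basic_clusters <- function(chars) {
  bp <- which(chars %in% BASIC_RES)
  if (length(bp) == 0) return(NULL)
  grp <- cumsum(c(1, diff(bp) > 3))
  do.call(rbind, lapply(split(bp, grp), function(p)
    data.frame(start = min(p), end = max(p), n_basic = length(p))))
}

#' Scan for nuclear localization signals (basic clusters)
#'
#' Monopartite NLS: a basic cluster spanning at most 7 residues with at least
#' 3 K/R residues, a basic fraction of at least 0.6, starting and ending on a
#' basic residue. Bipartite NLS: two
#' basic clusters (>= 2 and >= 3 basics) separated by a 5-12 residue spacer,
#' rendered in the compact notation `cluster1<spacer>cluster2` (e.g.
#' `KRK7KKRRR`). Hits are sorted by proximity to `region_start` and the
#' nearest is flagged `primary` (the presumptive functional NLS, which in
#' this family sits just C-terminal of the HR-A/B region).
#'
#' @param record protein record.
#' @param region_start 1-based scan start (typically HR-B end + 1).
#' @return a data.frame of motif hits (possibly empty): `kind`
#'   (`NLS_mono`/`NLS_bipartite`), `position`, `text`, `notation`, `score`
#'   (basic residue count), `primary`.
#' @export
scan_nls <- function(record, region_start = 1) {
  rec <- as_record(record)
  chars <- aa_chars(aa_check(rec$sequence))
  if (region_start > length(chars)) stop("region_start beyond sequence end")
  cl <- basic_clusters(chars)
  hits <- empty_motif_hits()
  if (is.null(cl)) return(hits)
  cl <- cl[cl$start >= region_start, , drop = FALSE]
  if (nrow(cl) == 0) return(hits)
  cl$len <- cl$end - cl$start + 1L
  mono <- cl[cl$len <= 7 & cl$n_basic >= 3 & cl$n_basic / cl$len >= 0.6, ,
             drop = FALSE]
  for (i in seq_len(nrow(mono))) {
    txt <- paste(chars[mono$start[i]:mono$end[i]], collapse = "")
    hits <- rbind(hits, data.frame(
      kind = "NLS_mono", position = mono$start[i], text = txt, notation = txt,
      score = mono$n_basic[i], primary = FALSE, stringsAsFactors = FALSE))
  }
  if (nrow(cl) >= 2) {
    for (i in seq_len(nrow(cl) - 1L)) {
      for (j in (i + 1L):nrow(cl)) {
        spacer <- cl$start[j] - cl$end[i] - 1L
        if (spacer < 5 || spacer > 12) next
        if (cl$n_basic[i] < 2 || cl$n_basic[j] < 3) next
        t1 <- paste(chars[cl$start[i]:cl$end[i]], collapse = "")
        t2 <- paste(chars[cl$start[j]:cl$end[j]], collapse = "")
        txt <- paste(chars[cl$start[i]:cl$end[j]], collapse = "")
        hits <- rbind(hits, data.frame(
          kind = "NLS_bipartite", position = cl$start[i], text = txt,
          notation = paste0(t1, spacer, t2),
          score = cl$n_basic[i] + cl$n_basic[j], primary = FALSE,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(abs(hits$position - region_start), -hits$score,
                     hits$position), , drop = FALSE]
  hits$primary[1] <- TRUE
  rownames(hits) <- NULL
  hits
}

#' Scan for nuclear export signals (hydrophobic-rich stretches)
#'
#' Reports 5-12 residue windows with at least 2 hydrophobic residues
#' (L/I/V/F/M), hydrophobic density of at least 0.375, and hydrophobic first
#' and last residues (the leucine-rich NES consensus anchors on a terminal
#' hydrophobic). Overlapping windows are merged to the best-scoring one
#' (score = hydrophobic density, longer windows preferred on ties).
#'
#' @param record protein record.
#' @param region `c(start, end)` scan region, 1-based inclusive.
#' @param min_hydro minimum hydrophobic count (default 2).
#' @param min_density minimum hydrophobic fraction (default 0.375).
#' @return data.frame of `NES` motif hits (possibly empty).
#' @export
scan_nes <- function(record, region = NULL, min_hydro = 2, min_density = 0.375) {
  rec <- as_record(record)
  chars <- aa_chars(aa_check(rec$sequence))
  region <- check_region(region, length(chars))
  hyd <- chars %in% NES_HYDRO
  wins <- window_hits(region, 5L, 12L, function(s, e) {
    if (!hyd[s] || !hyd[e]) return(NULL)
    cnt <- sum(hyd[s:e]); len <- e - s + 1L
    if (cnt < min_hydro || cnt / len < min_density) return(NULL)
    cnt / len
  })
  finalize_hits(wins, chars, "NES", max_hits = Inf)
}

#' Scan for AHA activator motifs
#'
#' AHA modules are short windows rich in aromatic (W/Y/F), hydrophobic
#' (L/I/V/M) and acidic (D/E) residues. Windows of 8-12 residues are scored
#' by the in-class residue fraction; a window qualifies when it contains at
#' least one aromatic, one acidic and one hydrophobic residue and its
#' in-class fraction reaches `threshold` (default 0.5, the minimum over the
#' published family motifs). Up to `max_hits` best non-overlapping hits are
#' reported (activation domains carry at most two AHA modules).
#'
#' @param record protein record.
#' @param region `c(start, end)` scan region (default: whole sequence;
#'   [annotate_member()] uses C-terminal of the primary NLS).
#' @param threshold minimum in-class fraction.
#' @param max_hits maximum reported hits (default 2).
#' @return data.frame of `AHA` motif hits (possibly empty).
#' @export
scan_aha <- function(record, region = NULL, threshold = 0.5, max_hits = 2) {
  rec <- as_record(record)
  chars <- aa_chars(aa_check(rec$sequence))
  region <- check_region(region, length(chars))
  arom <- chars %in% AHA_AROMATIC
  hyd <- chars %in% AHA_HYDRO
  acid <- chars %in% AHA_ACIDIC
  inclass <- arom | hyd | acid
  wins <- window_hits(region, 8L, 12L, function(s, e) {
    idx <- s:e
    if (!any(arom[idx]) || !any(acid[idx]) || !any(hyd[idx])) return(NULL)
    frac <- sum(inclass[idx]) / length(idx)
    if (frac < threshold) return(NULL)
    frac
  })
  finalize_hits(wins, chars, "AHA", max_hits = max_hits)
}

check_region <- function(region, n) {
  if (is.null(region)) region <- c(1L, n)
  if (length(region) != 2 || region[1] < 1 || region[2] > n || region[1] > region[2])
    stop("invalid scan region")
  as.integer(region)
}

# Enumerate all windows of widths min_w..max_w inside region; scorer returns
# a numeric score or NULL to reject.
window_hits <- function(region, min_w, max_w, scorer) {
  out <- list()
  for (s in region[1]:region[2]) {
    for (w in min_w:max_w) {
      e <- s + w - 1L
      if (e > region[2]) break
      sc <- scorer(s, e)
      if (!is.null(sc)) out[[length(out) + 1L]] <- c(s, e, sc)
    }
  }
  out
}

# Greedy non-overlap selection: best score, then longest, then leftmost.
finalize_hits <- function(wins, chars, kind, max_hits) {
  if (length(wins) == 0) return(empty_motif_hits())
  m <- do.call(rbind, wins)
  ord <- order(-m[, 3], -(m[, 2] - m[, 1]), m[, 1])
  m <- m[ord, , drop = FALSE]
  sel <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(m))) {
    if (nrow(sel) >= max_hits) break
    if (nrow(sel) == 0 || all(m[i, 1] > sel[, 2] | m[i, 2] < sel[, 1]))
      sel <- rbind(sel, m[i, ])
  }
  sel <- sel[order(sel[, 1]), , drop = FALSE]
  data.frame(kind = kind, position = as.integer(sel[, 1]),
             text = vapply(seq_len(nrow(sel)), function(i)
               paste(chars[sel[i, 1]:sel[i, 2]], collapse = ""), character(1)),
             notation = vapply(seq_len(nrow(sel)), function(i)
               paste(chars[sel[i, 1]:sel[i, 2]], collapse = ""), character(1)),
             score = sel[, 3], primary = FALSE, stringsAsFactors = FALSE)
}

#' Compose the full per-member annotation
#'
#' Combines the DBD hit, the HR-A/B region, classification and the three
#' motif scans into one domain-table-style record. The NLS scan starts at the
#' HR-B end (the functional NLS sits just C-terminal of the HR-A/B region);
#' the NES scan covers HR-B end to the C-terminus; the AHA scan covers the
#' region C-terminal of the primary NLS. Class B and C members never receive
#' AHA hits in the report - these classes lack activator function - so any
#' scanner hits are suppressed and flagged.
#'
#' @param record protein record.
#' @param domain_hit `domain_hit` from [scan_profile()].
#' @param hrab `hrab_region` from [find_hrab()].
#' @param tol class tolerance passed to [assign_class()].
#' @return list of class `hsf_annotation`.
#' @export
annotate_member <- function(record, domain_hit, hrab, tol = 2) {
  if (is.null(domain_hit) || is.null(hrab))
    stop("annotate_member requires both a domain hit and an HR-A/B region")
  rec <- as_record(record)
  n <- nchar(rec$sequence)
  linker <- measure_linker(domain_hit$interval, hrab$total)
  cls <- assign_class(hrab$insertion_length, linker, tol = tol)
  cls$od_length <- interval_length(hrab$total)

  nls_from <- min(unname(hrab$hrb["end"]) + 1L, n)
  nls <- scan_nls(rec, region_start = nls_from)
  if (nrow(nls) == 0)
    warning("no NLS found for '", rec$id, "'")
  nes <- scan_nes(rec, region = c(nls_from, n))
  aha_from <- if (nrow(nls) > 0) {
    p <- nls[nls$primary, ][1, ]
    min(p$position + nchar(p$text), n)
  } else nls_from
  aha <- scan_aha(rec, region = c(aha_from, n))
  aha_suppressed <- FALSE
  if (cls$class_label %in% c("B", "C") && nrow(aha) > 0) {
    aha_suppressed <- TRUE
    aha <- empty_motif_hits()
  }
  structure(list(id = rec$id, length = n, classification = cls,
                 dbd = domain_hit$interval, domain_score = domain_hit$score,
                 hra = hrab$hra, hrb = hrab$hrb, od = hrab$total,
                 insertion_length = hrab$insertion_length,
                 linker_length = linker,
                 nls = nls, nes = nes, aha = aha,
                 aha_suppressed = aha_suppressed),
            class = "hsf_annotation")
}

#' @export
print.hsf_annotation <- function(x, ...) {
  cat(x$id, ": class ", x$classification$class_label,
      ", DBD ", x$dbd["start"], "-", x$dbd["end"],
      ", OD ", x$od["start"], "-", x$od["end"],
      " (insertion ", x$insertion_length, " aa, linker ", x$linker_length, " aa)\n",
      sep = "")
  if (nrow(x$nls) > 0) {
    p <- x$nls[x$nls$primary, ][1, ]
    cat("  NLS (", p$position, ") ", p$notation, "\n", sep = "")
  }
  if (nrow(x$nes) > 0)
    cat("  NES (", x$nes$position[1], ") ", x$nes$text[1], "\n", sep = "")
  if (nrow(x$aha) > 0)
    for (i in seq_len(nrow(x$aha)))
      cat("  AHA", i, " (", x$aha$position[i], ") ", x$aha$text[i], "\n", sep = "")
  invisible(x)
}

# Flatten annotations into the report table (domain-table layout).
annotation_table <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    pn <- if (nrow(a$nls) > 0) a$nls[a$nls$primary, ][1, ] else NULL
    data.frame(
      id = a$id, class = a$classification$class_label,
      length = a$length,
      dbd = paste0(a$dbd["start"], "-", a$dbd["end"]),
      od = paste0(a$od["start"], "-", a$od["end"]),
      insertion = a$insertion_length,
      linker = a$linker_length,
      linker_consistent = isTRUE(a$classification$linker_consistent),
      nls = if (is.null(pn)) "" else paste0("(", pn$position, ") ", pn$notation),
      nes = if (nrow(a$nes) > 0) paste0("(", a$nes$position[1], ") ", a$nes$text[1]) else "",
      aha = if (nrow(a$aha) > 0)
        paste(sprintf("(%d) %s", a$aha$position, a$aha$text), collapse = "; ")
      else "",
      aha_suppressed = a$aha_suppressed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
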