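# Shared fixtures built in code.

# Small family used across tests (cached per session).
.small_family_cache <- new.env(parent = emptyenv())
small_family <- function(seed = 101) {
  key <- paste0("fam", seed)
  if (is.null(.small_family_cache[[key]])) {
    cfg <- family_sim_config(n_per_class = c(A = 5L, B = 3L, C = 2L),
                             n_duplicate_pairs = 2L, seed = seed)
    .small_family_cache[[key]] <- simulate_family(cfg)
  }
  .small_family_cache[[key]]
}

# Embed a motif in a scanner-neutral polar context.
neutral_embed <- function(motif, flank = 40) {
  ctx <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("S", "T", "N", "Q", "G", "A", "P"), n, replace = TRUE),
          collapse = "")
  }
  list(sequence = paste0(ctx(flank, 11), motif, ctx(flank, 12)),
       start = flank + 1L, end = flank + nchar(motif))
}

# Expand the compact bipartite NLS notation (spacer digits -> polar run).
expand_bipartite <- function(s) {
  m <- regmatches(s, regexpr("[0-9]+", s))
  if (length(m) == 0) return(s)
  parts <- strsplit(s, "[0-9]+")[[1]]
  paste0(parts[1], strrep("S", as.integer(m)), parts[2])
}

# Does any hit overlap the embedded interval?
any_hit_overlaps <- function(hits, start, end) {
  nrow(hits) > 0 &&
    any(hits$position <= end & (hits$position + nchar(hits$text) - 1L) >= start)
}

# Unordered pair keys for comparing planted vs found duplications.
pair_keys <- function(a, b) {
  vapply(seq_along(a), function(i) paste(sort(c(a[i], b[i])), collapse = "|"),
         character(1))
}

planted_pair_keys <- function(truth) {
  tp <- truth[!is.na(truth$duplicate_partner), c("gene_id", "duplicate_partner")]
  unique(pair_keys(tp$gene_id, tp$duplicate_partner))
}

# True-class recovery of the identify -> classify route on a simulated family.
class_recovery <- function(fam) {
  res <- suppressMessages(identify_candidates(fam$records, fam$loci))
  cls <- vapply(res$members$id, function(id)
    assign_class(res$hrab[[id]]$insertion_length)$class_label, character(1))
  truth_cls <- fam$truth$true_class[match(res$members$id, fam$truth$gene_id)]
  list(candidates = res, labels = cls,
       recovered = sum(cls == truth_cls), total = nrow(fam$records))
}

# Scanner false-positive rates on background windows length-matched to the
# printed motifs, drawn from the composition the scanners actually scan
# (polar spacers plus disorder-like flank residues).
scanner_fpr <- function(n_draw, seed) {
  t2 <- hsf_table2()
  lens <- list(nls = nchar(t2$nls[!grepl("[0-9]", t2$nls)]),
               nes = nchar(stats::na.omit(t2$nes)),
               aha = nchar(stats::na.omit(c(t2$aha1, t2$aha2))))
  bgset <- c("S", "T", "N", "Q", "G", "A", "P", "D", "E", "H", "K", "R")
  set.seed(seed)
  fp <- c(nls = 0, nes = 0, aha = 0)
  for (i in seq_len(n_draw)) {
    for (sc in names(fp)) {
      w <- paste(sample(bgset, sample(lens[[sc]], 1), replace = TRUE),
                 collapse = "")
      e <- neutral_embed(w)
      rec <- list(id = "bg", sequence = e$sequence)
      hits <- switch(sc,
                     nls = scan_nls(rec, 1),
                     nes = scan_nes(rec),
                     aha = scan_aha(rec))
      if (any_hit_overlaps(hits, e$start, e$end)) fp[sc] <- fp[sc] + 1
    }
  }
  fp / n_draw
}

# Best window score of a sequence against a profile (internal scan kernel).
profile_best_score <- function(s, prof) {
  max(hsfminer:::profile_scan_cpp(hsfminer:::aa_encode(s), prof$log_odds))
}

# Random peptide from the background composition.
random_peptide <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}
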