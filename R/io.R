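#' Protein record table
#'
#' Constructs the table of protein records used throughout the pipeline:
#' one row per protein with `id`, `sequence` (uppercase, 20-letter alphabet
#' plus X) and free-text `description`.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param description optional character vector of descriptions.
#' @return a `data.frame` with class `protein_records`.
#' @export
protein_records <- function(id, sequence, description = "") {
  if (length(id) != length(sequence)) stop("id and sequence lengths differ")
  if (anyDuplicated(id)) stop("duplicate record ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- vapply(seq_along(sequence), function(i)
    aa_check(sequence[i], paste0("record '", id[i], "'")), character(1))
  out <- data.frame(id = as.character(id), sequence = sequence,
                    description = rep_len(as.character(description), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' Sequences are uppercased; gap (`-`, `.`) and stop (`*`) characters are
#' stripped with a warning. Records containing residues outside the accepted
#' alphabet (20 standard amino acids plus X) are rejected with a warning and
#' dropped; ambiguity codes B/Z/U are not accepted.
#'
#' @param path path to a FASTA file.
#' @return a [protein_records()] table, one row per FASTA entry in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- toupper(as.character(set))
  if (any(grepl("[-.*]", seqs))) {
    warning("gap/stop characters stripped from ",
            sum(grepl("[-.*]", seqs)), " record(s)")
    seqs <- gsub("[-.*]", "", seqs)
  }
  ok <- vapply(seqs, function(s) nzchar(s) && !grepl(paste0("[^", paste(AA21, collapse = ""), "]"), s),
               logical(1), USE.NAMES = FALSE)
  if (any(!ok))
    warning("rejected ", sum(!ok), " record(s) with illegal residues or empty sequence: ",
            paste(id[!ok], collapse = ", "))
  if (!any(ok)) stop("no valid records in FASTA file: ", path)
  protein_records(id[ok], seqs[ok], desc[ok])
}

#' Write protein records to FASTA
#'
#' @param records a [protein_records()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene locus table
#'
#' Expects a TSV with header columns `gene_id`, `chromosome`, `start`,
#' `strand` (`+`, `-` or `unknown`). Start positions are 1-based.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` of loci; zero rows for a header-only table.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("locus table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "chromosome", "start", "strand")
  if (!all(need %in% names(tab)))
    stop("locus table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  if (nrow(tab) == 0) return(tab)
  tab$start <- suppressWarnings(as.numeric(tab$start))
  if (anyNA(tab$start) || any(tab$start < 1) || any(tab$start != floor(tab$start)))
    stop("malformed start position: must be an integer >= 1")
  tab$start <- as.integer(tab$start)
  if (any(!nzchar(tab$chromosome))) stop("empty chromosome label")
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id rows: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  bad <- !tab$strand %in% c("+", "-", "unknown")
  if (any(bad)) stop("malformed strand value: ", paste(unique(tab$strand[bad]), collapse = ", "))
  tab
}

#' 1-based inclusive residue interval
#'
#' All residue coordinates in the package are 1-based and inclusive, the
#' notation used for domain tables such as "41-134".
#'
#' @param start,end integer positions, `1 <= start <= end`.
#' @return named integer vector `c(start, end)`.
#' @export
interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start)
    stop("invalid interval: need 1 <= start <= end, got [", start, ", ", end, "]")
  c(start = start, end = end)
}

interval_length <- function(iv) unname(iv["end"] - iv["start"] + 1L)

#' Write the per-member annotation and duplicate-pair report tables
#'
#' Serializes the family annotation (domain-table layout: class, DBD, OD,
#' linker, NLS/NES/AHA) and the duplicate-pair table as deterministic TSVs:
#' identical input yields byte-identical files.
#'
#' @param annotations list of annotations from [annotate_member()].
#' @param pairs data.frame of duplicate pairs from [find_duplicate_pairs()]
#'   (may have zero rows).
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths, invisibly.
#' @export
write_family_report <- function(annotations, pairs, dir) {
  if (length(annotations) == 0) stop("annotations must be non-empty")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann_tab <- annotation_table(annotations)
  f1 <- file.path(dir, "member_annotations.tsv")
  f2 <- file.path(dir, "duplicate_pairs.tsv")
  write_tsv_det(ann_tab, f1)
  ptab <- if (is.null(pairs) || nrow(pairs) == 0) {
    data.frame(id_a = character(0), id_b = character(0),
               coverage = numeric(0), similarity = numeric(0),
               event = character(0))
  } else {
    p <- pairs[, c("id_a", "id_b", "coverage", "similarity", "event")]
    p$coverage <- sprintf("%.4f", p$coverage)
    p$similarity <- sprintf("%.4f", p$similarity)
    p
  }
  write_tsv_det(ptab, f2)
  invisible(c(f1, f2))
}

# Deterministic TSV writer (fixed eol, no quoting surprises).
write_tsv_det <- function(tab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con, sep = "\n")
  if (nrow(tab) > 0) {
    rows <- do.call(paste, c(lapply(tab, as.character), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Write a phylogenetic tree to newick
#'
#' Branch lengths are kept; per-edge bootstrap supports (if present as
#' `node.label`) become internal node labels. The output re-parses with
#' [ape::read.tree()].
#'
#' @param tree an [ape::phylo] tree with >= 2 uniquely labeled leaves.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 leaves")
  if (any(!nzchar(tree$tip.label)) || anyNA(tree$tip.label))
    stop("all leaves must be labeled")
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  ape::write.tree(tree, file = path)
  invisible(path)
}

## ---- bundled fixtures (printed reference tables) ------------------------

fixture_path <- function(fname) {
  p <- system.file("extdata", fname, package = "hsfminer")
  if (!nzchar(p)) stop("fixture not found: ", fname)
  p
}

#' Bundled reference tables for the 25-member maize Hsf family
#'
#' `hsf_table1()` returns the published per-protein summary (accession, size,
#' molecular weight, pI, chromosome); `hsf_table2()` the published domain and
#' motif table (class group, DBD and OD intervals, NLS/NES/AHA strings with
#' their printed 1-based start positions); `hsf_meme_motifs()` the published
#' MEME consensus motifs (read-only fixture; motif 1 is the DBD core
#' consensus). `hsf_table1_loci()` returns the chromosome placement as a
#' locus table (start positions are ordinal ranks along each chromosome,
#' since only the ordering is published).
#'
#' @return a `data.frame`.
#' @export
hsf_table1 <- function() {
  utils::read.delim(fixture_path("table1_zmhsf.tsv"), stringsAsFactors = FALSE)
}

#' @rdname hsf_table1
#' @export
hsf_table1_loci <- function() read_locus_table(fixture_path("table1_loci.tsv"))

#' @rdname hsf_table1
#' @export
hsf_table2 <- function() {
  utils::read.delim(fixture_path("table2_domains.tsv"), stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' @rdname hsf_table1
#' @export
hsf_meme_motifs <- function() {
  utils::read.delim(fixture_path("table3_motifs.tsv"), stringsAsFactors = FALSE)
}

#' DBD consensus and extended template
#'
#' `hsf_dbd_consensus()` is the 52-residue DBD core consensus (motif 1 of the
#' bundled MEME table). `hsf_dbd_template()` extends it with fixed flanking
#' stretches to 95 residues, the approximate span of the full Hsf DNA-binding
#' domain; the extended template is the default profile source and the
#' synthetic generator's DBD seed.
#'
#' @return a single string.
#' @export
hsf_dbd_consensus <- function() {
  m <- hsf_meme_motifs()
  m$consensus[m$motif == 1]
}

#' @rdname hsf_dbd_consensus
#' @export
hsf_dbd_template <- function() {
  # Fixed flanks modeled on the N-terminal beta-strand / C-terminal cap that
  # surround the core helix-turn-helix consensus in plant Hsf DBDs.
  paste0("DPAPFLTKTYDMVDDPSTDAV", hsf_dbd_consensus(), "DFSNEYFKRGRPDLLVNI")
}
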