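## End-to-end orchestration of the family-mining pipeline.

#' Pipeline configuration
#'
#' Collects inputs (in-memory tables or file paths), stage thresholds and
#' the seed into one validated object. Either `records`/`loci` or
#' `fasta`/`locus_file` must be given.
#'
#' @param records a [protein_records()] table (or `NULL` to read `fasta`).
#' @param loci a locus table (or `NULL` to read `locus_file`).
#' @param fasta,locus_file input file paths (used when tables are `NULL`).
#' @param out_dir output directory for the artifact bundle.
#' @param profile scanning profile (default [hsf_dbd_profile()]).
#' @param threshold profile score threshold (`NULL` = 0.6 x consensus).
#' @param coverage,similarity duplication criteria (defaults 0.8 / 0.7).
#' @param bootstrap_reps bootstrap replicates for the tree (default 1000).
#' @param min_support subclass support threshold (default 50).
#' @param outgroup optional outgroup id for rooting (added from
#'   `reference_records` if not among the members).
#' @param reference_records optional labeled reference [protein_records()].
#' @param reference_labels named vector tip -> subclass for the references.
#' @param ct_table optional Ct table for the expression stage.
#' @param reference_gene,calibrator_condition expression-stage settings.
#' @param seed master RNG seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(records = NULL, loci = NULL, fasta = NULL,
                            locus_file = NULL, out_dir,
                            profile = NULL, threshold = NULL,
                            coverage = 0.8, similarity = 0.7,
                            bootstrap_reps = 1000, min_support = 50,
                            outgroup = NULL, reference_records = NULL,
                            reference_labels = NULL, ct_table = NULL,
                            reference_gene = "Actin1",
                            calibrator_condition = "control", seed = 1L) {
  if (is.null(records)) {
    if (is.null(fasta)) stop("either records or fasta must be given")
    if (!file.exists(fasta)) stop("FASTA not found: ", fasta)
  }
  if (is.null(loci)) {
    if (is.null(locus_file)) stop("either loci or locus_file must be given")
    if (!file.exists(locus_file)) stop("locus table not found: ", locus_file)
  }
  structure(list(records = records, loci = loci, fasta = fasta,
                 locus_file = locus_file, out_dir = out_dir,
                 profile = profile, threshold = threshold,
                 coverage = coverage, similarity = similarity,
                 bootstrap_reps = bootstrap_reps, min_support = min_support,
                 outgroup = outgroup, reference_records = reference_records,
                 reference_labels = reference_labels, ct_table = ct_table,
                 reference_gene = reference_gene,
                 calibrator_condition = calibrator_condition,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the family-mining pipeline end to end
#'
#' Executes identify, annotate, duplications, tree (with optional rooting
#' and subclass assignment), physicochemical summary and (optionally)
#' relative expression; writes the report tables, the newick tree and a run
#' log into `out_dir`. The same config and seed always reproduce the bundle
#' byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results: `candidates`,
#'   `annotations`, `pairs`, `tree`, `subclasses`, `physchem`,
#'   `expression`, and the output `files`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c("hsfminer pipeline run",
                 paste0("seed: ", config$seed),
                 paste0("coverage/similarity: ", config$coverage, "/", config$similarity),
                 paste0("bootstrap replicates: ", config$bootstrap_reps),
                 paste0("min subclass support: ", config$min_support))

  records <- stage("input", {
    if (is.null(config$records)) read_fasta(config$fasta) else config$records
  })
  loci <- stage("input", {
    if (is.null(config$loci)) read_locus_table(config$locus_file) else config$loci
  })
  profile <- if (is.null(config$profile)) hsf_dbd_profile() else config$profile

  cand <- stage("identify", suppressMessages(
    identify_candidates(records, loci, profile, config$threshold)))
  log_lines <- c(log_lines,
                 paste0("identify: ", nrow(records), " candidates -> ",
                        nrow(cand$members), " members (dropped ",
                        cand$drop_counts["no_dbd"], " no-DBD, ",
                        cand$drop_counts["same_locus"], " same-locus, ",
                        cand$drop_counts["no_coiled_coil"], " no-coiled-coil)"))
  if (nrow(cand$members) == 0) stop("pipeline stage 'identify' retained no members")

  annotations <- stage("annotate", {
    suppressWarnings(lapply(cand$members$id, function(id)
      annotate_member(cand$members[cand$members$id == id, ],
                      cand$domain_hits[[id]], cand$hrab[[id]])))
  })
  names(annotations) <- cand$members$id

  pairs <- stage("duplications",
                 find_duplicate_pairs(cand$members, loci,
                                      coverage = config$coverage,
                                      similarity = config$similarity))
  log_lines <- c(log_lines, paste0("duplications: ", nrow(pairs), " pairs (",
                                   sum(pairs$event == "segmental"), " segmental, ",
                                   sum(pairs$event == "tandem"), " tandem)"))

  files <- write_family_report(annotations, pairs, config$out_dir)

  # tree on N-terminal regions (members plus optional labeled references)
  tree <- NULL; subclasses <- NULL
  nseq <- setNames(
    vapply(cand$members$id, function(id)
      extract_nterminal(annotations[[id]], cand$members[cand$members$id == id, ]),
      character(1)), cand$members$id)
  if (!is.null(config$reference_records))
    nseq <- c(nseq, setNames(config$reference_records$sequence,
                             config$reference_records$id))
  if (length(nseq) >= 3) {
    tree <- stage("tree", {
      msa <- progressive_align(nseq)
      bootstrap_support(msa, n_reps = config$bootstrap_reps,
                        seed = derive_seed(config$seed, "bootstrap"))
    })
    if (!is.null(config$outgroup) && config$outgroup %in% tree$tip.label)
      tree <- stage("tree", root_with_outgroup(tree, config$outgroup))
    tf <- file.path(config$out_dir, "tree.nwk")
    write_newick(tree, tf)
    files <- c(files, tf)
    if (!is.null(config$reference_labels))
      subclasses <- stage("subclass",
                          assign_subclass(tree, config$reference_labels,
                                          config$min_support))
    log_lines <- c(log_lines, paste0("tree: ", length(nseq), " leaves, ",
                                     config$bootstrap_reps, " bootstrap replicates"))
  } else {
    log_lines <- c(log_lines, "tree: skipped (fewer than 3 sequences)")
  }

  pc <- stage("physchem", physicochemical_properties(cand$members))
  pcf <- file.path(config$out_dir, "physchem.tsv")
  pc_out <- pc
  pc_out$mw <- sprintf("%.2f", pc_out$mw)
  pc_out$pi <- sprintf("%.2f", pc_out$pi)
  write_tsv_det(pc_out, pcf)
  files <- c(files, pcf)

  expression <- NULL
  if (!is.null(config$ct_table)) {
    expression <- stage("expression",
                        relative_expression(config$ct_table,
                                            config$reference_gene,
                                            config$calibrator_condition))
    ef <- file.path(config$out_dir, "expression.tsv")
    eo <- expression
    eo$fold_change <- ifelse(is.na(eo$fold_change), "NA",
                             sprintf("%.4f", eo$fold_change))
    write_tsv_det(eo, ef)
    files <- c(files, ef)
    log_lines <- c(log_lines,
                   paste0("expression: ", sum(expression$category == "up", na.rm = TRUE),
                          " up, ", sum(expression$category == "down", na.rm = TRUE),
                          " down, ",
                          sum(expression$category == "unchanged", na.rm = TRUE),
                          " unchanged, ",
                          sum(expression$category == "not_expressed", na.rm = TRUE),
                          " not expressed"))
  }

  writeLines(log_lines, logf)
  files <- c(files, logf)
  invisible(list(candidates = cand, annotations = annotations, pairs = pairs,
                 tree = tree, subclasses = subclasses, physchem = pc,
                 expression = expression, files = files))
}
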