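#' Configuration for the synthetic Hsf family generator
#'
#' Defaults reproduce the published family's study conditions: 25 members
#' split 15/7/3 over classes A/B/C, insertions of 21/0/7 residues between
#' HR-A and HR-B, class-typical linker ranges (A: 9-39, B: 50-78, C: 14-49),
#' and 9 duplicated gene pairs (one tandem, the rest segmental). The DBD seed
#' is the bundled extended DBD consensus template mutated at `dbd_noise` per
#' site. Flanks, linkers, insertions and spacers are drawn from a neutral
#' polar alphabet so that every embedded feature is the only signal of its
#' kind in the sequence.
#'
#' @param n_per_class named counts for classes A, B, C.
#' @param insertion_by_class named insertion lengths (must be distinct).
#' @param linker_range_by_class list of `c(min, max)` linker lengths.
#' @param dbd_template DBD seed string.
#' @param dbd_noise per-site substitution probability applied to the template.
#' @param n_duplicate_pairs planted duplicate pairs (pair members count
#'   toward `n_per_class`; the first planted pair is tandem).
#' @param duplicate_divergence per-site substitution probability between
#'   duplicate partners.
#' @param duplicate_indel_rate per-eligible-site Poisson rate of short
#'   (1-3 residue) indels, confined to the terminal flanks.
#' @param motif_templates NLS/NES/AHA seed strings; a digit inside an NLS
#'   template is expanded to that many polar spacer residues (bipartite form).
#' @param flank_length_range range of terminal flank lengths.
#' @param seed RNG seed; each record derives its own stream from
#'   `(seed, id)`, so adding records never perturbs existing ones.
#' @return a list of class `family_sim_config`.
#' @export
family_sim_config <- function(n_per_class = c(A = 15L, B = 7L, C = 3L),
                              insertion_by_class = CLASS_INSERTION,
                              linker_range_by_class = LINKER_RANGE,
                              dbd_template = hsf_dbd_template(),
                              dbd_noise = 0.08,
                              n_duplicate_pairs = 9L,
                              duplicate_divergence = 0.05,
                              duplicate_indel_rate = 0.01,
                              motif_templates = list(
                                nls = c("RKRRR", "KRK7KKRRR", "KKRRR", "SKKRR"),
                                nes = c("LENLALNI", "LDVLTLSV", "VRQLDLGL"),
                                aha = c("DDFWEELLNE", "DSFWEQFL", "DVFWERFLTD")),
                              flank_length_range = c(20L, 150L),
                              seed = 20110127L) {
  stopifnot(all(c("A", "B", "C") %in% names(n_per_class)),
            all(n_per_class >= 0), sum(n_per_class) > 0)
  if (anyDuplicated(insertion_by_class))
    stop("insertion lengths must be distinct between classes")
  if (dbd_noise < 0 || dbd_noise > 1) stop("dbd_noise must be in [0,1]")
  if (duplicate_divergence < 0 || duplicate_divergence >= 1)
    stop("duplicate_divergence must be in [0,1)")
  structure(list(n_per_class = n_per_class,
                 insertion_by_class = insertion_by_class,
                 linker_range_by_class = linker_range_by_class,
                 dbd_template = dbd_template, dbd_noise = dbd_noise,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 duplicate_divergence = duplicate_divergence,
                 duplicate_indel_rate = duplicate_indel_rate,
                 motif_templates = motif_templates,
                 flank_length_range = as.integer(flank_length_range),
                 seed = as.integer(seed)),
            class = "family_sim_config")
}

rand_polar <- function(n) paste(sample(POLAR_NEUTRAL, n, replace = TRUE), collapse = "")

rand_flank <- function(n) paste(sample(DISORDER_SET, n, replace = TRUE), collapse = "")

rand_heptads <- function(k) {
  paste(vapply(seq_len(k), function(i) {
    h <- sample(POLAR_NEUTRAL, 7, replace = TRUE)
    h[1] <- sample(c("L", "I", "V", "M"), 1)
    h[4] <- sample(c("L", "I", "V", "M"), 1)
    paste(h, collapse = "")
  }, character(1)), collapse = "")
}

mutate_string <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- aa_chars(s)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  paste(ch, collapse = "")
}

expand_nls_template <- function(tmpl) {
  # A digit inside the template is a bipartite spacer length.
  m <- regmatches(tmpl, regexpr("[0-9]+", tmpl))
  if (length(m) == 0) return(tmpl)
  parts <- strsplit(tmpl, "[0-9]+")[[1]]
  paste0(parts[1], rand_polar(as.integer(m)), parts[2])
}

#' Simulate an Hsf-like protein family with full ground truth
#'
#' Each member is assembled as flank - DBD (noisy template copy) - linker
#' (class-sampled length) - HR-A (3 heptads, hydrophobic a/d positions) -
#' insertion (class-specific length, polar) - HR-B (2 heptads) - spacer -
#' NLS - spacer - optional NES - optional AHA motifs (class A only) - flank.
#' Duplicate pairs are planted by replacing a class-mate with a diverged copy
#' of a donor member (substitutions genome-wide, with heptad a/d positions
#' constrained to the hydrophobic set; indels only in the terminal flanks so
#' ground-truth coordinates shift by a computable offset).
#'
#' The same seed always yields byte-identical output.
#'
#' @param config a [family_sim_config()].
#' @return list with `records` ([protein_records()]), `loci` (locus table)
#'   and `truth` (data.frame of true class, feature coordinates, motif
#'   strings and duplicate partner per member).
#' @export
simulate_family <- function(config = family_sim_config()) {
  classes <- c("A", "B", "C")
  ids <- unlist(lapply(classes, function(cl)
    sprintf("Sim%s-%02d", cl, seq_len(config$n_per_class[[cl]]))))
  cls_of <- unlist(lapply(classes, function(cl)
    rep(cl, config$n_per_class[[cl]])))
  n <- length(ids)

  built <- vector("list", n)
  for (i in seq_len(n))
    built[[i]] <- with_seed(derive_seed(config$seed, ids[i]),
                            build_member(ids[i], cls_of[i], config))

  # chromosome placement: members spread over chromosomes 1-10 round-robin
  loci <- data.frame(gene_id = ids,
                     chromosome = as.character(rep_len(1:10, n)),
                     start = as.integer(1e6 + (seq_len(n) - 1L) * 997000L),
                     strand = "+", stringsAsFactors = FALSE)

  partner <- setNames(rep(NA_character_, n), ids)
  if (config$n_duplicate_pairs > 0) {
    free <- split(seq_len(n), factor(cls_of, levels = classes))
    plan <- list()
    ci <- 0L
    while (length(plan) < config$n_duplicate_pairs) {
      if (all(vapply(free, length, integer(1)) < 2))
        stop("not enough members to plant ", config$n_duplicate_pairs,
             " duplicate pairs")
      ci <- ci + 1L
      cl <- classes[(ci - 1L) %% 3L + 1L] # round-robin over classes
      if (length(free[[cl]]) < 2) next
      donor <- free[[cl]][1]
      target <- free[[cl]][length(free[[cl]])]
      free[[cl]] <- setdiff(free[[cl]], c(donor, target))
      plan[[length(plan) + 1L]] <- c(donor, target)
    }
    for (p in seq_along(plan)) {
      donor <- plan[[p]][1]; target <- plan[[p]][2]
      built[[target]] <- duplicate_member(built[[donor]], ids[target], config,
                                          derive_seed(config$seed, paste0("dup-", ids[target])))
      partner[ids[donor]] <- ids[target]
      partner[ids[target]] <- ids[donor]
      if (p == 1) { # tandem: same chromosome, nearby start
        loci$chromosome[target] <- loci$chromosome[donor]
        loci$start[target] <- loci$start[donor] + 50000L
      } else if (loci$chromosome[target] == loci$chromosome[donor]) {
        loci$chromosome[target] <-
          as.character((as.integer(loci$chromosome[donor])) %% 10L + 1L)
      }
    }
  }

  records <- protein_records(ids, vapply(built, `[[`, character(1), "sequence"))
  truth <- do.call(rbind, lapply(built, `[[`, "truth"))
  truth$duplicate_partner <- unname(partner[truth$gene_id])
  rownames(truth) <- NULL
  list(records = records, loci = loci, truth = truth)
}

# Assemble one member; returns sequence plus the truth row.
build_member <- function(id, cl, config) {
  fl <- config$flank_length_range
  flank1 <- rand_flank(sample(fl[1]:fl[2], 1))
  dbd <- mutate_string(config$dbd_template, config$dbd_noise)
  lr <- config$linker_range_by_class[[cl]]
  linker <- rand_flank(sample(lr[1]:lr[2], 1))
  hra <- rand_heptads(3L)
  ins_len <- config$insertion_by_class[[cl]]
  insertion <- if (ins_len > 0) rand_polar(ins_len) else ""
  hrb <- rand_heptads(2L)
  spacer1 <- rand_polar(sample(8:15, 1))
  nls <- expand_nls_template(sample(config$motif_templates$nls, 1))
  spacer2 <- rand_polar(sample(5:15, 1))
  has_nes <- stats::runif(1) < 0.5
  nes <- if (has_nes) sample(config$motif_templates$nes, 1) else ""
  spacer3 <- if (has_nes) rand_polar(sample(5:12, 1)) else ""
  n_aha <- if (cl == "A") sample(1:2, 1) else 0L
  aha <- if (n_aha > 0) sample(config$motif_templates$aha, n_aha) else character(0)
  aha_sp <- if (n_aha == 2) rand_polar(sample(5:12, 1)) else ""
  flank2 <- rand_flank(sample(fl[1]:fl[2], 1))

  parts <- c(flank1, dbd, linker, hra, insertion, hrb, spacer1, nls, spacer2,
             nes, spacer3,
             if (n_aha >= 1) aha[1] else "", aha_sp,
             if (n_aha == 2) aha[2] else "", flank2)
  seqs <- paste(parts, collapse = "")
  off <- cumsum(c(0L, nchar(parts)))
  pos <- function(k) off[k] + 1L # 1-based start of part k
  truth <- data.frame(
    gene_id = id, true_class = cl,
    dbd_start = pos(2), dbd_end = off[3],
    linker_length = nchar(linker),
    hra_start = pos(4), hra_end = off[5],
    insertion_length = ins_len,
    hrb_start = pos(6), hrb_end = off[7],
    nls_pos = pos(8), nls = nls,
    nes_pos = if (has_nes) pos(10) else NA_integer_,
    nes = if (has_nes) nes else NA_character_,
    aha1_pos = if (n_aha >= 1) pos(12) else NA_integer_,
    aha1 = if (n_aha >= 1) aha[1] else NA_character_,
    aha2_pos = if (n_aha == 2) pos(14) else NA_integer_,
    aha2 = if (n_aha == 2) aha[2] else NA_character_,
    stringsAsFactors = FALSE)
  list(sequence = seqs, truth = truth, flank1_len = nchar(flank1),
       seq_len = nchar(seqs))
}

# Indel-eligible terminal flanks: everything before the DBD and everything
# after the last embedded feature.
flank_regions <- function(tr, seq_len) {
  last_feat <- max(c(tr$nls_pos + nchar(tr$nls) - 1L,
                     if (!is.na(tr$nes)) tr$nes_pos + nchar(tr$nes) - 1L,
                     if (!is.na(tr$aha1)) tr$aha1_pos + nchar(tr$aha1) - 1L,
                     if (!is.na(tr$aha2)) tr$aha2_pos + nchar(tr$aha2) - 1L))
  regs <- rbind(c(1L, tr$dbd_start - 1L))
  if (last_feat + 1L < seq_len) regs <- rbind(regs, c(last_feat + 1L, seq_len))
  regs
}

# Diverged copy of a donor member under purifying selection on the heptad
# register; truth coordinates shift by the net flank-1 indel length.
duplicate_member <- function(donor, new_id, config, seed) {
  tr <- donor$truth
  ad <- function(start, k) as.vector(outer(c(0L, 3L), 7L * (seq_len(k) - 1L), "+")) + start
  adpos <- c(ad(tr$hra_start, 3L), ad(tr$hrb_start, 2L))
  rec <- protein_records(new_id, donor$sequence)
  mut <- mutate_duplicate(rec, divergence = config$duplicate_divergence,
                          seed = seed,
                          constrained = list(list(positions = adpos,
                                                  allowed = c("L", "I", "V", "M"))),
                          indel_rate = config$duplicate_indel_rate,
                          indel_regions = flank_regions(tr, donor$seq_len))
  indels <- attr(mut, "indels")
  offset <- 0L
  if (!is.null(indels) && nrow(indels) > 0) {
    pre <- indels[indels$pos < tr$dbd_start, , drop = FALSE]
    if (nrow(pre) > 0)
      offset <- sum(ifelse(pre$type == "ins", pre$len, -pre$len))
  }
  seqs <- mut$sequence
  shift <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x + offset))
  t2 <- tr
  t2$gene_id <- new_id
  for (col in c("dbd_start", "dbd_end", "hra_start", "hra_end", "hrb_start",
                "hrb_end", "nls_pos", "nes_pos", "aha1_pos", "aha2_pos"))
    t2[[col]] <- shift(t2[[col]])
  sub_at <- function(p, s) if (is.na(p)) NA_character_ else substr(seqs, p, p + nchar(s) - 1L)
  t2$nls <- sub_at(t2$nls_pos, tr$nls)
  t2$nes <- if (is.na(tr$nes)) NA_character_ else sub_at(t2$nes_pos, tr$nes)
  t2$aha1 <- if (is.na(tr$aha1)) NA_character_ else sub_at(t2$aha1_pos, tr$aha1)
  t2$aha2 <- if (is.na(tr$aha2)) NA_character_ else sub_at(t2$aha2_pos, tr$aha2)
  list(sequence = seqs, truth = t2, flank1_len = donor$flank1_len + offset,
       seq_len = nchar(seqs))
}

#' Apply controlled divergence to a protein record
#'
#' Substitutions are i.i.d. per site with probability `divergence`; the
#' replacement is uniform over the other 19 residues, except at
#' caller-`constrained` sites where it is resampled within the allowed set
#' (e.g. heptad a/d positions stay hydrophobic). Short indels (1-3 residues,
#' count Poisson with rate `indel_rate` per eligible site) are confined to
#' `indel_regions`. Expected sequence identity is `1 - divergence`. Note the
#' operation does not compose: applying divergence d twice is not equivalent
#' to applying 2d once (back-substitutions occur).
#'
#' @param record one-row [protein_records()] table.
#' @param divergence substitution probability in `[0, 1)`.
#' @param seed RNG seed.
#' @param constrained list of `list(positions =, allowed =)` site constraints.
#' @param indel_rate Poisson rate per eligible site (0 disables indels).
#' @param indel_regions matrix of `c(start, end)` rows eligible for indels.
#' @return a one-row [protein_records()] table; attribute `"indels"` logs
#'   applied indels (`pos` in original coordinates, `type`, `len`).
#' @export
mutate_duplicate <- function(record, divergence, seed, constrained = NULL,
                             indel_rate = 0, indel_regions = NULL) {
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0,1)")
  rec <- as_record(record)
  ch <- aa_chars(aa_check(rec$sequence))
  n <- length(ch)
  allowed_of <- rep(list(NULL), n)
  for (cs in constrained)
    for (p in cs$positions) if (p >= 1 && p <= n) allowed_of[[p]] <- cs$allowed
  indel_log <- data.frame(pos = integer(0), type = character(0), len = integer(0))
  with_seed(seed, {
    hit <- which(stats::runif(n) < divergence)
    for (i in hit) {
      pool <- if (is.null(allowed_of[[i]])) AA20 else allowed_of[[i]]
      pool <- setdiff(pool, ch[i])
      if (length(pool) > 0) ch[i] <- sample(pool, 1)
    }
    site <- ch # per-original-site text; "" = deleted, may grow by insertion
    if (indel_rate > 0 && !is.null(indel_regions) && nrow(indel_regions) > 0) {
      elig <- sum(indel_regions[, 2] - indel_regions[, 1] + 1)
      k <- stats::rpois(1, indel_rate * elig)
      for (e in seq_len(k)) {
        ri <- sample(nrow(indel_regions), 1,
                     prob = indel_regions[, 2] - indel_regions[, 1] + 1)
        r <- indel_regions[ri, ]
        len <- sample(1:3, 1)
        if (stats::runif(1) < 0.5) { # deletion, fully inside the region
          if (r[2] - r[1] + 1 <= len) next
          p <- sample(r[1]:(r[2] - len + 1L), 1)
          site[p:(p + len - 1L)] <- ""
          indel_log <- rbind(indel_log,
                             data.frame(pos = p, type = "del", len = len))
        } else { # insertion after position p
          p <- sample(r[1]:r[2], 1)
          site[p] <- paste0(site[p],
                            paste(sample(AA20, len, replace = TRUE,
                                         prob = AA_BACKGROUND), collapse = ""))
          indel_log <- rbind(indel_log,
                             data.frame(pos = p, type = "ins", len = len))
        }
      }
    }
    out <- protein_records(rec$id, paste(site, collapse = ""))
    attr(out, "indels") <- indel_log
    out
  })
}

#' Simulate decoy proteins for mining-pipeline tests
#'
#' `type = "random"` draws residues from the background composition (no DBD,
#' no coiled-coil); `type = "dbd_only"` embeds a noisy DBD template in polar
#' flanks with no heptad region downstream, the decoy class the coiled-coil
#' filter must remove.
#'
#' @param n number of decoys.
#' @param type decoy construction.
#' @param length_range sequence length range for random decoys.
#' @param dbd_noise template noise for `dbd_only` decoys.
#' @param seed RNG seed.
#' @return a [protein_records()] table with ids `Decoy-01`, ...
#' @export
simulate_decoys <- function(n, type = c("random", "dbd_only"),
                            length_range = c(150L, 500L), dbd_noise = 0.08,
                            seed = 1L) {
  type <- match.arg(type)
  ids <- sprintf("Decoy%s-%02d", if (type == "random") "" else "D", seq_len(n))
  seqs <- vapply(ids, function(id) with_seed(derive_seed(seed, id), {
    if (type == "random") {
      paste(sample(AA20, sample(length_range[1]:length_range[2], 1),
                   replace = TRUE, prob = AA_BACKGROUND), collapse = "")
    } else {
      paste0(rand_polar(30), mutate_string(hsf_dbd_template(), dbd_noise),
             rand_polar(80))
    }
  }), character(1), USE.NAMES = FALSE)
  protein_records(ids, seqs)
}

#' Configuration for the qPCR Ct-table simulator
#'
#' Defaults emulate the published heat-shock experiment: 25 target genes of
#' which 12 are up-regulated more than 2-fold, 5 down-regulated below
#' 0.5-fold, 5 essentially unchanged and 3 not expressed in either
#' condition, with the reference gene (`Actin1`) at fold 1 and three
#' replicates per gene and condition.
#'
#' @param genes gene ids (reference gene appended if absent).
#' @param true_log2_fold named per-gene true log2 fold changes; `NA` marks a
#'   gene with no amplification in either condition.
#' @param reference_gene internal-control gene id.
#' @param ct_baseline baseline Ct in cycles.
#' @param noise_sd per-measurement normal noise, cycles.
#' @param replicates technical replicates per gene x condition.
#' @param seed RNG seed.
#' @return list of class `ct_sim_config`.
#' @export
ct_sim_config <- function(genes = sprintf("Gene-%02d", 1:25),
                          true_log2_fold = NULL,
                          reference_gene = "Actin1",
                          ct_baseline = 24, noise_sd = 0.25,
                          replicates = 3L, seed = 20110127L) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(true_log2_fold)) {
    stopifnot(length(genes) >= 25)
    true_log2_fold <- setNames(rep(0, length(genes)), genes)
    true_log2_fold[1:12] <- seq(1.5, 6, length.out = 12) # > 2-fold up
    true_log2_fold[13:17] <- seq(-3, -1.2, length.out = 5) # < 0.5-fold down
    true_log2_fold[18:22] <- c(-0.2, 0.1, 0, 0.3, -0.4) # unchanged
    true_log2_fold[23:25] <- NA # not expressed
  }
  if (!reference_gene %in% genes) genes <- c(genes, reference_gene)
  if (!reference_gene %in% names(true_log2_fold)) {
    true_log2_fold[reference_gene] <- 0
  } else if (!is.na(true_log2_fold[reference_gene]) &&
             true_log2_fold[reference_gene] != 0) {
    warning("reference gene fold forced to 0")
    true_log2_fold[reference_gene] <- 0
  }
  structure(list(genes = genes, true_log2_fold = true_log2_fold,
                 reference_gene = reference_gene, ct_baseline = ct_baseline,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "ct_sim_config")
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' `Ct(gene, condition, rep) = baseline - true_log2_fold * [treated] +
#' N(0, noise_sd)`. Genes with `NA` fold are emitted with `NA` Ct (the
#' no-amplification sentinel) in both conditions.
#'
#' @param config a [ct_sim_config()].
#' @return data.frame with columns `gene`, `condition`
#'   (`control`/`treated`), `replicate`, `ct`.
#' @export
simulate_ct_table <- function(config = ct_sim_config()) {
  if (!config$reference_gene %in% config$genes) stop("reference gene missing")
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      condition = c("control", "treated"),
                      gene = config$genes, stringsAsFactors = FALSE)[, 3:1]
  with_seed(config$seed, {
    fold <- config$true_log2_fold[grid$gene]
    ct <- config$ct_baseline - ifelse(grid$condition == "treated", fold, 0) +
      stats::rnorm(nrow(grid), 0, config$noise_sd)
    grid$ct <- ifelse(is.na(fold), NA_real_, ct)
    grid
  })
}
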