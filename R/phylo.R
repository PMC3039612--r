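## Neighbor-joining phylogeny of N-terminal Hsf regions with
## Poisson-corrected pairwise-deletion distances and bootstrap support.

#' Extract the N-terminal region used for tree building
#'
#' Returns the residues from the DBD start through the HR-B end: the
#' DNA-binding domain, the linker and the full HR-A/B region - the conserved
#' N-terminal module on which family phylogenies are built.
#'
#' @param annotation an `hsf_annotation` (or any list with `dbd` and `hrb`
#'   intervals).
#' @param record the corresponding protein record.
#' @return the subsequence as a string.
#' @export
extract_nterminal <- function(annotation, record) {
  if (is.null(annotation$dbd) || is.null(annotation$hrb))
    stop("annotation lacks DBD and/or HR-A/B coordinates")
  rec <- as_record(record)
  substr(rec$sequence, annotation$dbd["start"], annotation$hrb["end"])
}

## ---- progressive multiple alignment -------------------------------------

kmer_sets <- function(seqs, k = 3) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment: a UPGMA guide tree on k-mer (k = 3)
#' Jaccard distances drives profile-profile Needleman-Wunsch merges under
#' BLOSUM62 with affine gaps. All tie-breaks (guide-tree joins, merge
#' orientation, traceback) are canonical in the sequence ids, so permuting
#' the input yields the same alignment up to row order.
#'
#' @param sequences named character vector (>= 2) or [protein_records()].
#' @param gap_open,gap_extend affine gap penalties for the profile merges.
#' @return named character vector of equal-length gapped rows, in input
#'   order; class `msa`.
#' @export
progressive_align <- function(sequences, gap_open = 10, gap_extend = 0.5) {
  if (is.data.frame(sequences)) sequences <- setNames(sequences$sequence, sequences$id)
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  sequences <- vapply(sequences, aa_check, character(1))
  input_order <- names(sequences)

  # UPGMA guide tree on k-mer Jaccard distances, canonical tie-breaks.
  sets <- kmer_sets(sequences)
  n <- length(sequences)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    D[i, j] <- D[j, i] <- 1 - inter / max(uni, 1)
  }
  clusters <- lapply(names(sequences), function(id)
    list(ids = id, aln = setNames(sequences[id], id)))
  names(clusters) <- names(sequences)
  sizes <- setNames(rep(1, n), names(sequences))
  while (length(clusters) > 1) {
    labs <- names(clusters)
    best <- NULL; bd <- Inf
    for (i in seq_len(length(labs) - 1)) for (j in (i + 1):length(labs)) {
      a <- labs[i]; b <- labs[j]
      key <- sort(c(a, b))
      dv <- D[a, b]
      if (dv < bd - 1e-12 ||
          (abs(dv - bd) <= 1e-12 && !is.null(best) &&
           (key[1] < best[1] || (key[1] == best[1] && key[2] < best[2]))))
        { bd <- dv; best <- key }
    }
    a <- best[1]; b <- best[2]
    merged <- merge_alignments(clusters[[a]]$aln, clusters[[b]]$aln,
                               gap_open, gap_extend)
    new_lab <- a # cluster label = lexicographically smallest member id
    others <- setdiff(labs, c(a, b))
    # UPGMA average-linkage update
    for (o in others)
      D[new_lab, o] <- D[o, new_lab] <-
        (D[a, o] * sizes[a] + D[b, o] * sizes[b]) / (sizes[a] + sizes[b])
    sizes[new_lab] <- sizes[a] + sizes[b]
    clusters[[b]] <- NULL
    clusters[[new_lab]] <- list(ids = c(clusters[[a]]$ids, b), aln = merged)
  }
  out <- clusters[[1]]$aln[input_order]
  class(out) <- "msa"
  out
}

# Profile-profile NW merge of two sub-alignments.
merge_alignments <- function(A, B, gap_open, gap_extend) {
  S <- blosum62_matrix()[AA20, AA20]
  pa <- alignment_profile(A)
  pb <- alignment_profile(B)
  C <- pa %*% S %*% t(pb)
  path <- pairdp_cpp(C, gap_open, gap_extend, FALSE)
  ma <- do.call(rbind, strsplit(unname(A), ""))
  mb <- do.call(rbind, strsplit(unname(B), ""))
  La <- length(path$ai)
  outA <- matrix("-", nrow(ma), La)
  outB <- matrix("-", nrow(mb), La)
  outA[, path$ai > 0] <- ma[, path$ai[path$ai > 0], drop = FALSE]
  outB[, path$bi > 0] <- mb[, path$bi[path$bi > 0], drop = FALSE]
  res <- c(apply(outA, 1, paste, collapse = ""),
           apply(outB, 1, paste, collapse = ""))
  setNames(res, c(names(A), names(B)))
}

# Column residue frequencies (gaps carry no mass).
alignment_profile <- function(rows) {
  m <- do.call(rbind, strsplit(unname(rows), ""))
  L <- ncol(m)
  prof <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (r in seq_len(nrow(m))) {
    ok <- m[r, ] %in% AA20
    idx <- cbind(which(ok), match(m[r, ok], AA20))
    prof[idx] <- prof[idx] + 1
  }
  prof / nrow(m)
}

## ---- distances ----------------------------------------------------------

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa), ""))
  if (length(unique(nchar(msa))) != 1) stop("alignment rows differ in length")
  enc <- matrix(match(m, AA21, nomatch = 0L), nrow(m), ncol(m))
  rownames(enc) <- names(msa)
  enc
}

#' Pairwise-deletion p-distances from an alignment
#'
#' For each sequence pair, the proportion of mismatching sites among sites
#' where both rows are ungapped (pairwise deletion).
#'
#' @param msa named character vector of equal-length gapped rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pdistance_pairwise_deletion <- function(msa) {
  enc <- msa_matrix(msa)
  res <- pdist_cpp(enc, seq_len(ncol(enc)))
  p <- res$p
  if (anyNA(p)) stop("sequence pair with zero shared ungapped sites")
  dimnames(p) <- list(rownames(enc), rownames(enc))
  p
}

#' Poisson correction of a p-distance
#'
#' `d = -ln(1 - p)`, the multiple-hit correction under a Poisson model of
#' amino-acid substitution. Vectorized.
#'
#' @param p proportion(s) of differing sites, `0 <= p < 1`.
#' @return corrected distance(s).
#' @export
poisson_correct <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p >= 1))
    stop("p must satisfy 0 <= p < 1")
  -log(1 - p)
}

## ---- neighbor joining ---------------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion and
#' branch-length formulas. Ties on Q are broken by the lexicographically
#' smallest label pair. Negative branch-length estimates are clamped to 0
#' (flagged via the `"clamped"` attribute). Additive distance matrices are
#' reproduced exactly by the tree's path lengths.
#'
#' @param D symmetric distance matrix with unique dimnames (>= 2 taxa;
#'   2 taxa yield a single split edge).
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  labs <- rownames(D)
  if (is.null(labs) || anyDuplicated(labs)) stop("D needs unique dimnames")
  n <- nrow(D)
  if (n < 2) stop("need at least 2 taxa")
  clamped <- FALSE
  # subtree newick fragments, keyed by active label (smallest member leaf)
  frag <- setNames(sprintf("%s", labs), labs)
  act <- labs
  clamp <- function(x) { if (x < 0) { clamped <<- TRUE; 0 } else x }
  while (length(act) > 3) {
    r <- length(act)
    Dm <- D[act, act]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    best <- NULL; bq <- Inf
    for (i in seq_len(r - 1)) for (j in (i + 1):r) {
      key <- sort(c(act[i], act[j]))
      if (Q[i, j] < bq - 1e-12 ||
          (abs(Q[i, j] - bq) <= 1e-12 && !is.null(best) &&
           (key[1] < best[1] || (key[1] == best[1] && key[2] < best[2]))))
        { bq <- Q[i, j]; best <- key }
    }
    a <- best[1]; b <- best[2]
    va <- clamp(D[a, b] / 2 + (R[a] - R[b]) / (2 * (r - 2)))
    vb <- clamp(D[a, b] - (D[a, b] / 2 + (R[a] - R[b]) / (2 * (r - 2))))
    newf <- sprintf("(%s:%.10g,%s:%.10g)", frag[a], va, frag[b], vb)
    others <- setdiff(act, c(a, b))
    newd <- (D[a, others] + D[b, others] - D[a, b]) / 2
    u <- a # reuse label slot
    D[u, others] <- newd; D[others, u] <- newd; D[u, u] <- 0
    frag[u] <- newf
    act <- c(u, others)
  }
  if (length(act) == 3) {
    a <- act[1]; b <- act[2]; c3 <- act[3]
    va <- clamp((D[a, b] + D[a, c3] - D[b, c3]) / 2)
    vb <- clamp((D[a, b] + D[b, c3] - D[a, c3]) / 2)
    vc <- clamp((D[a, c3] + D[b, c3] - D[a, b]) / 2)
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   frag[a], va, frag[b], vb, frag[c3], vc)
  } else { # 2 taxa: one edge, split at its midpoint
    a <- act[1]; b <- act[2]
    nwk <- sprintf("(%s:%.10g,%s:%.10g);",
                   frag[a], D[a, b] / 2, frag[b], D[a, b] / 2)
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

## ---- bootstrap ----------------------------------------------------------

# Leaf sets per internal node (node number -> tip labels).
node_tipsets <- function(phy) {
  n <- length(phy$tip.label)
  nn <- phy$Nnode
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  # process internal nodes in decreasing order (children before parents in
  # ape's numbering is not guaranteed, so iterate until stable)
  todo <- as.integer(names(kids))
  remaining <- todo
  while (length(remaining) > 0) {
    prog <- FALSE
    for (nd in remaining) {
      ch <- kids[[as.character(nd)]]
      if (all(!vapply(sets[ch], is.null, logical(1)))) {
        sets[[nd]] <- sort(unlist(sets[ch]))
        remaining <- setdiff(remaining, nd)
        prog <- TRUE
      }
    }
    if (!prog) stop("malformed tree")
  }
  sets
}

# Canonical non-trivial bipartition keys of an unrooted tree.
bipartition_keys <- function(phy) {
  tips <- sort(phy$tip.label)
  n <- length(tips)
  sets <- node_tipsets(phy)
  keys <- character(0)
  for (nd in (n_tips(phy) + 1):(n_tips(phy) + phy$Nnode)) {
    s <- sets[[nd]]
    if (length(s) < 2 || length(s) > n - 2) next
    side <- if (tips[1] %in% s) setdiff(tips, s) else s
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

n_tips <- function(phy) length(phy$tip.label)

#' Bootstrap support for a distance-based tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' tree for each replicate with `build` (default: pairwise-deletion
#' p-distance, Poisson correction, neighbor joining), and maps the
#' percentage of replicates containing each original-tree bipartition onto
#' the original tree's internal nodes (`node.label`).
#'
#' @param msa named character vector of gapped rows (>= 3 sequences).
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed for the column resampling.
#' @param build function `msa -> phylo` (default the package's
#'   distance pipeline).
#' @return the original tree with `node.label` supports in `[0, 100]`
#'   (trivial bipartitions get `NA`).
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1,
                              build = build_nj_tree) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  tree <- build(msa)
  enc <- msa_matrix(msa)
  L <- ncol(enc)
  orig <- bipartition_keys(tree)
  counts <- setNames(numeric(length(orig)), orig)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_msa <- encoded_to_msa(enc[, cols, drop = FALSE])
      rep_tree <- try(build(rep_msa), silent = TRUE)
      if (inherits(rep_tree, "try-error")) next
      hit <- intersect(orig, bipartition_keys(rep_tree))
      counts[hit] <- counts[hit] + 1
    }
  })
  supp <- round(100 * counts / n_reps, 1)
  # map supports onto internal nodes
  n <- n_tips(tree)
  sets <- node_tipsets(tree)
  tips <- sort(tree$tip.label)
  node_lab <- rep(NA_character_, tree$Nnode)
  for (nd in (n + 1):(n + tree$Nnode)) {
    s <- sets[[nd]]
    if (length(s) < 2 || length(s) > length(tips) - 2) next
    side <- if (tips[1] %in% s) setdiff(tips, s) else s
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(counts)) node_lab[nd - n] <- as.character(supp[key])
  }
  tree$node.label <- node_lab
  tree
}

#' @rdname bootstrap_support
#' @param msa alignment to turn into a tree.
#' @param max_p saturation cap applied to p-distances before the Poisson
#'   correction (a pair differing at every shared site has undefined
#'   corrected distance; it is set to the cap's corrected value instead).
#' @export
build_nj_tree <- function(msa, max_p = 1 - 1e-6) {
  p <- pdistance_pairwise_deletion(msa)
  neighbor_joining(poisson_correct(pmin(p, max_p)))
}

encoded_to_msa <- function(enc) {
  chars <- c(AA21, "-")
  code <- enc
  code[code == 0L] <- 22L
  out <- apply(code, 1, function(r) paste(chars[r], collapse = ""))
  setNames(out, rownames(enc))
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree an [ape::phylo].
#' @param outgroup_id tip label of the outgroup.
#' @return rooted [ape::phylo].
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label)
    stop("outgroup not in tree: ", outgroup_id)
  rt <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
  root_node <- n_tips(rt) + 1L
  re <- which(rt$edge[, 1] == root_node)
  if (length(re) == 2 && !is.null(rt$edge.length)) {
    tot <- sum(rt$edge.length[re])
    rt$edge.length[re] <- tot / 2
  }
  rt
}

#' Assign subclasses from labeled reference leaves
#'
#' Each unlabeled member receives the label of the smallest clade that
#' (a) has bootstrap support above `min_support`, (b) contains the member,
#' and (c) contains at least one reference leaf - provided all references in
#' that clade carry a single label. Conflicting references leave the member
#' unassigned (flagged).
#'
#' @param tree rooted [ape::phylo] with `node.label` supports (from
#'   [bootstrap_support()] and [root_with_outgroup()]).
#' @param reference_labels named character vector: reference tip -> label.
#' @param min_support support threshold (default 50, strict `>`).
#' @return named character vector for the non-reference tips (`NA` =
#'   unassigned); attribute `"conflict"` lists tips whose smallest supported
#'   reference clade was label-conflicted.
#' @export
assign_subclass <- function(tree, reference_labels, min_support = 50) {
  if (length(reference_labels) == 0 || is.null(names(reference_labels)))
    stop("need at least one named reference label")
  refs <- names(reference_labels)
  miss <- setdiff(refs, tree$tip.label)
  if (length(miss) > 0) stop("reference tip(s) not in tree: ", paste(miss, collapse = ", "))
  queries <- setdiff(tree$tip.label, refs)
  n <- n_tips(tree)
  sets <- node_tipsets(tree)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  internal <- (n + 1):(n + tree$Nnode)
  ord <- internal[order(lengths(sets[internal]))]
  out <- setNames(rep(NA_character_, length(queries)), queries)
  conflict <- character(0)
  for (q in queries) {
    for (nd in ord) {
      s <- sets[[nd]]
      sv <- supp[nd - n]
      if (!(q %in% s)) next
      if (is.na(sv) || sv <= min_support) next
      rin <- intersect(s, refs)
      if (length(rin) == 0) next
      labsin <- unique(reference_labels[rin])
      if (length(labsin) == 1) out[q] <- labsin else conflict <- c(conflict, q)
      break
    }
  }
  attr(out, "conflict") <- conflict
  out
}
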