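test_that("N-terminal extraction spans DBD start through HR-B end", {
  seqs <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 15), collapse = "")
  ann <- list(dbd = interval(41, 134), hrb = interval(167, 217))
  nt <- extract_nterminal(ann, list(id = "t", sequence = seqs))
  expect_equal(nchar(nt), 217 - 41 + 1)
  expect_identical(nt, substr(seqs, 41, 217))

  ann1 <- list(dbd = interval(1, 90), hrb = interval(120, 140))
  expect_identical(extract_nterminal(ann1, list(id = "t", sequence = seqs)),
                   substr(seqs, 1, 140))
  expect_error(extract_nterminal(list(dbd = interval(1, 5)),
                                 list(id = "t", sequence = seqs)),
               "lacks")
})

test_that("progressive alignment handles identity, insertions and permutation", {
  m1 <- progressive_align(c(x = "MKTAYIAKQR", y = "MKTAYIAKQR"))
  expect_false(any(grepl("-", m1)))

  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  with_ins <- paste0(substr(base, 1, 15), "WWWWW", substr(base, 16, nchar(base)))
  m2 <- progressive_align(c(a = base, b = with_ins, c = base))
  expect_equal(unique(nchar(m2)), nchar(with_ins))
  gap_cols <- apply(do.call(rbind, strsplit(unname(m2), "")), 2,
                    function(col) any(col == "-"))
  expect_equal(sum(gap_cols), 5) # one 5-column gap block
  expect_equal(diff(which(gap_cols)), rep(1, 4))

  m2p <- progressive_align(c(c = base, a = base, b = with_ins))
  expect_identical(m2[c("a", "b", "c")], m2p[c("a", "b", "c")])

  expect_error(progressive_align(c(a = "MKT")), "at least 2")
})

test_that("pairwise-deletion distances and Poisson correction follow their closed forms", {
  p <- pdistance_pairwise_deletion(c(a = "AAA", b = "AAT"))
  expect_equal(p["a", "b"], 1 / 3)

  # gapped site excluded: two shared sites, one mismatch
  p2 <- pdistance_pairwise_deletion(c(a = "G-A", b = "AAA"))
  expect_equal(p2["a", "b"], 1 / 2)

  expect_error(pdistance_pairwise_deletion(c(a = "--A", b = "AA-")),
               "zero shared")

  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), -log(0.5))
  expect_error(poisson_correct(1), "p must")
  # correction always dominates the raw proportion
  grid <- seq(0, 0.95, by = 0.05)
  expect_true(all(poisson_correct(grid) >= grid))
  expect_true(all(diff(poisson_correct(grid)) > 0))
})

test_that("neighbor joining matches closed forms and reconstructs additive trees", {
  # 3 taxa: v_A = (d_AB + d_AC - d_BC) / 2 etc.
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(D3)
  v <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(v[c("A", "B", "C")], c(A = 1, B = 2, C = 3))

  # 2 taxa: single split edge
  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(D2)
  expect_equal(sum(t2$edge.length), 4)

  # random additive trees are reconstructed exactly (topology and lengths)
  set.seed(55)
  for (r in 1:25) {
    tr <- ape::unroot(ape::rtree(sample(4:12, 1),
                                 br = function(n) runif(n, 0.1, 1)))
    D <- cophenetic(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    nj <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(nj), tr), 0, ignore_attr = TRUE)
    expect_lt(max(abs(cophenetic(nj)[rownames(D), rownames(D)] - D)), 1e-6)
  }

  # equidistant taxa: deterministic tie-broken output
  De <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(De) <- 0
  expect_identical(ape::write.tree(neighbor_joining(De)),
                   ape::write.tree(neighbor_joining(De)))
  expect_error(neighbor_joining(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
})

test_that("bootstrap supports are seeded, leaf-order invariant and signal-responsive", {
  msa <- structure(c(A = "AAAAAAAAAACCCCCCCCCC", B = "AAAAAAAAAACCCCCCCCCG",
                     C = "TTTTTTTTTTGGGGGGGGGG", D = "TTTTTTTTTTGGGGGGGGGA",
                     E = "AAAAATTTTTGGGGGCCCCC"), class = "msa")
  t1 <- bootstrap_support(msa, n_reps = 100, seed = 5)
  t2 <- bootstrap_support(msa, n_reps = 100, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  # strongly supported clades: AB and CD recover near-certain support
  supp <- suppressWarnings(as.numeric(t1$node.label))
  expect_gte(max(supp, na.rm = TRUE), 95)

  # permuting MSA rows leaves supports per bipartition unchanged
  t3 <- bootstrap_support(msa[c(3, 1, 5, 2, 4)], n_reps = 100, seed = 5)
  lab_of <- function(tr) {
    sets <- hsfminer:::node_tipsets(tr)
    n <- length(tr$tip.label)
    out <- character(0)
    for (nd in (n + 1):(n + tr$Nnode)) {
      key <- paste(sort(sets[[nd]]), collapse = "|")
      out[key] <- tr$node.label[nd - n]
    }
    out[!is.na(out)]
  }
  l1 <- lab_of(t1); l3 <- lab_of(t3)
  common <- intersect(names(l1), names(l3))
  expect_gt(length(common), 0)
  expect_identical(l1[common], l3[common])

  expect_equal(formals(bootstrap_support)$n_reps, 1000)
  expect_error(bootstrap_support(msa, n_reps = 0), "n_reps")
})

test_that("outgroup rooting splits the pendant edge at its midpoint", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
  tr <- ape::unroot(tr)
  rt <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(rt))
  root_node <- length(rt$tip.label) + 1L
  kids <- rt$edge[rt$edge[, 1] == root_node, 2]
  expect_true(which(rt$tip.label == "D") %in% kids)
  re <- which(rt$edge[, 1] == root_node)
  expect_equal(rt$edge.length[re[1]], rt$edge.length[re[2]])
  expect_error(root_with_outgroup(tr, "Z"), "outgroup")
})

test_that("subclass assignment follows the smallest supported reference clade", {
  labs <- c(R1 = "A2", R2 = "A2", R3 = "B", R4 = "B")
  t1 <- root_with_outgroup(ape::read.tree(
    text = "((Q:0.1,(R1:0.1,R2:0.1)90:0.1)80:0.2,(R3:0.1,R4:0.1)95:0.2,O:0.5);"), "O")
  a1 <- assign_subclass(t1, labs)
  expect_equal(unname(a1["Q"]), "A2")

  # support at or below the threshold leaves the member unassigned
  t2 <- root_with_outgroup(ape::read.tree(
    text = "((Q:0.1,(R1:0.1,R2:0.1)40:0.1)40:0.2,(R3:0.1,R4:0.1)95:0.2,O:0.5);"), "O")
  expect_true(is.na(assign_subclass(t2, labs)["Q"]))

  # conflicting references in the smallest supported clade: unassigned, flagged
  t3 <- root_with_outgroup(ape::read.tree(
    text = "((Q:0.1,(R1:0.1,R3:0.1)90:0.1)85:0.2,(R2:0.1,R4:0.1)95:0.2,O:0.5);"), "O")
  a3 <- assign_subclass(t3, labs)
  expect_true(is.na(a3["Q"]))
  expect_true("Q" %in% attr(a3, "conflict"))

  expect_error(assign_subclass(t1, character(0)), "reference")
})
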