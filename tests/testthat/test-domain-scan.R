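test_that("build_profile matches the hand-computed log-odds arithmetic", {
  # 2 sequences, 3 columns, uniform background 1/20, pseudocount 1
  prof <- build_profile(c("ACD", "AAD"), pseudocount = 1,
                        background = setNames(rep(1 / 20, 20),
                                              strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  bg <- 1 / 20
  # column 1: A count 2 -> log2(((2 + 1*bg) / (2 + 1)) / bg)
  expect_equal(unname(prof$log_odds[1, "A"]), log2(((2 + bg) / 3) / bg))
  # column 2: C count 1, A count 1
  expect_equal(unname(prof$log_odds[2, "C"]), log2(((1 + bg) / 3) / bg))
  expect_equal(unname(prof$log_odds[2, "G"]), log2(((0 + bg) / 3) / bg))
  expect_equal(prof$length, 3)
  # X always scores background
  expect_equal(prof$log_odds[, "X"], rep(0, 3))

  # identical sequences: consensus maximal in every column
  p2 <- build_profile(c("MKT", "MKT", "MKT"))
  expect_equal(apply(p2$log_odds[, 1:20], 1, which.max),
               match(c("M", "K", "T"), colnames(p2$log_odds)[1:20]))

  # gap-majority columns dropped
  p3 <- build_profile(c("A-D", "A-D", "ACD"))
  expect_equal(p3$length, 2)

  expect_error(build_profile(c("AC", "ACD")), "equal length")
  expect_error(build_profile("AC"), "at least 2")
  expect_error(build_profile(c("AC", "AC"), pseudocount = 0), "pseudocount")
})

test_that("scan_profile finds embedded consensus and is calibrated", {
  m1 <- hsf_dbd_consensus()
  prof <- consensus_profile(m1)
  bg <- random_peptide(500, 61)
  seqe <- paste0(substr(bg, 1, 100), m1, substr(bg, 101 + nchar(m1), 500))
  hit <- scan_profile(list(id = "e", sequence = seqe), prof)
  expect_equal(unname(hit$interval["start"]), 101)
  expect_equal(hit$score, prof$consensus_score)

  # maximality: no equal-length sequence outscores the consensus
  set.seed(17)
  others <- replicate(50, random_peptide(nchar(m1), sample.int(1e6, 1)))
  other_scores <- vapply(others, function(s)
    profile_best_score(s, prof), numeric(1))
  expect_true(all(other_scores <= prof$consensus_score))

  # shuffled sequences rarely reach the default threshold
  set.seed(23)
  fp <- 0
  chars <- strsplit(seqe, "")[[1]]
  for (i in 1:150) {
    sh <- paste(sample(chars), collapse = "")
    if (!is.null(suppressMessages(scan_profile(list(id = "s", sequence = sh), prof))))
      fp <- fp + 1
  }
  expect_lt(fp / 150, 0.05)

  # short sequences give no hit, with a message rather than an error
  expect_message(res <- scan_profile(list(id = "short", sequence = "MKT"), prof),
                 "shorter than profile")
  expect_null(res)
  expect_error(scan_profile(list(id = "x", sequence = "MKT"), list()),
               "scoring_profile")
})

test_that("find_hrab recovers planted heptad architecture", {
  polar <- function(n) strrep("S", n)
  hep <- function(k) strrep("LSTLQNP", k)
  # HR-A (3 heptads) + 21 polar + HR-B (2 heptads)
  s <- paste0(polar(30), hep(3), polar(21), hep(2), polar(30))
  r <- find_hrab(list(id = "t", sequence = s), search_start = 1)
  expect_equal(r$insertion_length, 21L)
  expect_equal(unname(r$hra), c(31L, 51L))
  expect_equal(unname(r$hrb), c(73L, 86L))
  expect_equal(unname(r$total), c(31L, 86L))

  # continuous 5-heptad block: no insertion
  s2 <- paste0(polar(30), hep(5), polar(30))
  r2 <- find_hrab(list(id = "t", sequence = s2), search_start = 1)
  expect_equal(r2$insertion_length, 0L)
  expect_equal(unname(r2$total), c(31L, 65L))

  # class-C style 7-residue insertion
  s3 <- paste0(polar(30), hep(3), polar(7), hep(2), polar(30))
  expect_equal(find_hrab(list(id = "t", sequence = s3))$insertion_length, 7L)

  expect_null(find_hrab(list(id = "g", sequence = strrep("G", 120))))
  expect_error(find_hrab(list(id = "t", sequence = "MKT"), search_start = 10),
               "beyond sequence end")
})

test_that("same-locus deduplication keeps the longest protein deterministically", {
  recs <- protein_records(c("iso_b", "iso_a", "other"),
                          c(strrep("M", 384), strrep("M", 300), strrep("K", 100)))
  loci <- data.frame(gene_id = c("iso_b", "iso_a", "other"),
                     chromosome = c("1", "1", "2"),
                     start = c(1000L, 1000L, 99L), strand = "+")
  kept <- deduplicate_by_locus(recs, loci)
  expect_setequal(kept$id, c("iso_b", "other"))

  # exact length tie: lexicographically smallest id survives
  recs2 <- protein_records(c("z", "a"), c(strrep("M", 10), strrep("M", 10)))
  loci2 <- data.frame(gene_id = c("z", "a"), chromosome = "1",
                      start = 5L, strand = "+")
  expect_equal(deduplicate_by_locus(recs2, loci2)$id, "a")

  # distinct loci: unchanged
  loci3 <- data.frame(gene_id = c("z", "a"), chromosome = c("1", "2"),
                      start = 5L, strand = "+")
  expect_equal(nrow(deduplicate_by_locus(recs2, loci3)), 2)

  expect_error(deduplicate_by_locus(recs2, loci3[1, ]), "missing locus")
})

test_that("identify_candidates keeps exactly the true members and is order-independent", {
  fam <- small_family()
  decoys <- rbind(simulate_decoys(5, "random", seed = 3),
                  simulate_decoys(2, "dbd_only", seed = 3))
  all_recs <- rbind(fam$records, decoys)
  class(all_recs) <- class(fam$records)
  loci <- rbind(fam$loci,
                data.frame(gene_id = decoys$id, chromosome = "9",
                           start = 5e6 + seq_len(nrow(decoys)) * 1000L,
                           strand = "+"))
  res <- suppressMessages(identify_candidates(all_recs, loci))
  expect_setequal(res$members$id, fam$records$id)
  expect_equal(unname(res$drop_counts["no_coiled_coil"]), 2L)

  # permuting the input yields the same member set
  set.seed(99)
  perm <- all_recs[sample(nrow(all_recs)), ]
  class(perm) <- class(all_recs)
  res2 <- suppressMessages(identify_candidates(perm, loci))
  expect_setequal(res2$members$id, res$members$id)

  empty <- fam$records[0, ]
  class(empty) <- class(fam$records)
  expect_equal(nrow(suppressMessages(identify_candidates(empty, loci))$members), 0)
})
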