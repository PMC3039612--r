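test_that("linker measurement matches published domain-table geometry", {
  # DBD 41-134, OD 167-217 -> linker 32 (printed class-A geometry)
  expect_equal(measure_linker(interval(41, 134), interval(167, 217)), 32L)
  # DBD 69-162, OD 231-260 -> 68, inside the class-B range 50-78
  expect_equal(measure_linker(interval(69, 162), interval(231, 260)), 68L)
  # adjacency
  expect_equal(measure_linker(interval(1, 10), interval(11, 40)), 0L)
  expect_error(measure_linker(interval(41, 134), interval(100, 217)), "overlaps")
})

test_that("class assignment is a pure function of the insertion length", {
  expect_equal(assign_class(21, 32)$class_label, "A")
  expect_true(assign_class(21, 32)$linker_consistent)
  expect_equal(assign_class(7, 30)$class_label, "C")
  expect_equal(assign_class(0, 60)$class_label, "B")
  expect_true(assign_class(0, 60)$linker_consistent)
  expect_equal(assign_class(12, 40)$class_label, "unclassified")

  # tolerance boundaries (default 2)
  expect_equal(assign_class(19)$class_label, "A")
  expect_equal(assign_class(23)$class_label, "A")
  expect_equal(assign_class(5)$class_label, "C")
  expect_equal(assign_class(9)$class_label, "C")
  expect_equal(assign_class(2)$class_label, "B")
  expect_equal(assign_class(3)$class_label, "unclassified")

  # purity: label depends only on insertion, never on the linker
  for (ins in 0:30)
    for (lk in c(5, 30, 60))
      expect_identical(assign_class(ins, lk)$class_label,
                       assign_class(ins, NA)$class_label)

  # linker consistency is advisory only
  cls <- assign_class(7, 53) # class-C geometry outside the 14-49 range
  expect_equal(cls$class_label, "C")
  expect_false(cls$linker_consistent)

  expect_error(assign_class(-1), "insertion_length")
})

test_that("published OD geometry reclassifies all 25 members to their groups", {
  t2 <- hsf_table2()
  od_len <- t2$od_end - t2$od_start + 1
  # class-B ODs span 29-30 residues (no insertion); insertion = OD length - 30
  ins <- pmax(od_len - 30, 0)
  lk <- mapply(function(ds, de, os, oe)
    measure_linker(interval(ds, de), interval(os, oe)),
    t2$dbd_start, t2$dbd_end, t2$od_start, t2$od_end)
  got <- vapply(seq_along(ins), function(i)
    assign_class(ins[i], lk[i])$class_label, character(1))
  expect_identical(got, substr(t2$group, 1, 1))
})

test_that("NLS scanner detects printed motifs, bipartite notation and primacy", {
  e <- neutral_embed("RKRRR")
  h <- scan_nls(list(id = "t", sequence = e$sequence), region_start = 1)
  expect_true(any_hit_overlaps(h, e$start, e$end))
  expect_equal(h$kind[h$primary], "NLS_mono")

  # bipartite: KRK + 7 spacer + KKRRR in the compact notation
  e2 <- neutral_embed(paste0("KRK", strrep("S", 7), "KKRRR"))
  h2 <- scan_nls(list(id = "t", sequence = e2$sequence), region_start = 1)
  expect_true("KRK7KKRRR" %in% h2$notation)
  expect_equal(h2$kind[h2$notation == "KRK7KKRRR"], "NLS_bipartite")

  expect_equal(nrow(scan_nls(list(id = "t", sequence = strrep("A", 60)))), 0)

  # primary = nearest to region_start
  s3 <- paste0(strrep("S", 20), "KKRR", strrep("S", 40), "RKRRR", strrep("S", 10))
  h3 <- scan_nls(list(id = "t", sequence = s3), region_start = 15)
  expect_equal(h3$text[h3$primary], "KKRR")
})

test_that("NES scanner detects printed motifs and merges overlaps", {
  for (m in c("LENLALNI", "LDVLTLSV")) {
    e <- neutral_embed(m)
    h <- scan_nes(list(id = "t", sequence = e$sequence))
    expect_true(any_hit_overlaps(h, e$start, e$end))
  }
  expect_equal(nrow(scan_nes(list(id = "t", sequence = strrep("G", 60)))), 0)
  # overlapping windows collapse to non-overlapping hits
  e2 <- neutral_embed("LDVLTLSVLLNI")
  h2 <- scan_nes(list(id = "t", sequence = e2$sequence))
  if (nrow(h2) > 1) {
    ends <- h2$position + nchar(h2$text) - 1
    expect_true(all(h2$position[-1] > ends[-nrow(h2)]))
  }
})

test_that("AHA scanner detects printed motifs and caps reported hits", {
  for (m in c("DDFWEELLNE", "DSFWEQFL")) {
    e <- neutral_embed(m)
    h <- scan_aha(list(id = "t", sequence = e$sequence))
    expect_true(any_hit_overlaps(h, e$start, e$end))
  }
  expect_equal(nrow(scan_aha(list(id = "t", sequence = strrep("G", 60)))), 0)
  # at most 2 non-overlapping hits even with 3 planted motifs
  s <- paste0(strrep("S", 10), "DDFWEELLNE", strrep("S", 8), "DSFWEQFL",
              strrep("S", 8), "DVFWERFLTD", strrep("S", 10))
  expect_lte(nrow(scan_aha(list(id = "t", sequence = s))), 2)
})

test_that("all printed family motifs are detected; background windows rarely fire", {
  t2 <- hsf_table2()

  nls_ok <- vapply(t2$nls, function(m) {
    mm <- expand_bipartite(m)
    e <- neutral_embed(mm)
    any_hit_overlaps(scan_nls(list(id = "t", sequence = e$sequence), 1),
                     e$start, e$end)
  }, logical(1))
  expect_true(all(nls_ok))

  nes_ok <- vapply(stats::na.omit(t2$nes), function(m) {
    e <- neutral_embed(m)
    any_hit_overlaps(scan_nes(list(id = "t", sequence = e$sequence)),
                     e$start, e$end)
  }, logical(1))
  expect_true(all(nes_ok))

  aha_strings <- stats::na.omit(c(t2$aha1, t2$aha2))
  expect_length(aha_strings, 16)
  aha_ok <- vapply(aha_strings, function(m) {
    e <- neutral_embed(m)
    any_hit_overlaps(scan_aha(list(id = "t", sequence = e$sequence)),
                     e$start, e$end)
  }, logical(1))
  expect_true(all(aha_ok))

  # calibration: length-matched background windows almost never fire
  expect_true(all(scanner_fpr(300, seed = 77) < 0.05))
})

test_that("annotate_member composes classification and motifs with AHA suppression", {
  fam <- small_family()
  res <- suppressMessages(identify_candidates(fam$records, fam$loci))
  truth <- fam$truth

  idA <- truth$gene_id[truth$true_class == "A" & !is.na(truth$aha1)][1]
  annA <- annotate_member(res$members[res$members$id == idA, ],
                          res$domain_hits[[idA]], res$hrab[[idA]])
  expect_equal(annA$classification$class_label, "A")
  expect_gt(nrow(annA$nls), 0)
  expect_gt(nrow(annA$aha), 0)
  expect_false(annA$aha_suppressed)

  # class-B member with an AHA-like window planted after its NLS
  idB <- truth$gene_id[truth$true_class == "B"][1]
  recB <- res$members[res$members$id == idB, ]
  seqB <- paste0(recB$sequence, "DDFWEELLNE", strrep("S", 5))
  recB2 <- protein_records(idB, seqB)
  annB <- annotate_member(recB2[1, ], res$domain_hits[[idB]], res$hrab[[idB]])
  expect_equal(annB$classification$class_label, "B")
  expect_equal(nrow(annB$aha), 0)
  expect_true(annB$aha_suppressed)

  # member lacking an NLS gets an empty table and a warning
  polar <- function(n) strrep("S", n)
  bare <- paste0(polar(20), hsf_dbd_template(), polar(20), strrep("LSTLQNP", 5),
                 polar(40))
  recN <- protein_records("noNLS", bare)
  hitN <- scan_profile(recN[1, ], hsf_dbd_profile())
  hrabN <- find_hrab(recN[1, ], search_start = hitN$interval["end"] + 1)
  expect_warning(annN <- annotate_member(recN[1, ], hitN, hrabN), "no NLS")
  expect_equal(nrow(annN$nls), 0)
})
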