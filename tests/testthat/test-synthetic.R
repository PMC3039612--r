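test_that("simulate_family produces the configured family with exact ground truth", {
  fam <- small_family()
  expect_equal(nrow(fam$records), 10)
  expect_equal(unname(table(fam$truth$true_class)[c("A", "B", "C")]),
               c(5L, 3L, 2L), ignore_attr = TRUE)
  expect_true(all(fam$truth$insertion_length[fam$truth$true_class == "C"] == 7))
  expect_true(all(fam$truth$insertion_length[fam$truth$true_class == "A"] == 21))
  expect_true(all(fam$truth$insertion_length[fam$truth$true_class == "B"] == 0))

  # every recorded coordinate indexes the emitted sequence correctly
  for (i in seq_len(nrow(fam$truth))) {
    tr <- fam$truth[i, ]
    s <- fam$records$sequence[fam$records$id == tr$gene_id]
    expect_identical(substr(s, tr$nls_pos, tr$nls_pos + nchar(tr$nls) - 1), tr$nls)
    if (!is.na(tr$nes))
      expect_identical(substr(s, tr$nes_pos, tr$nes_pos + nchar(tr$nes) - 1), tr$nes)
    if (!is.na(tr$aha1))
      expect_identical(substr(s, tr$aha1_pos, tr$aha1_pos + nchar(tr$aha1) - 1), tr$aha1)
    # structural geometry is internally consistent
    expect_lt(tr$dbd_end, tr$hra_start)
    expect_equal(tr$hrb_start - tr$hra_end - 1L, tr$insertion_length)
    expect_equal(tr$hra_start - tr$dbd_end - 1L, tr$linker_length)
  }

  # linker lengths stay in the class-typical ranges
  rng <- list(A = c(9, 39), B = c(50, 78), C = c(14, 49))
  for (cl in names(rng)) {
    lk <- fam$truth$linker_length[fam$truth$true_class == cl]
    expect_true(all(lk >= rng[[cl]][1] & lk <= rng[[cl]][2]))
  }
})

test_that("simulation is deterministic and per-record streams are stable", {
  cfg <- family_sim_config(n_per_class = c(A = 3L, B = 2L, C = 1L),
                           n_duplicate_pairs = 0L, seed = 7)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$records$sequence, f2$records$sequence)
  expect_identical(f1$truth, f2$truth)

  # adding members does not perturb existing ones
  cfg2 <- family_sim_config(n_per_class = c(A = 4L, B = 2L, C = 1L),
                            n_duplicate_pairs = 0L, seed = 7)
  f3 <- simulate_family(cfg2)
  shared <- intersect(f1$records$id, f3$records$id)
  expect_identical(f1$records$sequence[match(shared, f1$records$id)],
                   f3$records$sequence[match(shared, f3$records$id)])
})

test_that("config validation rejects colliding insertions and bad rates", {
  expect_error(family_sim_config(insertion_by_class = c(A = 7, B = 0, C = 7)),
               "distinct")
  expect_error(family_sim_config(duplicate_divergence = 1), "divergence")
  expect_error(simulate_family(family_sim_config(n_per_class = c(A = 0L, B = 0L, C = 0L))))
})

test_that("mutate_duplicate respects divergence and constraints", {
  rec <- protein_records("p", random_peptide(400, 31))
  same <- mutate_duplicate(rec, divergence = 0, seed = 5)
  expect_identical(same$sequence, rec$sequence)

  mut <- mutate_duplicate(rec, divergence = 0.1, seed = 5)
  obs <- mean(strsplit(rec$sequence, "")[[1]] != strsplit(mut$sequence, "")[[1]])
  # binomial 99% CI around 0.1 at n = 400
  expect_gt(obs, 0.1 - 2.58 * sqrt(0.1 * 0.9 / 400))
  expect_lt(obs, 0.1 + 2.58 * sqrt(0.1 * 0.9 / 400))

  # constrained sites stay within the allowed set
  con <- list(list(positions = 1:50, allowed = c("L", "I", "V", "M")))
  base <- protein_records("q", strrep("L", 50))
  m2 <- mutate_duplicate(base, divergence = 0.5, seed = 9, constrained = con)
  expect_true(all(strsplit(m2$sequence, "")[[1]] %in% c("L", "I", "V", "M")))

  expect_error(mutate_duplicate(rec, divergence = 1, seed = 1), "divergence")
})

test_that("Ct simulation has the configured shape and exact zero-noise folds", {
  cfg <- ct_sim_config(genes = c("g1", "g2"),
                       true_log2_fold = c(g1 = 3, g2 = 0),
                       noise_sd = 0, replicates = 3, seed = 2)
  tab <- simulate_ct_table(cfg)
  expect_equal(nrow(tab), 18) # 3 genes (incl. reference) x 2 conditions x 3 reps
  expect_equal(sum(tab$gene == "g1" & tab$condition == "treated"), 3)
  res <- relative_expression(tab, "Actin1")
  expect_equal(res$fold_change[res$gene == "g1"], 8.0)
  expect_equal(res$fold_change[res$gene == "g2"], 1.0)

  expect_warning(ct_sim_config(genes = c("g1", "Actin1"),
                               true_log2_fold = c(g1 = 1, Actin1 = 2)),
                 "forced to 0")
})

test_that("decoy generators produce the advertised structures", {
  d1 <- simulate_decoys(3, "random", seed = 4)
  expect_equal(nrow(d1), 3)
  d2 <- simulate_decoys(2, "dbd_only", seed = 4)
  # dbd_only decoys carry a DBD hit but no heptad region
  hit <- scan_profile(d2[1, ], hsf_dbd_profile())
  expect_false(is.null(hit))
  expect_null(find_hrab(d2[1, ], search_start = hit$interval["end"] + 1))
})
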