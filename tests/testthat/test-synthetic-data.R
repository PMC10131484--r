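test_that("occupancy model reproduces closed-form hand evaluations", {
  # identity perturbation
  expect_equal(occupancy_ratio(0, 0), 1)
  # hand evaluation: ddg_superopen = +6 moves G_SO from -3 to +3
  RT <- 0.593
  p <- function(gc, go) exp(-gc / RT) / (1 + exp(-gc / RT) + exp(-go / RT))
  expect_equal(occupancy_ratio(0, 6), p(-2, 3) / p(-2, -3),
               tolerance = 1e-12)
  # destabilized closed conformation: activity collapses
  expect_lt(occupancy_ratio(20, 0), 0.01)
  expect_error(occupancy_ratio(NA, 0), "non-finite")
})

test_that("ground truth obeys the consequence rules and is reproducible", {
  truth <- fix_truth()
  expect_true(all(truth$true_activity >= 0))
  expect_true(all(truth$true_activity[truth$consequence == "nonsense"] == 0))
  expect_false(any(truth$consequence == "synonymous"))
  expect_equal(nrow(truth), 59 * 20)
  # wt residues match the attached reference protein
  prot <- strsplit(attr(truth, "protein"), "")[[1]]
  expect_equal(truth$wt_aa, prot[truth$position])
  # byte-identical regeneration under the same seed
  again <- generate_truth(protein_length = 60, mutable_range = c(2, 60),
                          seed = 5)
  expect_identical(truth$true_activity, again$true_activity)
})

test_that("screen counts conserve depth and regenerate under a seed", {
  cnt <- fix_counts()
  acc <- attr(cnt, "accounting")
  # multinomial conservation: variant + wt + excluded reads = depth
  per_tile <- tapply(cnt$count,
                     list(cnt$tile, cnt$condition, cnt$replicate), sum)
  for (i in seq_len(nrow(acc))) {
    tot <- per_tile[as.character(acc$tile[i]), acc$condition[i],
                    as.character(acc$replicate[i])] +
      acc$wt_reads[i] + acc$multi_reads[i]
    expect_identical(as.integer(tot), as.integer(acc$depth[i]))
  }
  again <- simulate_screen(fix_truth(),
                           screen_config(depth_per_tile = 5e5,
                                         n_clones = 5e4, seed = 7))
  expect_identical(cnt$count, again$count)
  expect_identical(cnt$variant, again$variant)
})

test_that("mutational load follows the Poisson model", {
  cnt <- simulate_screen(generate_truth(protein_length = 60,
                                        mutable_range = c(2, 60), seed = 5),
                         screen_config(depth_per_tile = 1e4,
                                       n_clones = 1e5, seed = 3))
  ls <- attr(cnt, "library_stats")
  expect_equal(ls$frac_mutation_free, rep(exp(-0.35), nrow(ls)),
               tolerance = 0.01 / exp(-0.35))
})

test_that("selection arithmetic: null variants deplete ~2^generations", {
  truth <- fix_truth()
  # craft a binary landscape: half null, half wild-type-like
  truth$true_activity[truth$consequence == "missense"] <-
    rep(c(0, 1), length.out = sum(truth$consequence == "missense"))
  cnt <- simulate_screen(truth, screen_config(depth_per_tile = 1e6,
                                              n_clones = 5e4, seed = 11))
  act <- setNames(truth$true_activity, truth$variant)
  pre <- cnt[cnt$condition == "pre" & cnt$replicate == 1, ]
  post <- cnt[cnt$condition == "post" & cnt$replicate == 1, ]
  m <- merge(pre, post, by = "variant", suffixes = c("_pre", "_post"))
  m <- m[m$variant %in% names(act)[!is.na(act)] & m$count_pre >= 50, ]
  a <- act[m$variant]
  enr1 <- sum(m$count_post[a == 1]) / sum(m$count_pre[a == 1])
  enr0 <- sum(m$count_post[a == 0]) / sum(m$count_pre[a == 0])
  ratio <- enr1 / enr0
  expect_gt(ratio, 1024 / 3)
  expect_lt(ratio, 1024 * 3)
})

test_that("enrichment is monotone across an activity ladder", {
  truth <- fix_truth()
  ladder <- c(0, 0.25, 0.5, 1, 1.5)
  mis <- which(truth$consequence == "missense")
  truth$true_activity[mis] <- rep(ladder, length.out = length(mis))
  cnt <- simulate_screen(truth, screen_config(depth_per_tile = 1e6,
                                              n_clones = 5e4, seed = 13))
  act <- setNames(truth$true_activity, truth$variant)
  pre <- cnt[cnt$condition == "pre" & cnt$replicate == 1, ]
  post <- cnt[cnt$condition == "post" & cnt$replicate == 1, ]
  m <- merge(pre, post, by = "variant", suffixes = c("_pre", "_post"))
  m <- m[m$variant %in% truth$variant[mis] & m$count_pre >= 50, ]
  a <- act[m$variant]
  mean_enr <- vapply(ladder, function(l)
    sum(m$count_post[a == l]) / sum(m$count_pre[a == l]), numeric(1))
  expect_true(all(diff(mean_enr) > 0))
})

test_that("ddg tables carry noise, units and the disordered-loop gap", {
  truth <- generate_truth(protein_length = 200, mutable_range = c(2, 200),
                          seed = 2)
  tabs0 <- simulate_ddg_tables(truth, noise_sd = 0, seed = 1)
  mis <- truth[truth$consequence == "missense", ]
  expect_equal(tabs0$closed$ddg,
               mis$ddg_closed[match(tabs0$closed$variant, mis$variant)])
  # positions 157-179 present in closed, absent in super-open
  expect_true(any(tabs0$closed$position %in% 157:179))
  expect_false(any(tabs0$superopen$position %in% 157:179))
  # internal-energy-unit emission divides back to kcal/mol
  reu <- simulate_ddg_tables(truth, noise_sd = 0.1, seed = 9,
                             unit = "internal_energy_units")
  kcal <- simulate_ddg_tables(truth, noise_sd = 0.1, seed = 9)
  expect_equal(reu$closed$ddg / 2.9, kcal$closed$ddg, tolerance = 1e-9)
  expect_error(simulate_ddg_tables(truth, noise_sd = -1), "nonnegative")
})

test_that("toy MSA sampling follows the preference weights", {
  pref <- matrix(0, nrow = 4, ncol = 20,
                 dimnames = list(NULL, c("A","R","N","D","C","Q","E","G",
                                         "H","I","L","K","M","F","P","S",
                                         "T","W","Y","V")))
  pref[, "A"] <- 1
  m <- simulate_msa(pref, n_sequences = 10, gap_rate = 0, seed = 1)
  expect_true(all(m$seqs == "A"))

  m0 <- simulate_msa(pref, n_sequences = 0, gap_rate = 0, seed = 1)
  expect_equal(nrow(m0$seqs), 1L)           # only the wild-type row

  pref[1, ] <- 0; pref[1, c("A", "V")] <- c(0.9, 0.1)
  mm <- simulate_msa(pref, n_sequences = 1e4, gap_rate = 0, seed = 2)
  expect_equal(mean(mm$seqs[-1, 1] == "A"), 0.9, tolerance = 0.02 / 0.9)

  bad <- pref; bad[2, ] <- 0
  expect_error(simulate_msa(bad, 10), "positive row sums")
  expect_error(simulate_msa(pref, 10, gap_rate = 0, seed = 1,
                            wt = "AAA"), "length")
})
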