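test_that("binarize equals an elementwise indicator oracle and is idempotent", {
  expect_equal(unname(binarize(tiny_counts())$counts[1, ]),
               c(0L, 1L, 1L, 0L))
  set.seed(5)
  counts <- matrix(rpois(20 * 30, 0.7), 20, 30)
  bins <- data.frame(contig = "c1", start = (0:29) * 50L, width = 50L)
  cm <- count_matrix(counts, bins, samples = paste0("s", 1:20))
  st <- binarize(cm)
  oracle <- matrix(0L, 20, 30)
  for (i in 1:20) for (j in 1:30) if (counts[i, j] > 0) oracle[i, j] <- 1L
  expect_equal(unname(st$counts), oracle)
  expect_identical(binarize(st)$counts, st$counts)
  # degenerate: all-zero matrix is all-methylated
  cm0 <- count_matrix(matrix(0L, 2, 3),
                      data.frame(contig = "c1", start = (0:2) * 50L,
                                 width = 50L), c("a", "b"))
  expect_true(all(binarize(cm0)$counts == 0L))
})

test_that("methylation proportion is the exact complement of the state mean", {
  st <- binarize(tiny_counts())
  pr <- proportion_methylated(st, tiny_meta())
  expect_equal(pr$proportion + rowMeans(st$counts), rep(1, 3),
               ignore_attr = TRUE)
  # 10 loci, 3 methylated -> 0.3
  counts <- matrix(c(rep(0L, 3), rep(2L, 7)), 1, 10)
  cm <- count_matrix(counts, data.frame(contig = "c1", start = (0:9) * 50L,
                                        width = 50L), "s1x")
  meta <- sample_meta("s1x", "i1", "adult", "disperser")
  expect_equal(proportion_methylated(binarize(cm), meta)$proportion, 0.3)
  expect_error(proportion_methylated(st, meta), "missing from metadata.*s1")
})

test_that("transitions are enumerated per locus with exact conservation", {
  x <- two_stage_states(earlier = matrix(c(1L, 1L, 0L, 0L), 1),
                        later = matrix(c(0L, 1L, 0L, 1L), 1))
  tr <- score_transitions(x$states, x$meta)
  expect_equal(tr$n_gain, 1L)
  expect_equal(tr$n_loss, 1L)
  expect_equal(tr$n_stable, 2L)
  expect_equal(tr$n_changed, 2L)
  expect_equal(tr$n_total, 4L)
  # identical states -> nothing changes
  same <- two_stage_states(matrix(c(1L, 0L, 1L), 1), matrix(c(1L, 0L, 1L), 1))
  tr2 <- score_transitions(same$states, same$meta)
  expect_equal(tr2$n_changed, 0L)
  expect_equal(tr2$n_stable, tr2$n_total)
  # conservation on random inputs
  set.seed(8)
  for (r in 1:10) {
    x <- two_stage_states(matrix(rbinom(40, 1, 0.5), 2),
                          matrix(rbinom(40, 1, 0.5), 2))
    tr <- score_transitions(x$states, x$meta)
    expect_equal(tr$n_gain + tr$n_loss + tr$n_stable, tr$n_total)
    expect_true(all(tr$changed_fraction >= 0 & tr$changed_fraction <= 1))
  }
})

test_that("joint-missing loci can be dropped from the denominator", {
  x <- two_stage_states(matrix(c(0L, 0L, 1L), 1), matrix(c(0L, 1L, 1L), 1))
  full <- score_transitions(x$states, x$meta)
  dropped <- score_transitions(x$states, x$meta, drop_joint_missing = TRUE)
  expect_equal(full$n_total, 3L)
  expect_equal(dropped$n_total, 2L)  # the 0/0 locus leaves the denominator
  expect_equal(full$n_loss, dropped$n_loss)
})

test_that("incomplete individuals are skipped with a warning, duplicates error", {
  cfg <- flat_config(p = 0.5, c = 0.2, n_ind = 2, n_loci = 50, seed = 2)
  ds <- simulate_experiment(cfg)
  st <- binarize(ds$counts)
  keep <- ds$meta$sample_id != ds$meta$sample_id[3]  # drop one adult library
  st2 <- st
  st2$counts <- st$counts[keep, ]
  st2$samples <- st$samples[keep]
  expect_warning(tr <- score_transitions(st2, ds$meta), "lacks a")
  expect_equal(sum(tr$individual_id == ds$meta$individual_id[3]), 1)
  meta_dup <- ds$meta
  meta_dup$stage[2] <- "hatchling"
  expect_error(score_transitions(st, meta_dup), "duplicate sample")
})

test_that("per-individual flip fractions recover the generating change rate", {
  cfg <- flat_config(p = 0.6, c = 0.20, n_ind = 4, n_loci = 6000, seed = 19)
  ds <- simulate_experiment(cfg)
  tr <- score_transitions(binarize(ds$counts), ds$meta)
  se <- sqrt(0.2 * 0.8 / 6000)
  expect_true(all(abs(tr$changed_fraction - 0.2) <= 4 * se))
})

test_that("scoring truth states equals scoring perfectly measured counts", {
  cfg <- flat_config(p = 0.7, c = 0.25, n_ind = 3, n_loci = 800, seed = 29)
  ds <- simulate_experiment(cfg)
  st <- binarize(ds$counts)
  expect_identical(unname(st$counts), unname(ds$truth_states))
  truth_cm <- count_matrix(ds$truth_states, ds$counts$bins,
                           samples = rownames(ds$truth_states))
  pr_truth <- proportion_methylated(binarize(truth_cm), ds$meta)
  pr_counts <- proportion_methylated(st, ds$meta)
  expect_equal(pr_truth$proportion, pr_counts$proportion)
})

test_that("group change summaries distinguish consensus from pooled counts", {
  # two individuals; locus 1 gains in both, locus 2 gains in one
  x <- two_stage_states(rbind(c(1L, 1L, 0L), c(1L, 0L, 0L)),
                        rbind(c(0L, 0L, 0L), c(0L, 0L, 1L)))
  cons <- suppressWarnings(group_change_summary(x$states, x$meta, "consensus"))
  pool <- suppressWarnings(group_change_summary(x$states, x$meta, "pooled"))
  hf <- cons$transition == "hatchling->fledgling" & cons$dispersal == "disperser"
  expect_equal(cons$n_gain[hf], 1L)
  expect_equal(pool$n_gain[hf], 3L)
  expect_equal(pool$n_loss[hf], 1L)
  # frozen states -> all zero in both modes
  cfg <- flat_config(p = 0.5, c = 0, n_ind = 2, n_loci = 100, seed = 4)
  ds <- simulate_experiment(cfg)
  st <- binarize(ds$counts)
  for (mode in c("consensus", "pooled")) {
    gs <- group_change_summary(st, ds$meta, mode)
    expect_true(all(gs$n_gain == 0L & gs$n_loss == 0L))
  }
})

test_that("consensus gain counts follow the independence product at rate g^4", {
  # 4 individuals flipping independently: E[consensus gains] = L * g_eff^4
  # where g_eff = P(unmethylated locus gains) from the kernel
  cfg <- flat_config(p = 0.5, c = 0.4, n_ind = 4, n_loci = 20000, seed = 37)
  ds <- simulate_experiment(cfg)
  st <- binarize(ds$counts)
  gs <- group_change_summary(st, ds$meta, "consensus")
  k <- transition_kernel(0.5, 0.5, 0.4)
  # a consensus gain needs the locus unmethylated then gaining in all 4
  p1 <- (1 - 0.5) * k[["gain"]]
  expected <- 20000 * p1^4
  hf <- gs$transition == "hatchling->fledgling"
  se <- sqrt(20000 * p1^4 * (1 - p1^4))
  expect_true(all(abs(gs$n_gain[hf] - expected) <= 4 * se + 1))
})
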