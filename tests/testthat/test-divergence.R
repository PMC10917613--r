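test_that("tvi hits its range endpoints and hand-computed values", {
  p <- profile(A = 60, B = 40)
  expect_equal(tvi(p, p), 0)
  expect_equal(tvi(profile(X = 100), profile(Y = 100)), 200)
  expect_equal(tvi(profile(X = 60, Y = 40), profile(X = 40, Y = 60)), 40)
})

test_that("tvi refuses unnormalized input rather than rescaling", {
  expect_error(tvi(profile(A = 50), profile(A = 100)),
               "renormalize", class = "saponinbias_normalization_error")
  expect_error(tvi(profile(A = 100), profile(A = 60, B = 30)),
               class = "saponinbias_normalization_error")
})

test_that("tvi is a symmetric metric matching an independent oracle", {
  withr::with_seed(42, {
    for (i in 1:50) {
      a <- random_profile(sample(2:10, 1))
      b <- random_profile(sample(2:10, 1))
      c_ <- random_profile(sample(2:10, 1))
      expect_equal(tvi(a, b), oracle_tvi(a, b), tolerance = 1e-12)
      expect_equal(tvi(a, b), tvi(b, a))
      expect_lte(tvi(a, c_), tvi(a, b) + tvi(b, c_) + 1e-9)
      expect_gte(tvi(a, b), 0)
      expect_lte(tvi(a, b), 200 + 1e-9)
    }
  })
})

test_that("compare_profiles reports deltas, lost and gained taxa", {
  cmp <- compare_profiles(profile(A = 70, B = 30), profile(A = 100))
  expect_equal(cmp$tvi, 60)
  expect_equal(cmp$lost$taxon, "B")
  expect_equal(cmp$lost$abundance, 30)
  expect_equal(nrow(cmp$gained), 0)

  same <- compare_profiles(profile(A = 100), profile(A = 100))
  expect_equal(same$tvi, 0)
  expect_equal(nrow(same$lost), 0)
  expect_equal(nrow(same$gained), 0)

  thr <- compare_profiles(profile(A = 99, B = 1), profile(A = 99, C = 1),
                          presence_threshold = 2)
  expect_equal(thr$tvi, 2)
  expect_equal(nrow(thr$lost), 0)
  expect_equal(nrow(thr$gained), 0)
})

test_that("comparison report invariants hold and ordering is deterministic", {
  u <- profile(A = 40, B = 25, C = 25, D = 10)
  t_ <- profile(A = 50, E = 25, F = 25)
  cmp <- compare_profiles(u, t_)
  expect_equal(cmp$tvi, sum(abs(cmp$deltas$delta)), tolerance = 1e-9)
  expect_true(all(cmp$deltas$abundance_treated[
    cmp$deltas$taxon %in% cmp$lost$taxon] == 0))
  expect_true(all(cmp$deltas$abundance_untreated[
    cmp$deltas$taxon %in% cmp$gained$taxon] == 0))
  # descending abundance, ties broken lexicographically
  expect_equal(cmp$lost$taxon, c("B", "C", "D"))
  expect_equal(cmp$gained$taxon, c("E", "F"))

  td <- tidy(cmp)
  expect_setequal(td$status[td$taxon %in% c("B", "C", "D")], "lost")
  expect_equal(glance(cmp)$n_lost, 3)
})

test_that("subsampling draws exactly depth reads and is seed-reproducible", {
  counts <- ten_taxon_counts()
  expect_equal(subsample_counts(counts, sum(counts$count)), counts)
  sub <- subsample_counts(counts, 200, seed = 9)
  expect_equal(sum(sub$count), 200)
  expect_equal(sub, subsample_counts(counts, 200, seed = 9))
  expect_error(subsample_counts(counts, sum(counts$count) + 1),
               class = "saponinbias_depth_error")
  expect_error(subsample_counts(counts, 0),
               class = "saponinbias_empty_count_error")
})

test_that("subsampled counts have the hypergeometric mean", {
  counts <- count_table(a = 50, b = 30, c = 20)
  n_total <- 100
  depth <- 30
  n_reps <- 3000
  draws <- withr::with_seed(1234, {
    vapply(seq_len(n_reps), function(i) {
      subsample_counts(counts, depth)$count
    }, numeric(3))
  })
  means <- rowMeans(draws)
  for (i in 1:3) {
    m <- counts$count[i]
    mu <- depth * m / n_total
    v <- depth * (m / n_total) * (1 - m / n_total) *
      (n_total - depth) / (n_total - 1)
    expect_lt(abs(means[i] - mu), 3 * sqrt(v / n_reps))
  }
})

test_that("comparability check is zero at full depth and for one taxon", {
  counts <- ten_taxon_counts()
  full <- comparability_check(counts, sum(counts$count), n_reps = 5, seed = 1)
  expect_true(all(full$replicates$tvi == 0))
  single <- comparability_check(count_table(only = 5000), 37, n_reps = 5,
                                seed = 1)
  expect_true(all(single$replicates$tvi == 0))
})

test_that("two equal taxa at depth 200 match the brute-force oracle", {
  counts <- count_table(a = 10000, b = 10000)
  n_reps <- 1000
  chk <- comparability_check(counts, 200, n_reps = n_reps, seed = 7)
  oracle <- withr::with_seed(1007, oracle_subsample_tvi(counts, 200, n_reps))
  se <- sqrt(stats::var(chk$replicates$tvi) / n_reps +
               stats::var(oracle) / n_reps)
  expect_lt(abs(mean(chk$replicates$tvi) - mean(oracle)), 3 * se)
})

test_that("subsampling TVI decreases stochastically with depth", {
  counts <- ten_taxon_counts()
  shallow <- glance(comparability_check(counts, 50, n_reps = 300, seed = 3))
  deep <- glance(comparability_check(counts, 5000, n_reps = 300, seed = 3))
  expect_gt(shallow$mean_tvi, deep$mean_tvi)
})
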