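test_that("community construction honours its parameters", {
  solo <- make_community(1, host_to_bacteria_ratio = 0, seed = 1)
  expect_equal(sum(solo$gram == "host"), 1)
  expect_equal(solo$copies[solo$gram == "host"], 0)
  expect_equal(nrow(solo), 2)

  comm <- make_community(8, host_to_bacteria_ratio = 9, seed = 2)
  bact <- comm$copies[comm$gram != "host"]
  expect_equal(comm$copies[comm$gram == "host"], 9 * sum(bact))

  flat <- make_community(20, abundance_spread = 0, seed = 3)
  cv <- flat$copies[flat$gram != "host"]
  expect_true(all(abs(cv / mean(cv) - 1) < 0.01))

  expect_error(make_community(0), class = "saponinbias_validation_error")
  expect_error(make_community(5, gram_neg_fraction = 1.5),
               class = "saponinbias_validation_error")
  expect_equal(make_community(5, seed = 9), make_community(5, seed = 9))
})

test_that("depletion multiplies copies by class survival exp(-k c)", {
  comm <- tibble::tibble(
    taxon = c("n", "p", "Homo sapiens"),
    gram = c("gram_negative", "gram_positive", "host"),
    copies = c(100, 100, 1000)
  )
  model <- depletion_model(k_host = 2, k_gram_neg = 0.8, k_gram_pos = 0)

  same <- apply_depletion(comm, 0, model)
  expect_equal(same, comm)

  depleted <- apply_depletion(comm, 1, model)
  expect_equal(depleted$copies[depleted$gram == "host"], 1000 * exp(-2),
               tolerance = 1e-9) # ~135.335
  expect_equal(depleted$copies[depleted$taxon == "p"], 100)
  expect_equal(depleted$copies[depleted$taxon == "n"], 100 * exp(-0.8))

  expect_error(apply_depletion(comm, -0.1, model),
               class = "saponinbias_validation_error")
  expect_error(depletion_model(k_host = -1),
               class = "saponinbias_validation_error")
})

test_that("sequencing conserves depth and books host filtering correctly", {
  comm <- make_community(5, host_to_bacteria_ratio = 1, seed = 4)
  seqd <- sequence_community(comm, depth = 10000, seed = 5)
  expect_equal(sum(seqd$counts$count), 10000)
  expect_equal(seqd$accounting$high_quality_reads, 10000)
  expect_equal(seqd$accounting$retained_after_host_filter,
               10000 - host_reads(seqd$counts))

  host_free <- make_community(5, host_to_bacteria_ratio = 0, seed = 4)
  sf <- sequence_community(host_free, depth = 5000, seed = 5)
  expect_equal(percent_host_filtered(sf$accounting)$pct_host_filtered, 0)

  host_only <- tibble::tibble(taxon = "Homo sapiens", gram = "host",
                              copies = 10)
  ho <- sequence_community(host_only, depth = 1000, seed = 5)
  expect_equal(ho$accounting$retained_after_host_filter, 0)

  empty <- tibble::tibble(taxon = "x", gram = "gram_positive", copies = 0)
  expect_error(sequence_community(empty, 100),
               class = "saponinbias_empty_community_error")
})

test_that("drawn host fraction sits within binomial error of its probability", {
  comm <- tibble::tibble(
    taxon = c("a", "Homo sapiens"),
    gram = c("gram_positive", "host"),
    copies = c(1, 1)
  )
  depth <- 1e6
  seqd <- sequence_community(comm, depth = depth, seed = 10)
  frac <- host_reads(seqd$counts) / depth
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / depth))
})

test_that("misclassification reroutes bacterial reads to unclassified", {
  comm <- make_community(4, host_to_bacteria_ratio = 1, seed = 6)
  all_mis <- sequence_community(comm, depth = 2000,
                                misclassification_rate = 1, seed = 7)
  bacterial <- setdiff(all_mis$counts$taxon, c("Homo sapiens", "unclassified"))
  expect_true(all(all_mis$counts$count[all_mis$counts$taxon %in% bacterial] == 0))
  expect_equal(unclassified_reads(all_mis$counts) +
                 host_reads(all_mis$counts), 2000)
})

test_that("empirical composition matches the depletion expectation at high depth", {
  comm <- make_community(6, host_to_bacteria_ratio = 0.5, seed = 11)
  model <- depletion_model()
  conc <- 1.0
  depleted <- apply_depletion(comm, conc, model)
  depth <- 1e6
  seqd <- sequence_community(depleted, depth = depth, seed = 12)
  p_true <- depleted$copies / sum(depleted$copies)
  p_hat <- seqd$counts$count[match(depleted$taxon, seqd$counts$taxon)] / depth
  se <- sqrt(p_true * (1 - p_true) / depth)
  expect_true(all(abs(p_hat - p_true) <= 3 * se + 1e-12))
})

test_that("scenario runs are deterministic and write a complete directory", {
  cfg <- default_scenario(
    concentrations = c(0, 0.5, 2),
    sequencing = list(depth = 5000, misclassification_rate = 0)
  )
  s1 <- run_scenario(cfg, seed = 13)
  s2 <- run_scenario(cfg, seed = 13)
  expect_identical(s1, s2)
  expect_equal(s1$concentration, c(0, 0.5, 2))

  out <- withr::local_tempdir()
  run_scenario(cfg, seed = 13, out_dir = out)
  expect_true(all(file.exists(file.path(out, c(
    "manifest.tsv", "accounting.tsv", "ground_truth.json",
    "counts_c0.tsv", "profile_c2.tsv"
  )))))
  truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$model$k_gram_neg, 0.8)
})

test_that("scenario config violations name the offending keys", {
  cfg <- default_scenario()
  cfg$model$k_host <- NULL
  expect_error(run_scenario(cfg), "model.k_host",
               class = "saponinbias_validation_error")
  cfg2 <- default_scenario(concentrations = c(1, 1))
  expect_error(run_scenario(cfg2), "concentrations",
               class = "saponinbias_validation_error")
})

test_that("a single-concentration scenario reproduces the untreated community", {
  cfg <- default_scenario(
    concentrations = 0,
    sequencing = list(depth = 20000, misclassification_rate = 0)
  )
  s <- run_scenario(cfg, seed = 14)
  expect_equal(nrow(s), 1)
  comm <- attr(s, "community")
  p_true <- comm$copies / sum(comm$copies)
  p_hat <- s$counts[[1]]$count[match(comm$taxon, s$counts[[1]]$taxon)] / 20000
  se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_true(all(abs(p_hat - p_true) <= 4 * se + 1e-12))
})
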