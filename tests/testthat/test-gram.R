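ann2 <- tibble::tibble(
  taxon = c("A", "B"),
  gram = c("gram_negative", "gram_positive")
)

test_that("gram fractions aggregate by class and bucket unannotated taxa", {
  one <- gram_fractions(profile(A = 100),
                        tibble::tibble(taxon = "A", gram = "gram_negative"))
  expect_equal(unlist(one), c(gram_negative_pct = 100, gram_positive_pct = 0,
                              unknown_pct = 0))
  even <- gram_fractions(profile(A = 50, B = 50), ann2)
  expect_equal(even$gram_negative_pct, 50)
  expect_equal(even$gram_positive_pct, 50)

  mixed <- gram_fractions(profile(A = 70, B = 20, C = 10), ann2)
  expect_equal(unlist(mixed), c(gram_negative_pct = 70, gram_positive_pct = 20,
                                unknown_pct = 10))
})

test_that("gram fractions conserve total abundance, normalized or not", {
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- random_profile(6)
      p$abundance <- p$abundance * stats::runif(1, 0.1, 3)
      ann <- tibble::tibble(
        taxon = sample(p$taxon, 4),
        gram = sample(c("gram_negative", "gram_positive"), 4, replace = TRUE)
      )
      g <- gram_fractions(p, ann)
      expect_equal(g$gram_negative_pct + g$gram_positive_pct + g$unknown_pct,
                   sum(p$abundance), tolerance = 1e-9)
    }
  })
})

test_that("empty profile yields zero fractions with a warning", {
  empty <- tibble::tibble(taxon = character(), abundance = double())
  expect_warning(g <- gram_fractions(empty), "empty")
  expect_equal(unlist(g), c(gram_negative_pct = 0, gram_positive_pct = 0,
                            unknown_pct = 0))
})

test_that("dose response recovers slope and rank correlation exactly on collinear points", {
  series <- tibble::tibble(
    concentration = c(0, 1, 2),
    profile = list(profile(A = 80, B = 20), profile(A = 60, B = 40),
                   profile(A = 40, B = 60))
  )
  dr <- dose_response(series, ann2)
  expect_equal(dr$slope, -20)
  expect_equal(dr$spearman_rho, -1)
  expect_equal(tidy(dr)$gram_negative_pct, c(80, 60, 40))
})

test_that("dose response flags an undefined correlation for flat series", {
  series <- tibble::tibble(
    concentration = c(0, 1),
    profile = list(profile(A = 50, B = 50), profile(A = 50, B = 50))
  )
  dr <- dose_response(series, ann2)
  expect_equal(dr$slope, 0)
  expect_true(is.na(dr$spearman_rho))
})

test_that("series validation rejects duplicates and negatives", {
  dup <- tibble::tibble(
    concentration = c(1, 1),
    profile = list(profile(A = 100), profile(A = 100))
  )
  expect_error(dose_response(dup, ann2), "duplicate",
               class = "saponinbias_validation_error")
  neg <- tibble::tibble(concentration = -1, profile = list(profile(A = 100)))
  expect_error(dose_response(neg, ann2), class = "saponinbias_validation_error")
})

test_that("survival contrast recovers a noise-free rate difference exactly", {
  # k_A - k_B = 1.0 per % wt/vol; beta_A with reference B must be -1.0
  series <- decay_series(c("A", "B"), a0 = c(30, 70), k = c(1.2, 0.2),
                         concentrations = c(0, 1, 2))
  fit <- survival_contrast(series, ref_taxon = "B")
  expect_equal(tidy(fit)$beta, -1.0, tolerance = 1e-10)
})

test_that("identical profiles across concentrations give all-zero betas", {
  series <- tibble::tibble(
    concentration = c(0, 0.5, 1),
    profile = list(profile(A = 60, B = 40), profile(A = 60, B = 40),
                   profile(A = 60, B = 40))
  )
  fit <- survival_contrast(series, ref_taxon = "B")
  expect_equal(tidy(fit)$beta, 0, tolerance = 1e-12)
})

test_that("survival contrast is invariant to per-profile rescaling", {
  series <- decay_series(c("A", "B", "C"), a0 = c(20, 30, 50),
                         k = c(0.9, 0.4, 0.1), concentrations = c(0, 1, 2, 3))
  scaled <- series
  scaled$profile <- lapply(seq_along(scaled$profile), function(i) {
    p <- scaled$profile[[i]]
    p$abundance <- p$abundance * (1 + i)
    p
  })
  expect_equal(tidy(survival_contrast(series, "C")),
               tidy(survival_contrast(scaled, "C")), tolerance = 1e-10)
})

test_that("survival contrast enforces the reference and drops zeroed taxa", {
  series <- tibble::tibble(
    concentration = c(0, 1),
    profile = list(profile(A = 50, B = 30, C = 20), profile(A = 60, B = 40))
  )
  expect_error(survival_contrast(series, "C"),
               class = "saponinbias_reference_error")
  expect_warning(fit <- survival_contrast(series, "A"), "dropped")
  expect_equal(tidy(fit)$taxon, "B")
})

test_that("gram_rate_contrast estimates k_neg - k_pos reference-free", {
  # neg taxa decay at 0.8, pos at 0.05: contrast 0.75 whatever the reference
  ann <- tibble::tibble(
    taxon = c("n1", "n2", "p1", "p2"),
    gram = c("gram_negative", "gram_negative", "gram_positive", "gram_positive")
  )
  series <- decay_series(ann$taxon, a0 = c(25, 25, 25, 25),
                         k = c(0.8, 0.8, 0.05, 0.05),
                         concentrations = c(0, 0.5, 1, 2))
  fit <- survival_contrast(series, "p1")
  expect_equal(gram_rate_contrast(fit, ann), 0.75, tolerance = 1e-10)
})
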