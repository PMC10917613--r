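#' Gram-stratified abundance summary of a profile
#'
#' Sums relative abundances by Gram class. Taxa missing from the
#' annotation accumulate in `unknown_pct` — they are never silently
#' dropped or prorated across the two known classes. The three outputs
#' always conserve the input profile's total abundance, so a normalized
#' profile yields fractions summing to 100.
#'
#' @param profile Profile tibble (`taxon`, `abundance`).
#' @param annotation Gram-annotation tibble (`taxon`, `gram`), or `NULL`
#'   (everything lands in `unknown_pct`).
#' @return One-row tibble: `gram_negative_pct`, `gram_positive_pct`,
#'   `unknown_pct`.
#' @examples
#' prof <- tibble::tibble(taxon = c("A", "B", "C"), abundance = c(70, 20, 10))
#' ann <- tibble::tibble(taxon = c("A", "B"),
#'                       gram = c("gram_negative", "gram_positive"))
#' gram_fractions(prof, ann) # 70 / 20 / 10
#' @export
gram_fractions <- function(profile, annotation = NULL) {
  validate_profile(profile)
  if (nrow(profile) == 0L) {
    warning("empty profile: Gram fractions are all zero", call. = FALSE)
    return(tibble::tibble(gram_negative_pct = 0, gram_positive_pct = 0,
                          unknown_pct = 0))
  }
  g <- gram_of(profile$taxon, annotation)
  tibble::tibble(
    gram_negative_pct = sum(profile$abundance[g == "gram_negative"]),
    gram_positive_pct = sum(profile$abundance[g == "gram_positive"]),
    unknown_pct = sum(profile$abundance[g == "unknown"])
  )
}

validate_series <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("concentration", "profile") %in% names(series))) {
    stop_saponinbias(
      "validation",
      "a dose-response series needs columns 'concentration' and 'profile' \\
       (a list-column of profile tibbles)"
    )
  }
  if (any(series$concentration < 0)) {
    stop_saponinbias("validation", "concentrations must be >= 0")
  }
  if (anyDuplicated(series$concentration)) {
    stop_saponinbias("validation", "duplicate concentrations in series")
  }
  invisible(series)
}

#' Gram-class dose-response across saponin concentrations
#'
#' Given one microbial profile per saponin concentration (% wt/vol;
#' concentration 0 is the untreated arm), summarises each by Gram class
#' and quantifies the trend of the Gram-negative share in concentration:
#' the Spearman rank correlation between concentration and
#' `gram_negative_pct`, and the ordinary-least-squares slope of
#' `gram_negative_pct` on concentration (percent points per % wt/vol).
#' Concentration stays on the linear scale — the untreated point at c = 0
#' rules out a log axis, and under an exponential-survival lysis model it
#' is log-abundance that is linear in c. With few points the rank
#' correlation is descriptive; no p-value is attached. If the
#' Gram-negative share is constant the correlation is undefined and
#' returned as `NA`.
#'
#' @param series Tibble with numeric column `concentration` and
#'   list-column `profile` of normalized profile tibbles; at least two
#'   distinct concentrations.
#' @param annotation Gram-annotation tibble.
#' @return Object of class `dose_response`; `tidy()` gives the
#'   per-concentration Gram fractions, `glance()` the slope, intercept and
#'   Spearman rho. Has an [ggplot2::autoplot()] method.
#' @export
dose_response <- function(series, annotation = NULL) {
  validate_series(series)
  if (nrow(series) < 2L) {
    stop_saponinbias("validation",
                     "dose_response() needs at least two concentrations")
  }
  series <- dplyr::arrange(series, .data$concentration)
  fractions <- purrr::map(series$profile, gram_fractions,
                          annotation = annotation) |>
    purrr::list_rbind()
  tab <- dplyr::bind_cols(
    tibble::tibble(concentration = series$concentration), fractions
  )
  fit <- stats::lm(gram_negative_pct ~ concentration, data = tab)
  rho <- if (stats::sd(tab$gram_negative_pct) == 0) {
    NA_real_
  } else {
    stats::cor(tab$concentration, tab$gram_negative_pct, method = "spearman")
  }
  structure(
    list(
      table = tab,
      slope = unname(stats::coef(fit)[["concentration"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      spearman_rho = rho
    ),
    class = "dose_response"
  )
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Gram dose-response over", nrow(x$table), "concentrations\n")
  cat(sprintf("  Gram-negative slope: %.4g pct points per %% wt/vol\n", x$slope))
  cat(sprintf("  Spearman rho (concentration vs Gram-negative %%): %s\n",
              ifelse(is.na(x$spearman_rho), "undefined (constant)",
                     sprintf("%.3f", x$spearman_rho))))
  print(x$table)
  invisible(x)
}

#' @rdname dose_response
#' @param x A `dose_response`.
#' @param ... Unused.
#' @method tidy dose_response
#' @export
tidy.dose_response <- function(x, ...) x$table

#' @rdname dose_response
#' @method glance dose_response
#' @export
glance.dose_response <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    spearman_rho = x$spearman_rho,
    n_concentrations = nrow(x$table)
  )
}

#' Per-taxon survival-rate contrasts from a concentration series
#'
#' Under a differential-lysis model where each taxon's DNA survives
#' treatment at concentration c with probability `exp(-k_t * c)`, the
#' log-ratio of relative abundances between taxon t and a reference taxon
#' is linear in c with slope `k_ref - k_t`: the closure constant of the
#' composition cancels in the ratio. This function fits, by ordinary
#' least squares, `log(p_t(c) / p_ref(c)) = alpha_t + beta_t * c` for
#' every taxon present (abundance > 0) at all concentrations, and
#' returns the fitted `beta_t`.
#'
#' Only contrasts of survival rates are identifiable from relative
#' abundances — never absolute rates; `beta_t` estimates `k_ref - k_t`,
#' and differences `beta_s - beta_t` estimate `k_t - k_s` free of the
#' reference. Estimates are invariant to any per-profile rescaling.
#'
#' @param series Tibble with columns `concentration` and `profile`
#'   (list-column), as for [dose_response()]; at least two concentrations.
#' @param ref_taxon Reference taxon; must have positive abundance at every
#'   concentration.
#' @return Object of class `survival_contrast`; `tidy()` gives one row per
#'   eligible taxon (`taxon`, `beta`, `alpha`, `se_beta`), `glance()` the
#'   reference and counts. Taxa with a zero at any concentration are
#'   dropped from estimation with a warning.
#' @export
survival_contrast <- function(series, ref_taxon) {
  validate_series(series)
  if (nrow(series) < 2L) {
    stop_saponinbias("validation",
                     "survival_contrast() needs at least two concentrations")
  }
  series <- dplyr::arrange(series, .data$concentration)
  long <- purrr::map2(series$profile, series$concentration, function(p, conc) {
    validate_profile(p)
    dplyr::mutate(p, concentration = conc)
  }) |> purrr::list_rbind()

  ref <- dplyr::filter(long, .data$taxon == ref_taxon)
  if (nrow(ref) < nrow(series) || any(ref$abundance <= 0)) {
    stop_saponinbias(
      "reference",
      "reference taxon '{ref_taxon}' must be present (abundance > 0) at all \\
       concentrations"
    )
  }

  n_conc <- nrow(series)
  presence <- long |>
    dplyr::filter(.data$abundance > 0) |>
    dplyr::count(.data$taxon)
  eligible <- setdiff(presence$taxon[presence$n == n_conc], ref_taxon)
  dropped <- setdiff(unique(long$taxon), c(eligible, ref_taxon))
  if (length(dropped) > 0L) {
    warning(sprintf(
      "%d taxon/taxa with a zero at some concentration dropped from estimation: %s",
      length(dropped), paste(dropped, collapse = ", ")), call. = FALSE)
  }

  ref_by_conc <- stats::setNames(ref$abundance, format(ref$concentration))
  fits <- purrr::map(eligible, function(t) {
    d <- dplyr::filter(long, .data$taxon == t)
    y <- log(d$abundance / ref_by_conc[format(d$concentration)])
    fit <- stats::lm(y ~ d$concentration)
    # a noise-free series fits exactly; the perfect-fit notice is expected
    cf <- withCallingHandlers(
      summary(fit)$coefficients,
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    tibble::tibble(
      taxon = t,
      beta = unname(cf[2, 1]),
      alpha = unname(cf[1, 1]),
      se_beta = if (nrow(d) > 2) unname(cf[2, 2]) else NA_real_
    )
  }) |> purrr::list_rbind()
  if (is.null(fits)) {
    fits <- tibble::tibble(taxon = character(), beta = double(),
                           alpha = double(), se_beta = double())
  }
  structure(
    list(
      estimates = dplyr::arrange(fits, .data$beta),
      ref_taxon = ref_taxon,
      n_concentrations = n_conc,
      n_dropped = length(dropped)
    ),
    class = "survival_contrast"
  )
}

#' @export
print.survival_contrast <- function(x, ...) {
  cat(sprintf(
    "Survival-rate contrasts vs '%s' (%d concentrations, %d taxa, %d dropped)\n",
    x$ref_taxon, x$n_concentrations, nrow(x$estimates), x$n_dropped
  ))
  cat("beta_t estimates k_ref - k_t; only contrasts are identifiable.\n")
  print(x$estimates)
  invisible(x)
}

#' @rdname survival_contrast
#' @param x A `survival_contrast`.
#' @param ... Unused.
#' @method tidy survival_contrast
#' @export
tidy.survival_contrast <- function(x, ...) x$estimates

#' @rdname survival_contrast
#' @method glance survival_contrast
#' @export
glance.survival_contrast <- function(x, ...) {
  tibble::tibble(
    ref_taxon = x$ref_taxon,
    n_taxa = nrow(x$estimates),
    n_concentrations = x$n_concentrations,
    n_dropped = x$n_dropped
  )
}

#' Estimate the Gram-class survival-rate contrast
#'
#' Reference-free summary of a [survival_contrast()] fit: the median beta
#' among Gram-positive taxa minus the median among Gram-negative taxa
#' estimates `k_neg - k_pos`, the excess lysis rate of Gram-negative
#' bacteria per % wt/vol saponin.
#'
#' @param contrast A `survival_contrast` object.
#' @param annotation Gram-annotation tibble.
#' @return A number (`NA` if either class has no estimated taxon).
#' @export
gram_rate_contrast <- function(contrast, annotation) {
  est <- contrast$estimates
  g <- gram_of(est$taxon, annotation)
  beta_pos <- est$beta[g == "gram_positive"]
  beta_neg <- est$beta[g == "gram_negative"]
  if (length(beta_pos) == 0L || length(beta_neg) == 0L) {
    return(NA_real_)
  }
  stats::median(beta_pos) - stats::median(beta_neg)
}
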