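#' Taxonomic variation index (TVI) between two profiles
#'
#' The TVI is the sum, over the union of taxa, of absolute differences in
#' relative abundance (percent scale) between two normalized profiles:
#' `sum_t |p_t(a) - p_t(b)|`. A taxon absent from one profile contributes
#' its full abundance in the other. The index ranges from 0 (identical
#' profiles) to 200 (profiles sharing no taxa) and equals 200 times the
#' Bray-Curtis dissimilarity of the two percent vectors.
#'
#' Both inputs must already be normalized (sum 100 within 1e-6);
#' unnormalized input is an error, never silently rescaled — use
#' [renormalize()] first.
#'
#' @param a,b Normalized profile tibbles (`taxon`, `abundance`).
#' @return A number in \[0, 200\].
#' @examples
#' a <- tibble::tibble(taxon = c("X", "Y"), abundance = c(60, 40))
#' b <- tibble::tibble(taxon = c("X", "Y"), abundance = c(40, 60))
#' tvi(a, b) # 40
#' @export
tvi <- function(a, b) {
  validate_profile(a, normalized = TRUE)
  validate_profile(b, normalized = TRUE)
  merged <- merge_profiles(a, b)
  sum(abs(merged$abundance_a - merged$abundance_b))
}

merge_profiles <- function(a, b) {
  dplyr::full_join(
    dplyr::rename(a, abundance_a = "abundance"),
    dplyr::rename(b, abundance_b = "abundance"),
    by = "taxon"
  ) |>
    dplyr::mutate(
      abundance_a = dplyr::coalesce(.data$abundance_a, 0),
      abundance_b = dplyr::coalesce(.data$abundance_b, 0)
    )
}

#' Compare an untreated and a treated profile
#'
#' Produces the full treated-vs-untreated contrast for one sample pair:
#' the TVI, per-taxon signed abundance differences over the union of taxa,
#' and the lost and gained taxa. A taxon is *lost* when its untreated
#' abundance exceeds `presence_threshold` and its treated abundance is
#' exactly zero (absent taxa count as zero); *gained* is symmetric. Lost
#' and gained lists are ordered by descending abundance, ties broken by
#' taxon name.
#'
#' @param untreated,treated Normalized profile tibbles.
#' @param presence_threshold Minimum abundance (percent) for a taxon to
#'   count as present on the side where it occurs. Default 0: any positive
#'   abundance counts.
#' @return An object of class `profile_comparison` with elements `tvi`
#'   (number), `deltas` (tibble: `taxon`, `abundance_untreated`,
#'   `abundance_treated`, `delta` = treated - untreated), `lost`, `gained`
#'   (tibbles), and `presence_threshold`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
compare_profiles <- function(untreated, treated, presence_threshold = 0) {
  validate_profile(untreated, normalized = TRUE)
  validate_profile(treated, normalized = TRUE)
  if (presence_threshold < 0) {
    stop_saponinbias("validation", "presence_threshold must be >= 0")
  }
  merged <- merge_profiles(untreated, treated)
  deltas <- tibble::tibble(
    taxon = merged$taxon,
    abundance_untreated = merged$abundance_a,
    abundance_treated = merged$abundance_b,
    delta = merged$abundance_b - merged$abundance_a
  )
  lost <- deltas |>
    dplyr::filter(.data$abundance_untreated > presence_threshold,
                  .data$abundance_treated == 0) |>
    dplyr::select("taxon", abundance = "abundance_untreated") |>
    dplyr::arrange(dplyr::desc(.data$abundance), .data$taxon)
  gained <- deltas |>
    dplyr::filter(.data$abundance_treated > presence_threshold,
                  .data$abundance_untreated == 0) |>
    dplyr::select("taxon", abundance = "abundance_treated") |>
    dplyr::arrange(dplyr::desc(.data$abundance), .data$taxon)
  structure(
    list(
      tvi = sum(abs(deltas$delta)),
      deltas = deltas,
      lost = lost,
      gained = gained,
      presence_threshold = presence_threshold
    ),
    class = "profile_comparison"
  )
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("Profile comparison (treated vs untreated)\n")
  cat(sprintf("  TVI: %.4g (range 0-200)\n", x$tvi))
  cat(sprintf("  taxa in union: %d | lost: %d | gained: %d\n",
              nrow(x$deltas), nrow(x$lost), nrow(x$gained)))
  if (nrow(x$lost) > 0) {
    cat("  top lost:", paste(utils::head(x$lost$taxon, 3), collapse = ", "), "\n")
  }
  if (nrow(x$gained) > 0) {
    cat("  top gained:", paste(utils::head(x$gained$taxon, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a profile comparison into per-taxon rows
#'
#' @param x A `profile_comparison`.
#' @param ... Unused.
#' @return Tibble with one row per taxon in the union: abundances on both
#'   sides, the signed difference `delta`, and a `status` column
#'   (`"lost"`, `"gained"` or `"shared"`).
#' @method tidy profile_comparison
#' @export
tidy.profile_comparison <- function(x, ...) {
  dplyr::mutate(
    x$deltas,
    status = dplyr::case_when(
      .data$taxon %in% x$lost$taxon ~ "lost",
      .data$taxon %in% x$gained$taxon ~ "gained",
      TRUE ~ "shared"
    )
  )
}

#' @rdname tidy.profile_comparison
#' @return For `glance()`: a one-row tibble with `tvi`, `n_taxa`,
#'   `n_lost`, `n_gained`.
#' @method glance profile_comparison
#' @export
glance.profile_comparison <- function(x, ...) {
  tibble::tibble(
    tvi = x$tvi,
    n_taxa = nrow(x$deltas),
    n_lost = nrow(x$lost),
    n_gained = nrow(x$gained)
  )
}

#' Subsample a count table to a fixed depth without replacement
#'
#' Draws exactly `depth` reads from the pooled reads of the table
#' (taxon, host and unclassified bins alike) without replacement — a
#' multivariate hypergeometric draw, i.e. rarefaction of the classified
#' read pool. Bin draws are generated sequentially by conditional
#' [stats::rhyper()] calls, so large tables need no read expansion.
#'
#' @param counts Count-table tibble (`taxon`, `count`).
#' @param depth Number of reads to keep; must be `>= 1` and at most the
#'   table total.
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return A count-table tibble with the same rows, counts summing to
#'   `depth`.
#' @export
subsample_counts <- function(counts, depth, seed = NULL) {
  validate_counts(counts)
  total <- sum(counts$count)
  if (depth > total) {
    stop_saponinbias("depth",
                     "depth {depth} exceeds the {total} reads available")
  }
  if (depth < 1) {
    stop_saponinbias("empty_count", "depth must be at least 1 read")
  }
  draw <- function() {
    n <- counts$count
    out <- integer(length(n))
    rest <- total
    k <- depth
    for (i in seq_along(n)) {
      rest <- rest - n[i]
      out[i] <- stats::rhyper(1, m = n[i], n = rest, k = k)
      k <- k - out[i]
    }
    out
  }
  new_counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  dplyr::mutate(counts, count = new_counts)
}

#' Subsampling comparability check
#'
#' Verifies that a fixed sequencing depth is sufficient for profile
#' comparison: repeatedly subsamples the table to `depth` reads, converts
#' each replicate to a microbial profile, and computes its TVI against the
#' full-depth profile. The distribution of TVIs is reported descriptively;
#' no pass/fail verdict is attached — smallness is for the analyst to
#' judge against the profile differences of interest.
#'
#' @param counts Count-table tibble.
#' @param depth Subsampling depth (e.g. 200 reads).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @inheritParams as_profile
#' @return An object of class `comparability_check`; `tidy()` gives one
#'   row per replicate (`replicate`, `tvi`), `glance()` the mean / sd /
#'   min / max TVI. Replicates whose subsample contains no microbial reads
#'   yield `NA` with a warning.
#' @export
comparability_check <- function(counts, depth, n_reps, seed = NULL,
                                host_taxon = "Homo sapiens") {
  if (n_reps < 1) {
    stop_saponinbias("validation", "n_reps must be >= 1")
  }
  full <- as_profile(counts, host_taxon = host_taxon)
  run <- function() {
    purrr::map_dbl(seq_len(n_reps), function(i) {
      sub <- subsample_counts(counts, depth)
      prof <- tryCatch(
        as_profile(sub, host_taxon = host_taxon),
        saponinbias_empty_profile_error = function(e) NULL
      )
      if (is.null(prof)) NA_real_ else tvi(full, prof)
    })
  }
  tvis <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (anyNA(tvis)) {
    warning("some replicates drew no microbial reads; their TVI is NA",
            call. = FALSE)
  }
  structure(
    list(
      replicates = tibble::tibble(replicate = seq_len(n_reps), tvi = tvis),
      depth = depth,
      full_depth = sum(counts$count)
    ),
    class = "comparability_check"
  )
}

#' @export
print.comparability_check <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Comparability check: %d reps at depth %d (full depth %d)\n  TVI mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
    nrow(x$replicates), x$depth, x$full_depth,
    g$mean_tvi, g$sd_tvi, g$min_tvi, g$max_tvi
  ))
  invisible(x)
}

#' @rdname comparability_check
#' @param x A `comparability_check`.
#' @param ... Unused.
#' @method tidy comparability_check
#' @export
tidy.comparability_check <- function(x, ...) x$replicates

#' @rdname comparability_check
#' @method glance comparability_check
#' @export
glance.comparability_check <- function(x, ...) {
  v <- x$replicates$tvi
  tibble::tibble(
    depth = x$depth,
    n_reps = length(v),
    mean_tvi = mean(v, na.rm = TRUE),
    sd_tvi = stats::sd(v, na.rm = TRUE),
    min_tvi = min(v, na.rm = TRUE),
    max_tvi = max(v, na.rm = TRUE),
    n_failed = sum(is.na(v))
  )
}
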