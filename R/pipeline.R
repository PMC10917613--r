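#' Evaluate a treated/untreated sample pair
#'
#' The core treated-vs-untreated contrast of a depletion experiment, in
#' one report: profile divergence (TVI, per-taxon deltas, lost/gained
#' taxa), the Gram-class shift, and — when accounting records are
#' supplied — the host-filtered percentages of both arms with the host
#' reduction. Inputs may be profiles or count tables (converted with
#' [as_profile()] defaults).
#'
#' @param untreated,treated Normalized profile tibbles (`taxon`,
#'   `abundance`) or count tables (`taxon`, `count`).
#' @param annotation Gram-annotation tibble; when `NULL`, the Gram section
#'   is emitted with everything in the unknown class, with a warning.
#' @param accounting_untreated,accounting_treated Optional one-row
#'   read-accounting tibbles.
#' @param presence_threshold Passed to [compare_profiles()].
#' @return Object of class `evaluation_report` with elements `comparison`
#'   (a `profile_comparison`), `gram` (per-arm fractions plus
#'   `gram_negative_shift_pp`), `host` (or `NULL`) and `provenance`.
#' @export
evaluate_pair <- function(untreated, treated, annotation = NULL,
                          accounting_untreated = NULL,
                          accounting_treated = NULL,
                          presence_threshold = 0) {
  untreated <- ensure_profile(untreated)
  treated <- ensure_profile(treated)
  if (is.null(annotation)) {
    warning("no Gram annotation supplied: Gram fractions reported as unknown",
            call. = FALSE)
  }
  comparison <- compare_profiles(untreated, treated,
                                 presence_threshold = presence_threshold)
  gram_u <- gram_fractions(untreated, annotation)
  gram_t <- gram_fractions(treated, annotation)
  gram <- dplyr::bind_rows(
    dplyr::mutate(gram_u, arm = "untreated", .before = 1),
    dplyr::mutate(gram_t, arm = "treated", .before = 1)
  )
  host <- NULL
  if (!is.null(accounting_untreated) && !is.null(accounting_treated)) {
    host <- host_reduction(treated = accounting_treated,
                           untreated = accounting_untreated)
  }
  structure(
    list(
      comparison = comparison,
      gram = gram,
      gram_negative_shift_pp =
        gram_t$gram_negative_pct - gram_u$gram_negative_pct,
      host = host,
      provenance = list(
        package_version = as.character(utils::packageVersion("saponinbias")),
        presence_threshold = presence_threshold,
        annotated = !is.null(annotation),
        timestamped = FALSE
      )
    ),
    class = "evaluation_report"
  )
}

ensure_profile <- function(x) {
  if (is.data.frame(x) && "count" %in% names(x) && !("abundance" %in% names(x))) {
    return(as_profile(x))
  }
  x
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Depletion-bias evaluation report\n")
  print(x$comparison)
  cat(sprintf("  Gram-negative shift: %+.2f percentage points\n",
              x$gram_negative_shift_pp))
  if (!is.null(x$host)) {
    cat(sprintf("  host filtered: %.2f%% (untreated) -> %.2f%% (treated)\n",
                x$host$pct_untreated, x$host$pct_treated))
  }
  invisible(x)
}

#' @rdname evaluate_pair
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return For `glance()`: a one-row tibble with the headline statistics.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  out <- dplyr::bind_cols(
    glance(x$comparison),
    tibble::tibble(gram_negative_shift_pp = x$gram_negative_shift_pp)
  )
  if (!is.null(x$host)) {
    out <- dplyr::bind_cols(out, x$host)
  }
  out
}

#' Serialize an evaluation report to JSON
#'
#' The JSON round-trips losslessly through [read_report()]: numbers are
#' written at full precision and tables column-wise.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    tvi = report$comparison$tvi,
    presence_threshold = report$comparison$presence_threshold,
    deltas = report$comparison$deltas,
    lost = report$comparison$lost,
    gained = report$comparison$gained,
    gram = report$gram,
    gram_negative_shift_pp = report$gram_negative_shift_pp,
    host = report$host,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_report
#' @return For `read_report()`: the report as an `evaluation_report`.
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(d) {
    if (is.null(d) || (is.data.frame(d) && nrow(d) == 0) || length(d) == 0) {
      return(tibble::tibble(taxon = character(), abundance = double()))
    }
    tibble::as_tibble(d)
  }
  comparison <- structure(
    list(
      tvi = p$tvi,
      deltas = tibble::as_tibble(p$deltas),
      lost = as_tbl(p$lost),
      gained = as_tbl(p$gained),
      presence_threshold = p$presence_threshold
    ),
    class = "profile_comparison"
  )
  structure(
    list(
      comparison = comparison,
      gram = tibble::as_tibble(p$gram),
      gram_negative_shift_pp = p$gram_negative_shift_pp,
      host = if (is.null(p$host)) NULL else tibble::as_tibble(p$host),
      provenance = p$provenance
    ),
    class = "evaluation_report"
  )
}

#' Simulate and evaluate a full depletion experiment
#'
#' End-to-end driver: runs a scenario ([run_scenario()]), evaluates every
#' treated concentration against the untreated (c = 0) arm
#' ([evaluate_pair()]), fits the Gram dose-response ([dose_response()])
#' and the per-taxon survival contrasts ([survival_contrast()]), and
#' collects a per-concentration summary. The reference taxon for the
#' contrast fit is the eligible taxon with the largest minimum abundance
#' across concentrations. Deterministic for a fixed config + seed.
#'
#' @param config Scenario config list or JSON path (see
#'   [default_scenario()]).
#' @param seed Integer seed.
#' @param out_dir Optional directory for per-concentration JSON reports
#'   and a `summary.tsv`.
#' @return Object of class `depletion_evaluation` with elements
#'   `summary` (tibble: concentration, tvi, gram fractions,
#'   pct_host_filtered), `reports` (list of `evaluation_report`),
#'   `dose_response`, `survival_contrast`, `gram_rate_contrast` (estimate
#'   of `k_neg - k_pos`), `noise_floor_tvi` (TVI between the untreated
#'   profile and an independent re-draw at the same depth — the pure
#'   sampling noise against which treatment TVIs should be judged),
#'   `annotation` (true Gram labels), and `scenario`. With a
#'   single-concentration grid the dose-response and contrast fits are
#'   `NULL`.
#' @export
end_to_end <- function(config = default_scenario(), seed = 1,
                       out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    config$concentrations <- as.numeric(config$concentrations)
  }
  scenario <- run_scenario(config, seed = seed)
  community <- attr(scenario, "community")
  annotation <- community |>
    dplyr::filter(.data$gram != "host") |>
    dplyr::select("taxon", "gram")

  untreated_idx <- which(scenario$concentration == 0)
  if (length(untreated_idx) == 0L) {
    stop_saponinbias("validation",
                     "scenario has no untreated (concentration 0) arm")
  }
  untreated_profile <- scenario$profile[[untreated_idx]]

  treated <- scenario[scenario$concentration != 0, ]
  reports <- purrr::map2(
    treated$profile, seq_len(nrow(treated)),
    function(prof, i) {
      evaluate_pair(
        untreated_profile, prof, annotation = annotation,
        accounting_untreated = scenario$accounting[[untreated_idx]],
        accounting_treated = treated$accounting[[i]]
      )
    }
  )
  names(reports) <- treated$sample_id

  series <- dplyr::select(scenario, "concentration", "profile")
  multi <- nrow(series) >= 2L
  dr <- if (multi) dose_response(series, annotation) else NULL
  sc <- if (multi) {
    survival_contrast(series, pick_reference(series))
  } else {
    NULL
  }

  # sampling-noise floor: TVI between the untreated profile and an
  # independent second sequencing draw of the same untreated community
  noise_seed <- (seed + 101L) %% 2147483647L
  redraw <- sequence_community(
    community, depth = config$sequencing$depth,
    seed = noise_seed, sample_id = "untreated_replicate"
  )
  noise_floor_tvi <- tvi(untreated_profile, as_profile(redraw$counts))

  acc <- purrr::list_rbind(scenario$accounting)
  host_pct <- percent_host_filtered(acc)$pct_host_filtered
  ord <- order(scenario$concentration)
  gram_tab <- if (multi) {
    tidy(dr)
  } else {
    dplyr::bind_cols(
      tibble::tibble(concentration = scenario$concentration[ord]),
      gram_fractions(untreated_profile, annotation)
    )
  }
  summary_tab <- dplyr::bind_cols(
    gram_tab,
    tibble::tibble(
      pct_host_filtered = host_pct[ord],
      tvi = purrr::map_dbl(
        scenario$profile[ord],
        ~ tvi(untreated_profile, .x)
      )
    )
  )
  out <- structure(
    list(
      summary = summary_tab,
      reports = reports,
      dose_response = dr,
      survival_contrast = sc,
      gram_rate_contrast =
        if (is.null(sc)) NA_real_ else gram_rate_contrast(sc, annotation),
      noise_floor_tvi = noise_floor_tvi,
      annotation = annotation,
      scenario = scenario,
      seed = seed
    ),
    class = "depletion_evaluation"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(reports, function(r, nm) {
      write_report(r, file.path(out_dir, paste0("report_", nm, ".json")))
    })
    utils::write.table(summary_tab, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# reference taxon: present everywhere, largest minimum relative abundance
pick_reference <- function(series) {
  long <- purrr::map2(series$profile, series$concentration, function(p, conc) {
    dplyr::mutate(p, concentration = conc)
  }) |> purrr::list_rbind()
  n_conc <- nrow(series)
  stats_tab <- long |>
    dplyr::filter(.data$abundance > 0) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(n = dplyr::n(), min_ab = min(.data$abundance),
                     .groups = "drop") |>
    dplyr::filter(.data$n == n_conc) |>
    dplyr::arrange(dplyr::desc(.data$min_ab), .data$taxon)
  if (nrow(stats_tab) == 0L) {
    stop_saponinbias("reference",
                     "no taxon is present at every concentration")
  }
  stats_tab$taxon[1L]
}

#' @export
print.depletion_evaluation <- function(x, ...) {
  cat("End-to-end depletion evaluation (seed", x$seed, ")\n\n")
  print(x$summary)
  if (!is.null(x$dose_response)) {
    cat(sprintf(
      "\nGram-negative slope: %.3f pct points per %% wt/vol; rho = %.3f\n",
      x$dose_response$slope, x$dose_response$spearman_rho
    ))
    cat(sprintf("Estimated k_neg - k_pos: %.3f per %% wt/vol\n",
                x$gram_rate_contrast))
  }
  cat(sprintf("Sampling-noise TVI floor at this depth: %.3f\n",
              x$noise_floor_tvi))
  invisible(x)
}

#' @rdname end_to_end
#' @param x A `depletion_evaluation`.
#' @param ... Unused.
#' @return For `tidy()`: the per-concentration summary tibble.
#' @method tidy depletion_evaluation
#' @export
tidy.depletion_evaluation <- function(x, ...) x$summary

#' @rdname end_to_end
#' @method glance depletion_evaluation
#' @export
glance.depletion_evaluation <- function(x, ...) {
  tibble::tibble(
    n_concentrations = nrow(x$summary),
    gram_negative_slope =
      if (is.null(x$dose_response)) NA_real_ else x$dose_response$slope,
    spearman_rho =
      if (is.null(x$dose_response)) NA_real_ else x$dose_response$spearman_rho,
    gram_rate_contrast = x$gram_rate_contrast,
    max_tvi = max(x$summary$tvi),
    noise_floor_tvi = x$noise_floor_tvi,
    seed = x$seed
  )
}
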