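#' Read a read-accounting table
#'
#' TSV with columns `sample_id`, `reads_produced`, `high_quality_reads`,
#' `retained_after_host_filter` — the three per-sample read totals reported
#' by a quality-filtering + host-alignment pipeline.
#'
#' @param path Path to the TSV (header required).
#' @return A read-accounting tibble.
#' @export
read_accounting <- function(path) {
  acc <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  acc <- tibble::as_tibble(acc)
  validate_accounting(acc)
  acc
}

validate_accounting <- function(acc) {
  needed <- c("sample_id", "reads_produced", "high_quality_reads",
              "retained_after_host_filter")
  missing_cols <- setdiff(needed, names(acc))
  if (length(missing_cols) > 0L) {
    stop_saponinbias(
      "validation",
      "accounting table is missing column(s): {paste(missing_cols, collapse = ', ')}"
    )
  }
  counts <- acc[c("reads_produced", "high_quality_reads",
                  "retained_after_host_filter")]
  neg <- acc$sample_id[rowSums(counts < 0) > 0]
  if (length(neg) > 0L) {
    stop_saponinbias("validation",
                     "negative read counts for sample(s): {paste(neg, collapse = ', ')}")
  }
  bad <- acc$sample_id[
    acc$retained_after_host_filter > acc$high_quality_reads |
      acc$high_quality_reads > acc$reads_produced
  ]
  if (length(bad) > 0L) {
    stop_saponinbias(
      "validation",
      "read totals must satisfy retained <= high-quality <= produced; \\
       violated for sample(s): {paste(bad, collapse = ', ')}"
    )
  }
  invisible(acc)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percent of high-quality reads filtered as host
#'
#' For each sample, `100 * (high_quality - retained) / high_quality`,
#' rounded half-up at 2 decimals — the rounding that reproduces a printed
#' filtering table bit-exactly from its count columns.
#'
#' @param acc Read-accounting tibble (see [read_accounting()]).
#' @return `acc` with an added numeric column `pct_host_filtered`.
#' @examples
#' acc <- tibble::tibble(
#'   sample_id = "Vaginal-NT", reads_produced = 154701,
#'   high_quality_reads = 151193, retained_after_host_filter = 4266
#' )
#' percent_host_filtered(acc)$pct_host_filtered # 97.18
#' @export
percent_host_filtered <- function(acc) {
  validate_accounting(acc)
  zero <- acc$sample_id[acc$high_quality_reads == 0]
  if (length(zero) > 0L) {
    stop_saponinbias(
      "undefined_percentage",
      "high_quality_reads is zero for sample(s): {paste(zero, collapse = ', ')}; \\
       the host-filtered percentage is undefined"
    )
  }
  dplyr::mutate(
    acc,
    pct_host_filtered = round_half_up(
      100 * (.data$high_quality_reads - .data$retained_after_host_filter) /
        .data$high_quality_reads, 2
    )
  )
}

#' Render a human-readable filtering table
#'
#' One row per sample, in input order, with comma thousands separators on
#' the count columns and the host-filtered percentage formatted as
#' `"NN.NN%"` — the layout of a publication filtering table. Machine
#' consumers should use [percent_host_filtered()], which keeps numbers
#' unformatted.
#'
#' @param acc Read-accounting tibble.
#' @return Tibble of character columns `sample_id`, `reads_produced`,
#'   `high_quality_reads`, `retained_after_host_filter`,
#'   `pct_host_filtered`.
#' @export
filtering_table <- function(acc) {
  if (nrow(acc) == 0L) {
    stop_saponinbias("validation", "empty accounting table")
  }
  withpct <- percent_host_filtered(acc)
  fmt <- function(n) format(n, big.mark = ",", trim = TRUE, scientific = FALSE)
  tibble::tibble(
    sample_id = withpct$sample_id,
    reads_produced = fmt(withpct$reads_produced),
    high_quality_reads = fmt(withpct$high_quality_reads),
    retained_after_host_filter = fmt(withpct$retained_after_host_filter),
    pct_host_filtered = sprintf("%.2f%%", withpct$pct_host_filtered)
  )
}

#' Host-percentage reduction between a treated/untreated pair
#'
#' Compares the host-filtered percentages of a treated sample and its
#' untreated counterpart, reporting the drop both as absolute percentage
#' points (`pct_untreated - pct_treated`) and relative to the untreated
#' percentage (`100 * drop / pct_untreated`). The relative reduction is
#' `NA` when the untreated percentage is zero.
#'
#' @param treated,untreated One-row read-accounting tibbles.
#' @return One-row tibble with `pct_treated`, `pct_untreated`,
#'   `absolute_reduction_pp`, `relative_reduction_pct`.
#' @export
host_reduction <- function(treated, untreated) {
  if (nrow(treated) != 1L || nrow(untreated) != 1L) {
    stop_saponinbias("validation",
                     "host_reduction() compares exactly one treated and one untreated record")
  }
  pt <- percent_host_filtered(treated)$pct_host_filtered
  pu <- percent_host_filtered(untreated)$pct_host_filtered
  abs_red <- pu - pt
  rel_red <- if (pu > 0) 100 * abs_red / pu else NA_real_
  tibble::tibble(
    pct_treated = pt,
    pct_untreated = pu,
    absolute_reduction_pp = abs_red,
    relative_reduction_pct = rel_red
  )
}

#' Published filtering tables bundled as examples
#'
#' Returns the read-accounting records of the saponin depletion study's two
#' filtering tables: `"matrices"` — fourteen treated/untreated pairs across
#' seven biological matrices at 2.5% wt/vol saponin; `"sputum_titration"` —
#' one sputum sample processed at six saponin concentrations plus its
#' untreated control. Only the three count columns are stored; the percent
#' column is recomputed by [percent_host_filtered()].
#'
#' @param which `"matrices"` or `"sputum_titration"`.
#' @return A read-accounting tibble.
#' @export
example_filtering_table <- function(which = c("matrices", "sputum_titration")) {
  which <- match.arg(which)
  fname <- switch(which,
    matrices = "filtering_matrices.tsv",
    sputum_titration = "filtering_sputum_titration.tsv"
  )
  path <- system.file("extdata", fname, package = "saponinbias", mustWork = TRUE)
  read_accounting(path)
}
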