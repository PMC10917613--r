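#' Read a taxonomic profile or classified-read count table
#'
#' Parses a two-column tab-separated table of `taxon<TAB>value`. Lines
#' starting with `#` and blank lines are ignored; a single optional header
#' line (second field non-numeric, e.g. `taxon<TAB>abundance`) is tolerated.
#' The dialect is always declared by the caller — a column of small percent
#' values is indistinguishable from read counts, so it is never sniffed.
#'
#' In the `"count"` dialect, rows named exactly like `host_taxon`
#' (default `"Homo sapiens"`) or `"unclassified"` are kept as reserved rows
#' of the count table; [host_reads()] and [unclassified_reads()] retrieve
#' them, and [as_profile()] routes them out of the microbial denominator.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param dialect `"percent"` for a relative-abundance profile (returns a
#'   tibble with columns `taxon`, `abundance`), `"count"` for classified
#'   read counts (columns `taxon`, `count`; integer-valued).
#' @param host_taxon Taxon name identifying host reads. Matching is exact
#'   (byte-level) on the name string.
#' @return A tibble: `taxon`/`abundance` (percent dialect, not yet
#'   normalized) or `taxon`/`count` (count dialect).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A\t60", "B\t40"), tf)
#' read_profile(tf, "percent")
#' @export
read_profile <- function(path, dialect = c("percent", "count"),
                         host_taxon = "Homo sapiens") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_saponinbias("io", "cannot open profile file '{path}'", path = path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop_saponinbias("parse", "no data lines in '{path}'", path = path)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)

  # tolerate one header line: first data line whose value field is non-numeric
  first <- fields[[1L]]
  if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))) {
    fields <- fields[-1L]
    idx <- idx[-1L]
    if (length(idx) == 0L) {
      stop_saponinbias("parse", "no data lines in '{path}'", path = path)
    }
  }

  parse_line <- function(f, line_no) {
    if (length(f) < 2L) {
      stop_saponinbias(
        "parse", "line {line_no}: expected at least 2 tab-separated columns",
        line = line_no
      )
    }
    value <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(value)) {
      stop_saponinbias(
        "parse", "line {line_no}: non-numeric value '{f[2L]}'", line = line_no
      )
    }
    if (value < 0) {
      stop_saponinbias(
        "parse", "line {line_no}: negative value {value}", line = line_no
      )
    }
    if (dialect == "count" && value != round(value)) {
      stop_saponinbias(
        "parse", "line {line_no}: count '{f[2L]}' is not an integer",
        line = line_no
      )
    }
    tibble::tibble(taxon = f[1L], value = value)
  }
  out <- purrr::list_rbind(Map(parse_line, fields, idx))

  dup <- out$taxon[duplicated(out$taxon)]
  if (length(dup) > 0L) {
    stop_saponinbias(
      "parse", "duplicate taxon name(s): {paste(unique(dup), collapse = ', ')}"
    )
  }
  if (dialect == "percent") {
    dplyr::rename(out, abundance = "value")
  } else {
    dplyr::rename(out, count = "value")
  }
}

#' Write a profile or count table as TSV
#'
#' Writes `taxon<TAB>value` with a header line, at full float precision so a
#' write/read round trip reproduces abundances to better than 1e-9.
#'
#' @param x Tibble with columns `taxon` and `abundance` (or `count`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  value_col <- if ("abundance" %in% names(x)) "abundance" else "count"
  lines <- c(
    paste("taxon", value_col, sep = "\t"),
    paste(x$taxon, format(x[[value_col]], digits = 17, trim = TRUE,
                          scientific = FALSE), sep = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a Gram-annotation table
#'
#' Two-column TSV `taxon<TAB>gram` with gram one of `gram_positive`,
#' `gram_negative`, `unknown`. Taxa absent from the annotation are treated
#' as `unknown` at lookup time ([gram_of()]), never as an error.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `taxon`, `gram`.
#' @export
read_gram_annotation <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) > 0L && length(fields[[1L]]) >= 2L &&
      fields[[1L]][2L] %in% c("gram", "class", "gram_class")) {
    fields <- fields[-1L]
  }
  ann <- purrr::map(fields, function(f) {
    tibble::tibble(taxon = f[1L], gram = f[2L])
  }) |> purrr::list_rbind()
  bad <- setdiff(unique(ann$gram), gram_levels())
  if (length(bad) > 0L) {
    stop_saponinbias(
      "validation",
      "invalid Gram label(s): {paste(bad, collapse = ', ')} \\
       (expected gram_positive, gram_negative or unknown)"
    )
  }
  ann
}

gram_levels <- function() c("gram_negative", "gram_positive", "unknown")

#' Look up Gram class for taxa
#'
#' @param taxa Character vector of taxon names.
#' @param annotation Tibble with columns `taxon`, `gram`, or `NULL`.
#' @return Character vector; unannotated taxa map to `"unknown"`.
#' @export
gram_of <- function(taxa, annotation = NULL) {
  if (is.null(annotation)) {
    return(rep("unknown", length(taxa)))
  }
  g <- annotation$gram[match(taxa, annotation$taxon)]
  g[is.na(g)] <- "unknown"
  g
}

#' Convert a count table to a normalized relative-abundance profile
#'
#' Relative abundance of taxon t is `100 * count(t) / D`, where D sums the
#' included reads. By default both the host row and the unclassified row are
#' excluded from the denominator, matching the convention that microbial
#' relative abundances are percentages of classified microbial reads after
#' host-read filtering.
#'
#' @param counts Tibble with columns `taxon`, `count`.
#' @param exclude_host,exclude_unclassified Drop the host / unclassified
#'   rows from both the numerator set and the denominator.
#' @param host_taxon Name of the host row.
#' @return A normalized profile tibble (`taxon`, `abundance`) summing to
#'   100 within 1e-6.
#' @examples
#' counts <- tibble::tibble(
#'   taxon = c("A", "B", "Homo sapiens"),
#'   count = c(30, 10, 60)
#' )
#' as_profile(counts)                       # A 75, B 25
#' as_profile(counts, exclude_host = FALSE) # A 30, B 10, Homo sapiens 60
#' @export
as_profile <- function(counts, exclude_host = TRUE,
                       exclude_unclassified = TRUE,
                       host_taxon = "Homo sapiens") {
  validate_counts(counts)
  x <- counts
  if (exclude_host) {
    x <- dplyr::filter(x, .data$taxon != host_taxon)
  }
  if (exclude_unclassified) {
    x <- dplyr::filter(x, .data$taxon != "unclassified")
  }
  denom <- sum(x$count)
  if (denom <= 0) {
    stop_saponinbias("empty_profile", "no included reads: denominator is zero")
  }
  tibble::tibble(taxon = x$taxon, abundance = 100 * x$count / denom)
}

#' Renormalize a profile after dropping taxa
#'
#' Drops the named taxa and rescales the remainder to sum to 100,
#' preserving row order. With an empty drop set on an already-normalized
#' profile this is the identity (idempotent).
#'
#' @param profile Profile tibble (`taxon`, `abundance`).
#' @param drop_taxa Character vector of taxon names to remove.
#' @return Normalized profile tibble.
#' @export
renormalize <- function(profile, drop_taxa = character()) {
  validate_profile(profile)
  kept <- dplyr::filter(profile, !(.data$taxon %in% drop_taxa))
  total <- sum(kept$abundance)
  if (total <= 0) {
    stop_saponinbias("empty_profile",
                     "all abundance mass dropped: cannot renormalize")
  }
  dplyr::mutate(kept, abundance = 100 * .data$abundance / total)
}

#' Test whether a profile is normalized
#'
#' @param profile Profile tibble.
#' @param tol Tolerance on the sum (default 1e-6).
#' @return Logical: does the abundance sum equal 100 within `tol`?
#' @export
is_normalized <- function(profile, tol = 1e-6) {
  abs(sum(profile$abundance) - 100) <= tol
}

# --- validators ------------------------------------------------------------

validate_profile <- function(profile, normalized = FALSE) {
  if (!is.data.frame(profile) || !all(c("taxon", "abundance") %in% names(profile))) {
    stop_saponinbias("validation",
                     "a profile needs columns 'taxon' and 'abundance'")
  }
  if (any(profile$abundance < 0)) {
    stop_saponinbias("validation", "negative abundance in profile")
  }
  if (anyDuplicated(profile$taxon)) {
    stop_saponinbias("validation", "duplicate taxon names in profile")
  }
  if (normalized && !is_normalized(profile)) {
    stop_saponinbias(
      "normalization",
      "profile is not normalized (sum = {format(sum(profile$abundance))}); \\
       renormalize() it explicitly"
    )
  }
  invisible(profile)
}

validate_counts <- function(counts) {
  if (!is.data.frame(counts) || !all(c("taxon", "count") %in% names(counts))) {
    stop_saponinbias("validation",
                     "a count table needs columns 'taxon' and 'count'")
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop_saponinbias("validation", "counts must be non-negative integers")
  }
  if (anyDuplicated(counts$taxon)) {
    stop_saponinbias("validation", "duplicate taxon names in count table")
  }
  invisible(counts)
}

#' Host / unclassified read totals of a count table
#'
#' @param counts Tibble with columns `taxon`, `count`.
#' @param host_taxon Name of the host row.
#' @return Integer count (0 when the row is absent).
#' @export
host_reads <- function(counts, host_taxon = "Homo sapiens") {
  sum(counts$count[counts$taxon == host_taxon])
}

#' @rdname host_reads
#' @export
unclassified_reads <- function(counts) {
  sum(counts$count[counts$taxon == "unclassified"])
}

# --- error helper ----------------------------------------------------------

stop_saponinbias <- function(class, msg, ..., call = rlang::caller_env()) {
  rlang::abort(
    glue_msg(msg, env = rlang::caller_env()),
    class = paste0("saponinbias_", class, "_error"),
    ...
  )
}

# minimal {glue}-style interpolation against the caller's environment
glue_msg <- function(msg, env) {
  msg <- gsub("\\\\\n\\s*", " ", msg)
  out <- msg
  m <- gregexpr("\\{[^{}]+\\}", msg)[[1]]
  if (m[1] == -1) return(out)
  exprs <- regmatches(msg, gregexpr("\\{[^{}]+\\}", msg))[[1]]
  for (e in exprs) {
    code <- substr(e, 2, nchar(e) - 1)
    val <- tryCatch(
      paste(format(eval(parse(text = code), envir = env)), collapse = ", "),
      error = function(err) code
    )
    out <- sub(e, val, out, fixed = TRUE)
  }
  out
}
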