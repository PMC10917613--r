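#' Generate a synthetic host + bacterial community
#'
#' Builds the absolute-abundance ground truth the depletion simulator
#' operates on: `n_taxa` bacterial taxa with log-normally distributed DNA
#' copy numbers (copies/mL scale), independent Gram labels, and a host
#' compartment whose copies are a fixed multiple of the total bacterial
#' copies. This emulates clinical matrices ranging from host-dominated
#' (saliva, biopsies; ratio around 9 for ~90% host reads) to bacteria-rich
#' (vaginal swabs; ratio near 0).
#'
#' @param n_taxa Number of bacterial taxa (>= 1).
#' @param gram_neg_fraction Probability each taxon is Gram-negative.
#' @param host_to_bacteria_ratio Host copies as a multiple of total
#'   bacterial copies (0 = host-free).
#' @param abundance_spread Log-normal sdlog of taxon copies; 0 gives equal
#'   abundances.
#' @param seed Optional integer for a reproducible community.
#' @return A community tibble with columns `taxon`, `gram`
#'   (`gram_negative` / `gram_positive` / `host`) and `copies`; the host
#'   compartment is the row `taxon == "Homo sapiens"`.
#' @export
make_community <- function(n_taxa, gram_neg_fraction = 0.5,
                           host_to_bacteria_ratio = 1,
                           abundance_spread = 1, seed = NULL) {
  if (n_taxa < 1) {
    stop_saponinbias("validation", "n_taxa must be >= 1")
  }
  if (gram_neg_fraction < 0 || gram_neg_fraction > 1) {
    stop_saponinbias("validation", "gram_neg_fraction must be in [0, 1]")
  }
  if (host_to_bacteria_ratio < 0 || abundance_spread < 0) {
    stop_saponinbias("validation",
                     "host_to_bacteria_ratio and abundance_spread must be >= 0")
  }
  build <- function() {
    copies <- stats::rlnorm(n_taxa, meanlog = log(1e6), sdlog = abundance_spread)
    gram <- ifelse(stats::runif(n_taxa) < gram_neg_fraction,
                   "gram_negative", "gram_positive")
    tibble::tibble(
      taxon = sprintf("taxon_%02d", seq_len(n_taxa)),
      gram = gram,
      copies = copies
    )
  }
  bacteria <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  host <- tibble::tibble(
    taxon = "Homo sapiens",
    gram = "host",
    copies = host_to_bacteria_ratio * sum(bacteria$copies)
  )
  dplyr::bind_rows(bacteria, host)
}

#' Differential-lysis survival rates
#'
#' One exponential survival-rate parameter per compartment class: after
#' treatment at saponin concentration c (% wt/vol), a class's DNA copies
#' are multiplied by `exp(-k * c)`. The defaults encode the regime a
#' saponin protocol produces — host cells lyse far faster than bacteria,
#' and Gram-negative bacteria (thin wall, outer membrane) faster than
#' Gram-positive (`k_host >> k_gram_neg > k_gram_pos >= 0`).
#'
#' @param k_host,k_gram_neg,k_gram_pos Non-negative decay rates per
#'   % wt/vol.
#' @return A named list of class `depletion_model`.
#' @export
depletion_model <- function(k_host = 2.0, k_gram_neg = 0.8,
                            k_gram_pos = 0.05) {
  ks <- c(k_host = k_host, k_gram_neg = k_gram_neg, k_gram_pos = k_gram_pos)
  if (any(ks < 0)) {
    stop_saponinbias("validation", "survival decay rates must be >= 0")
  }
  structure(as.list(ks), class = "depletion_model")
}

#' Apply concentration-dependent depletion to a community
#'
#' Deterministically multiplies each compartment's copies by its class
#' survival `exp(-k_class * c)`. DNase removal of the released host DNA is
#' folded into `k_host`: only the net host fraction is observable
#' downstream, so lysis and digestion need no separate steps.
#'
#' @param community Community tibble from [make_community()].
#' @param concentration Saponin concentration, % wt/vol (>= 0).
#' @param model A [depletion_model()].
#' @return The community tibble with depleted `copies`.
#' @export
apply_depletion <- function(community, concentration,
                            model = depletion_model()) {
  if (concentration < 0) {
    stop_saponinbias("validation", "concentration must be >= 0")
  }
  k <- c(host = model$k_host,
         gram_negative = model$k_gram_neg,
         gram_positive = model$k_gram_pos,
         unknown = 0)
  dplyr::mutate(
    community,
    copies = .data$copies * unname(exp(-k[.data$gram] * concentration))
  )
}

#' Simulate shallow shotgun sequencing of a community
#'
#' Draws `depth` reads multinomially with probabilities proportional to
#' DNA copies (reads are generated with replacement — sequencing samples
#' molecules from an effectively unbounded library, unlike
#' [subsample_counts()], which selects among already-sequenced reads).
#' Each bacterial read is independently relabeled `"unclassified"` with
#' probability `misclassification_rate`. The companion accounting record
#' mirrors a host-filtering pipeline: all reads count as high quality, and
#' retained reads are those not drawn from the host bin.
#'
#' @param community Community tibble.
#' @param depth Total reads to draw (>= 1).
#' @param misclassification_rate Probability a bacterial read is
#'   relabeled unclassified (default 0).
#' @param seed Optional integer for a reproducible draw.
#' @param sample_id Label written into the accounting record.
#' @return List with `counts` (count-table tibble including
#'   `"Homo sapiens"` and `"unclassified"` rows) and `accounting` (one-row
#'   read-accounting tibble).
#' @export
sequence_community <- function(community, depth, misclassification_rate = 0,
                               seed = NULL, sample_id = "synthetic") {
  if (depth < 1) {
    stop_saponinbias("validation", "depth must be >= 1")
  }
  if (misclassification_rate < 0 || misclassification_rate > 1) {
    stop_saponinbias("validation", "misclassification_rate must be in [0, 1]")
  }
  total <- sum(community$copies)
  if (total <= 0) {
    stop_saponinbias("empty_community",
                     "community has zero total copies; nothing to sequence")
  }
  draw <- function() {
    reads <- as.integer(stats::rmultinom(1, depth, community$copies / total))
    misclassified <- 0L
    if (misclassification_rate > 0) {
      bacterial <- community$gram != "host"
      flips <- stats::rbinom(sum(bacterial), reads[bacterial],
                             misclassification_rate)
      reads[bacterial] <- reads[bacterial] - flips
      misclassified <- sum(flips)
    }
    list(reads = reads, misclassified = misclassified)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  counts <- tibble::tibble(taxon = community$taxon, count = d$reads)
  if (d$misclassified > 0 || misclassification_rate > 0) {
    counts <- dplyr::bind_rows(
      counts,
      tibble::tibble(taxon = "unclassified", count = d$misclassified)
    )
  }
  host <- host_reads(counts)
  accounting <- tibble::tibble(
    sample_id = sample_id,
    reads_produced = depth,
    high_quality_reads = depth,
    retained_after_host_filter = depth - host
  )
  list(counts = counts, accounting = accounting)
}

#' Default simulation scenario
#'
#' The package's reference scenario: a sputum-like matrix with ten
#' bacterial taxa, an even Gram split, host reads near 53% of the
#' untreated library, differential lysis rates
#' `k_host = 2.0, k_gram_neg = 0.8, k_gram_pos = 0.05` per % wt/vol, and
#' the saponin titration grid 0 (untreated), 0.0125, 0.05, 0.1, 0.5, 1.5,
#' 2 and 2.5% wt/vol at a shallow depth of 1e5 reads.
#'
#' @param ... Named overrides of top-level keys (`community`, `model`,
#'   `concentrations`, `sequencing`); sub-lists are replaced wholesale.
#' @return A scenario config list.
#' @export
default_scenario <- function(...) {
  cfg <- list(
    community = list(
      n_taxa = 10,
      gram_neg_fraction = 0.5,
      host_to_bacteria_ratio = 0.53 / 0.47,
      abundance_spread = 1.0
    ),
    model = list(k_host = 2.0, k_gram_neg = 0.8, k_gram_pos = 0.05),
    concentrations = c(0, 0.0125, 0.05, 0.1, 0.5, 1.5, 2, 2.5),
    sequencing = list(depth = 1e5, misclassification_rate = 0)
  )
  utils::modifyList(cfg, list(...))
}

validate_scenario <- function(config) {
  required <- list(
    community = c("n_taxa", "gram_neg_fraction", "host_to_bacteria_ratio",
                  "abundance_spread"),
    model = c("k_host", "k_gram_neg", "k_gram_pos"),
    sequencing = c("depth", "misclassification_rate")
  )
  problems <- character()
  for (section in names(required)) {
    if (is.null(config[[section]]) || !is.list(config[[section]])) {
      problems <- c(problems, section)
    } else {
      missing_keys <- setdiff(required[[section]], names(config[[section]]))
      if (length(missing_keys) > 0L) {
        problems <- c(problems, paste0(section, ".", missing_keys))
      }
    }
  }
  if (is.null(config$concentrations) || length(config$concentrations) < 1 ||
      any(config$concentrations < 0) ||
      anyDuplicated(config$concentrations)) {
    problems <- c(problems, "concentrations")
  }
  if (length(problems) > 0L) {
    stop_saponinbias(
      "validation",
      "invalid scenario config; offending key(s): {paste(problems, collapse = ', ')}"
    )
  }
  invisible(config)
}

#' Run a depletion scenario across a concentration grid
#'
#' Builds one community, applies the depletion model at every
#' concentration in the grid (0 = untreated), sequences each depleted
#' community, and returns the per-concentration count tables, microbial
#' profiles and accounting records together with the ground-truth model.
#' Identical config + seed give byte-identical output. With `out_dir` the
#' datasets are also written as TSVs with a manifest and a ground-truth
#' JSON.
#'
#' @param config Scenario config list (see [default_scenario()]) or a path
#'   to a JSON file with the same structure.
#' @param seed Integer seed driving community construction and every
#'   sequencing draw.
#' @param out_dir Optional directory to write `counts_<c>.tsv`,
#'   `profile_<c>.tsv`, `accounting.tsv`, `manifest.tsv` and
#'   `ground_truth.json`.
#' @return Tibble with one row per concentration: `concentration`,
#'   `sample_id`, list-columns `counts` and `profile`, and nested
#'   `accounting`; attributes `community` (the untreated ground truth) and
#'   `model`.
#' @export
run_scenario <- function(config = default_scenario(), seed = 1,
                         out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    config$concentrations <- as.numeric(config$concentrations)
  }
  validate_scenario(config)
  model <- do.call(depletion_model, config$model)
  run <- function() {
    comm <- do.call(make_community, config$community)
    rows <- purrr::imap(sort(config$concentrations), function(conc, i) {
      depleted <- apply_depletion(comm, conc, model)
      sid <- if (conc == 0) "untreated" else sprintf("saponin_%g", conc)
      seqd <- sequence_community(
        depleted, depth = config$sequencing$depth,
        misclassification_rate = config$sequencing$misclassification_rate,
        sample_id = sid
      )
      tibble::tibble(
        concentration = conc,
        sample_id = sid,
        counts = list(seqd$counts),
        profile = list(as_profile(seqd$counts)),
        accounting = list(seqd$accounting)
      )
    })
    list(comm = comm, rows = purrr::list_rbind(rows))
  }
  res <- withr::with_seed(seed, run())
  out <- res$rows
  attr(out, "community") <- res$comm
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  if (!is.null(out_dir)) {
    write_scenario(out, config, out_dir)
  }
  out
}

write_scenario <- function(scenario, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fname <- function(stem, conc) sprintf("%s_c%g.tsv", stem, conc)
  manifest <- purrr::pmap(
    list(scenario$concentration, scenario$counts, scenario$profile),
    function(conc, counts, profile) {
      write_profile(counts, file.path(out_dir, fname("counts", conc)))
      write_profile(profile, file.path(out_dir, fname("profile", conc)))
      tibble::tibble(
        concentration = conc,
        counts_file = fname("counts", conc),
        profile_file = fname("profile", conc)
      )
    }
  ) |> purrr::list_rbind()
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  acc <- purrr::list_rbind(scenario$accounting)
  utils::write.table(acc, file.path(out_dir, "accounting.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    config = config,
    model = unclass(attr(scenario, "model")),
    seed = attr(scenario, "seed"),
    community = attr(scenario, "community")
  )
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
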