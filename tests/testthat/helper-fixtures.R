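# shared fixtures and independent oracles, all built in code

profile <- function(...) {
  v <- c(...)
  tibble::tibble(taxon = names(v), abundance = unname(v))
}

count_table <- function(...) {
  v <- c(...)
  tibble::tibble(taxon = names(v), count = unname(v))
}

# random normalized profile over a shared taxon pool (so pairs overlap)
random_profile <- function(n_taxa, pool_size = 12) {
  taxa <- sample(sprintf("sp%02d", seq_len(pool_size)), n_taxa)
  w <- stats::rgamma(n_taxa, shape = 0.7)
  tibble::tibble(taxon = taxa, abundance = 100 * w / sum(w))
}

# independent TVI oracle: named-vector arithmetic, no package code
oracle_tvi <- function(a, b) {
  av <- stats::setNames(a$abundance, a$taxon)
  bv <- stats::setNames(b$abundance, b$taxon)
  taxa <- union(names(av), names(bv))
  av <- ifelse(is.na(av[taxa]), 0, av[taxa])
  bv <- ifelse(is.na(bv[taxa]), 0, bv[taxa])
  sum(abs(av - bv))
}

# brute-force subsampling oracle: expand reads to labels, sample() without
# replacement, renormalize, take L1 distance to the full-depth composition
oracle_subsample_tvi <- function(counts, depth, n_reps) {
  labels <- rep(counts$taxon, counts$count)
  full <- 100 * counts$count / sum(counts$count)
  names(full) <- counts$taxon
  vapply(seq_len(n_reps), function(i) {
    drawn <- table(sample(labels, depth))
    sub <- 100 * as.numeric(drawn[counts$taxon]) / depth
    sub[is.na(sub)] <- 0
    sum(abs(full - sub))
  }, numeric(1))
}

# fixed 10-taxon count table used by the subsampling checks
ten_taxon_counts <- function() {
  count_table(
    sp01 = 6000, sp02 = 4200, sp03 = 3000, sp04 = 2300, sp05 = 1700,
    sp06 = 1200, sp07 = 800, sp08 = 500, sp09 = 200, sp10 = 100
  )
}

# noise-free exponential-decay series: abundances proportional to
# a0 * exp(-k * c), renormalized to 100 at each concentration
decay_series <- function(taxa, a0, k, concentrations) {
  profs <- lapply(concentrations, function(conc) {
    w <- a0 * exp(-k * conc)
    tibble::tibble(taxon = taxa, abundance = 100 * w / sum(w))
  })
  tibble::tibble(concentration = concentrations, profile = profs)
}
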