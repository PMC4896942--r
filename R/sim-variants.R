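#' Simulate per-locus allele read counts with known dosage
#'
#' For each locus and accession of ploidy `m`, a true dosage `d` is drawn
#' from the configured dosage distribution, total reads `n ~
#' Poisson(mean_depth)`, and alternate-supporting reads `~ Binomial(n,
#' f_eff)` with the error-adjusted alternate fraction
#' `f_eff = (d/m)(1 - e) + (1 - d/m) e`.  Deterministic under the config
#' seed.
#'
#' @param config a [sim_config()]
#' @return list with `counts` (data.table: locus, chrom, pos, ref, alt,
#'   accession, ploidy, ref_count, alt_count) and `truth` (data.table:
#'   locus, accession, dosage)
#' @export
simulate_locus_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_loci
  e <- config$error_rate
  acc <- config$accessions
  pos <- sort(sample.int(n * 50L, n))
  base_pairs <- cbind(sample(DNA_BASES, n, TRUE), NA)
  base_pairs[, 2] <- vapply(base_pairs[, 1], function(r)
    sample(setdiff(DNA_BASES, r), 1L), character(1))
  counts <- vector("list", length(acc))
  truth <- vector("list", length(acc))
  for (a in seq_along(acc)) {
    m <- acc[[a]]
    w <- config$dosage_distribution(m)
    stopifnot(length(w) == m + 1, all(w >= 0), abs(sum(w) - 1) < 1e-8)
    d <- sample(0:m, n, replace = TRUE, prob = w)
    tot <- stats::rpois(n, config$mean_depth)
    f <- (d / m) * (1 - e) + (1 - d / m) * e
    altc <- stats::rbinom(n, tot, f)
    counts[[a]] <- data.table::data.table(
      locus = seq_len(n), chrom = "chr1", pos = pos,
      ref = base_pairs[, 1], alt = base_pairs[, 2],
      accession = names(acc)[a], ploidy = m,
      ref_count = tot - altc, alt_count = altc)
    truth[[a]] <- data.table::data.table(
      locus = seq_len(n), accession = names(acc)[a], ploidy = m, dosage = d)
  }
  list(counts = data.table::rbindlist(counts),
       truth = data.table::rbindlist(truth))
}

#' Simulate randomized variant records for filter testing
#'
#' Generates a [variant_table] whose quality annotations straddle every
#' hard-filter threshold, so that roughly half the records fail at least
#' one rule.  A small fraction (`unfilterable_rate`) lacks MQ and is
#' tagged accordingly.
#'
#' @param n number of records
#' @param n_accessions number of accessions
#' @param seed integer seed
#' @param unfilterable_rate fraction of records with a missing required
#'   annotation
#' @return a [variant_table]
#' @export
simulate_variant_table <- function(n = 1000L, n_accessions = 12L, seed = 1L,
                                   unfilterable_rate = 0.02) {
  set.seed(derive_seed(seed, 2L))
  samples <- sprintf("ACC%02d", seq_len(n_accessions))
  chrom <- sample(sprintf("chr%d", 1:10), n, TRUE)
  pos <- sample.int(2e6L, n, replace = TRUE)
  ref <- sample(DNA_BASES, n, TRUE)
  alt <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1L, prob = c(0.9, 0.08, 0.02))
    sample(setdiff(DNA_BASES, ref[i]), k)
  })
  qual <- stats::runif(n, 0, 200)
  mq <- stats::runif(n, 10, 60)
  bq <- stats::runif(n, 5, 40)
  ad <- lapply(seq_len(n), function(i) {
    nal <- 1L + length(alt[[i]])
    # per-accession depth targeted so sums straddle the 600/3000 window
    mean_dep <- stats::runif(1, 20, 350)
    dep <- stats::rpois(n_accessions, mean_dep)
    altfrac <- stats::runif(1, 0, 0.6)
    m <- matrix(0L, nrow = nal, ncol = n_accessions)
    for (s in seq_len(n_accessions)) {
      a <- stats::rbinom(1L, dep[s], altfrac)
      sp <- if (nal > 2L) {
        stats::rmultinom(1L, a, rep(1, nal - 1L))[, 1]
      } else {
        a
      }
      m[, s] <- c(dep[s] - a, sp)
    }
    if (stats::runif(1) < 0.05) m[, sample.int(n_accessions, 1L)] <- NA_integer_
    m
  })
  unf <- stats::runif(n) < unfilterable_rate
  mq[unf] <- NA_real_
  dt <- data.table::data.table(
    chrom = chrom, pos = pos, id = sprintf("v%d", seq_len(n)),
    ref = ref, alt = alt, qual = qual, mq = mq, bq = bq,
    unfilterable = unf,
    reason = ifelse(unf, "missing MQ", ""),
    ad = ad, caller = "sim")
  new_variant_table(dt, samples)
}
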