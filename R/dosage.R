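#' Dosage-model configuration
#'
#' @param error_rate per-read miscall probability `e` (0 < e < 0.5)
#' @param min_depth minimum total reads to call a genotype
#' @param prior prior weights over dosages `0..m` (`NULL` = uniform), or a
#'   function of `m` returning `m + 1` weights
#' @param tie tie rule between equal-likelihood dosages: `"smaller"`
#'   (default, conservative heterozygosity) — kept explicit for
#'   determinism
#' @return an object of class `dosage_config`
#' @export
dosage_config <- function(error_rate = 0.01, min_depth = 5L, prior = NULL,
                          tie = "smaller") {
  stopifnot(error_rate > 0, error_rate < 0.5, min_depth >= 0)
  structure(list(error_rate = error_rate, min_depth = as.integer(min_depth),
                 prior = prior, tie = tie),
            class = "dosage_config")
}

dosage_prior <- function(config, m) {
  p <- config$prior
  if (is.null(p)) return(rep(1 / (m + 1), m + 1))
  if (is.function(p)) p <- p(m)
  stopifnot(length(p) == m + 1, all(p >= 0))
  p / sum(p)
}

#' Call bi-allelic allele dosage from read counts
#'
#' For a locus in an accession of even ploidy `m`, the dosage `d` (copies
#' of the alternate allele, `0..m`) maximizes the binomial likelihood of
#' the alternate read count with error-adjusted expected alternate
#' fraction `f_d = (d/m)(1 - e) + (1 - d/m) e`, under the configured
#' prior.  Ties resolve to the smaller `d`.  Loci below `min_depth` are
#' no-calls.  Vectorized over loci.
#'
#' @param ref_count,alt_count integer vectors of reference / alternate
#'   supporting reads
#' @param m ploidy (even, 2..12)
#' @param config a [dosage_config()]
#' @return data.table with columns `dosage`, `class` (`hom_ref`,
#'   `hom_alt`, `het`), `is_single_dose` (dosage 1 or m-1),
#'   `is_single_dose_alt` (dosage exactly 1), `ll_best`, `ll_second`,
#'   `no_call`
#' @export
call_dosage <- function(ref_count, alt_count, m, config = dosage_config()) {
  stopifnot(length(ref_count) == length(alt_count),
            all(ref_count >= 0, na.rm = TRUE),
            all(alt_count >= 0, na.rm = TRUE))
  if (m %% 2L != 0L || m < 2L || m > 12L) {
    stop("ploidy must be even and in 2..12, got ", m)
  }
  e <- config$error_rate
  n <- ref_count + alt_count
  f <- (0:m / m) * (1 - e) + (1 - 0:m / m) * e
  logprior <- log(dosage_prior(config, m))
  # loci x (m+1) log-likelihood surface
  ll <- vapply(0:m, function(d) {
    stats::dbinom(alt_count, n, f[d + 1L], log = TRUE) + logprior[d + 1L]
  }, numeric(length(n)))
  if (length(n) == 1L) ll <- matrix(ll, nrow = 1L)
  best <- max.col(ll, ties.method = "first")  # first = smaller d on ties
  ll_sorted <- t(apply(ll, 1L, sort, decreasing = TRUE))
  d <- best - 1L
  no_call <- n < config$min_depth
  d[no_call] <- NA_integer_
  cls <- ifelse(is.na(d), NA_character_,
                ifelse(d == 0L, "hom_ref",
                       ifelse(d == m, "hom_alt", "het")))
  data.table::data.table(
    dosage = d, ploidy = m, class = cls,
    is_single_dose = !is.na(d) & (d == 1L | d == m - 1L),
    is_single_dose_alt = !is.na(d) & d == 1L,
    ll_best = ifelse(no_call, NA_real_, ll_sorted[, 1L]),
    ll_second = ifelse(no_call, NA_real_, ll_sorted[, 2L]),
    no_call = no_call)
}

# all compositions of m into k non-negative parts, lexicographic
compositions_of <- function(m, k) {
  if (k == 1L) return(matrix(m, ncol = 1L))
  out <- list()
  for (first in 0:m) {
    rest <- compositions_of(m - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Call multi-allelic allele dosage
#'
#' Maximizes the multinomial likelihood of per-allele read counts over all
#' compositions of the ploidy `m` into `k` allele copy numbers (exhaustive
#' search; at most `choose(m + 3, 3)` compositions at m = 12, k = 4).
#' Expected read fractions are error-smoothed:
#' `f_i \propto (d_i/m)(1 - e) + (1 - d_i/m) e/(k - 1)`, which reduces to
#' the bi-allelic formula at k = 2.  Ties resolve to the
#' lexicographically smallest composition.
#'
#' @param counts integer vector of per-allele read counts (2--4 alleles,
#'   reference first)
#' @param m ploidy (even, 2..12)
#' @param config a [dosage_config()]
#' @return list with `dosage` (integer vector summing to `m`), `class`,
#'   `is_single_dose`, `ll_best`, `ll_second`, `no_call`
#' @export
call_multiallelic_dosage <- function(counts, m, config = dosage_config()) {
  k <- length(counts)
  if (k < 2L || k > 4L) stop("2-4 alleles supported, got ", k)
  stopifnot(all(counts >= 0))
  if (m %% 2L != 0L || m < 2L || m > 12L) {
    stop("ploidy must be even and in 2..12, got ", m)
  }
  if (sum(counts) < config$min_depth) {
    return(list(dosage = rep(NA_integer_, k), class = NA_character_,
                is_single_dose = NA, ll_best = NA_real_,
                ll_second = NA_real_, no_call = TRUE))
  }
  e <- config$error_rate
  comp <- compositions_of(m, k)
  ll <- apply(comp, 1L, function(d) {
    f <- (d / m) * (1 - e) + (1 - d / m) * e / (k - 1)
    f <- f / sum(f)
    stats::dmultinom(counts, prob = f, log = TRUE)
  })
  ord <- order(ll, decreasing = TRUE)
  d <- comp[ord[1L], ]
  cls <- if (any(d == m)) {
    if (d[1L] == m) "hom_ref" else "hom_alt"
  } else "het"
  list(dosage = as.integer(d), class = cls,
       is_single_dose = any(d == 1L),
       ll_best = ll[ord[1L]], ll_second = ll[ord[2L]], no_call = FALSE)
}

#' Single-dose-marker summary per accession
#'
#' Counts loci flagged single dose (`d` in \{1, m-1\}; the strict `d = 1`
#' count is also reported) and rates over called bi-allelic loci.
#'
#' @param genotypes data.table with columns `accession`, `class`,
#'   `is_single_dose`, `is_single_dose_alt`, `no_call`
#' @return data.table: accession, n_called, n_het, n_sdm, n_sdm_alt,
#'   sdm_rate
#' @export
sdm_table <- function(genotypes) {
  dt <- data.table::as.data.table(genotypes)
  called <- het <- is_single_dose <- is_single_dose_alt <- no_call <- NULL
  out <- dt[, list(
    n_called = sum(!no_call),
    n_het = sum(class == "het" & !no_call, na.rm = TRUE),
    n_sdm = sum(is_single_dose & !no_call, na.rm = TRUE),
    n_sdm_alt = sum(is_single_dose_alt & !no_call, na.rm = TRUE)
  ), by = "accession"]
  out[, "sdm_rate" := ifelse(out$n_called > 0, out$n_sdm / out$n_called, NA_real_)]
  out[]
}

#' Heterozygosity rate
#'
#' Number of heterozygous sites divided by the length of the aligned
#' region.
#'
#' @param genotypes data.table with `class` and `no_call` columns, or an
#'   integer count of heterozygous sites
#' @param aligned_length length of the aligned region (> 0)
#' @return fraction (multiply by 100 for the conventional %% reporting)
#' @export
heterozygosity_rate <- function(genotypes, aligned_length) {
  if (aligned_length <= 0) stop("aligned_length must be > 0")
  n_het <- if (is.numeric(genotypes) && length(genotypes) == 1L) {
    genotypes
  } else {
    sum(genotypes$class == "het" & !genotypes$no_call, na.rm = TRUE)
  }
  n_het / aligned_length
}
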