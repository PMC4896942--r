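#' Simulate an aligned CDS pair with controlled synonymous divergence
#'
#' Builds an ancestral CDS of `length_codons` sense codons (no internal
#' stops) and derives a copy by substituting third positions of 4-fold
#' degenerate codons, with the per-site substitution probability
#' calibrated so that the counting Ks estimator's expectation matches
#' `target_ks`: with `S` synonymous sites (NG86 counting) and `n4` 4-fold
#' sites, the per-site difference probability is
#' `p4 = pS_target * S / n4` where `pS_target` is the Jukes-Cantor
#' p-distance corresponding to `target_ks`.  No indels; no
#' nonsynonymous change (so Ka = 0 exactly).
#'
#' @param length_codons number of codons
#' @param target_ks desired expected Ks (>= 0)
#' @param seed integer seed
#' @return list with `ancestor` and `derived` CDS strings
#' @export
simulate_cds_pair <- function(length_codons, target_ks, seed = 1L) {
  stopifnot(length_codons >= 1, target_ks >= 0)
  set.seed(derive_seed(seed, 5L))
  codons <- sample(SENSE_CODONS, length_codons, replace = TRUE)
  anc <- paste(codons, collapse = "")
  if (target_ks == 0) return(list(ancestor = anc, derived = anc))

  S <- sum(vapply(codons, ng86_codon_syn_sites, numeric(1)))
  four_fold <- which(vapply(codons, is_fourfold_codon, logical(1)))
  n4 <- length(four_fold)
  pS_target <- 0.75 * (1 - exp(-4 / 3 * target_ks))
  if (n4 == 0L) stop("ancestor has no 4-fold degenerate sites")
  p4 <- pS_target * S / n4
  if (p4 > 0.75) {
    max_pS <- 0.75 * n4 / S
    max_ks <- if (max_pS < 0.75) -0.75 * log(1 - 4 / 3 * max_pS) else Inf
    stop(sprintf(paste0("target_ks %.3g not realizable on %d four-fold sites",
                        " (achievable maximum ~ %.3g)"),
                 target_ks, n4, max_ks))
  }
  der <- codons
  hit <- four_fold[stats::runif(n4) < p4]
  for (i in hit) {
    third <- substr(der[i], 3, 3)
    substr(der[i], 3, 3) <- sample(setdiff(DNA_BASES, third), 1L)
  }
  list(ancestor = anc, derived = paste(der, collapse = ""))
}

# TRUE when every third-position change preserves the amino acid
is_fourfold_codon <- function(codon) {
  aa <- translate_codon(codon)
  alts <- paste0(substr(codon, 1, 2), DNA_BASES)
  all(Biostrings::GENETIC_CODE[alts] == aa)
}
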