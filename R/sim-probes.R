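#' Simulate capture probes and their uniquely mapped read counts
#'
#' Probe sequences are drawn with per-probe GC content uniform on 20--80%.
#' A fraction carries a planted hairpin motif (an embedded
#' reverse-complement stem with a short loop), guaranteeing a hairpin
#' score at least the stem length.  Expected read counts follow the linear
#' capture-efficiency surface
#' `reads = b0 + b_gc*GC + b_pmfe*PMFE + b_dimer*Dimer + b_hairpin*Hairpin`
#' (defaults: the model fitted to deep-capture sugarcane data,
#' `164.46 + 5.08*GC + 13.3*PMFE - 2.11*Dimer - 10.67*Hairpin`) plus
#' Gaussian noise of s.d. `config$probe_noise_sd`.
#'
#' @param config a [sim_config()]
#' @param coefficients named numeric vector with elements `intercept`,
#'   `gc`, `pmfe`, `dimer`, `hairpin`
#' @param plant_structure_fraction fraction of probes with a planted
#'   hairpin stem
#' @param stem_length,loop_length planted stem geometry
#' @param pmfe_scale fixed factor mapping this package's pairing-weight
#'   PMFE (about -160..0 for a 120-mer) onto the kcal/mol-like scale the
#'   default coefficients were fitted on (default 0.1); see the methods
#'   vignette
#' @return list with `sequences` (named character), `features` (see
#'   [compute_features()]), `counts` (data.table: probe_id, reads),
#'   `truth` (data.table with the noiseless expected reads and planted
#'   flags)
#' @export
simulate_probes <- function(config,
                            coefficients = c(intercept = 164.46, gc = 5.08,
                                             pmfe = 13.3, dimer = -2.11,
                                             hairpin = -10.67),
                            plant_structure_fraction = 0.2,
                            stem_length = 10L, loop_length = 4L,
                            pmfe_scale = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$probe_length
  if (plant_structure_fraction > 0 && L < 2L * stem_length + loop_length) {
    stop("probe_length ", L, " too short for planted stem (need >= ",
         2L * stem_length + loop_length, ")")
  }
  set.seed(derive_seed(config$seed, 4L))
  np <- config$probe_count
  gc_target <- stats::runif(np, 0.2, 0.8)
  seqs <- vapply(seq_len(np), function(i) random_dna(1L, L, gc_target[i]),
                 character(1))
  planted <- stats::runif(np) < plant_structure_fraction
  for (i in which(planted)) {
    stem <- random_dna(1L, stem_length, 0.5)
    loop <- random_dna(1L, loop_length, 0.5)
    motif <- paste0(stem, loop, revcomp(stem))
    at <- sample.int(L - nchar(motif) + 1L, 1L)
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    s[at:(at + nchar(motif) - 1L)] <- strsplit(motif, "", fixed = TRUE)[[1]]
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("probe%05d", seq_len(np))
  feats <- compute_features(seqs)
  mu <- coefficients[["intercept"]] +
    coefficients[["gc"]] * feats$gc +
    coefficients[["pmfe"]] * (feats$pmfe * pmfe_scale) +
    coefficients[["dimer"]] * feats$dimer +
    coefficients[["hairpin"]] * feats$hairpin
  reads <- mu + stats::rnorm(np, 0, config$probe_noise_sd)
  reads <- pmax(0, round(reads))
  list(sequences = seqs,
       features = feats,
       counts = data.table::data.table(probe_id = names(seqs),
                                       reads = as.integer(reads)),
       truth = data.table::data.table(probe_id = names(seqs),
                                      expected_reads = mu,
                                      planted_hairpin = planted))
}
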