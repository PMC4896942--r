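# NG86-style synonymous site count of one codon: at each position the
# fraction of the 3 possible changes that preserve the amino acid
# (changes creating a stop codon count as nonsynonymous)
ng86_codon_syn_sites <- function(codon) {
  cached <- .polycap_env$syn_sites[[codon]]
  if (!is.null(cached)) return(cached)
  aa <- translate_codon(codon)
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (!(alt %in% STOP_CODONS) && translate_codon(alt) == aa) {
        syn <- syn + 1 / 3
      }
    }
  }
  if (is.null(.polycap_env$syn_sites)) .polycap_env$syn_sites <- list()
  .polycap_env$syn_sites[[codon]] <- syn
  syn
}

# pathway-averaged synonymous / nonsynonymous difference counts between
# two codons: enumerate all orderings of the differing positions, exclude
# pathways passing through stop codons (fall back to all pathways if every
# one is blocked), average the per-step classifications
codon_path_counts <- function(c1, c2) {
  key <- paste(sort(c(c1, c2)), collapse = "|")
  cached <- .polycap_env$paths[[key]]
  if (!is.null(cached)) return(cached)
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffs)) return(c(syn = 0, nonsyn = 0))
  perms <- all_permutations(diffs)
  tally <- matrix(NA_real_, nrow = length(perms), ncol = 2L)
  blocked <- logical(length(perms))
  for (k in seq_along(perms)) {
    cur <- c1
    sy <- ns <- 0
    for (p in perms[[k]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS && nxt != c2) {
        blocked[k] <- TRUE
        break
      }
      if (translate_codon(cur) == translate_codon(nxt)) sy <- sy + 1
      else ns <- ns + 1
      cur <- nxt
    }
    if (!blocked[k]) tally[k, ] <- c(sy, ns)
  }
  use <- if (all(blocked)) {
    # degenerate: every path crosses a stop; average over all anyway
    for (k in seq_along(perms)) {
      cur <- c1
      sy <- ns <- 0
      for (p in perms[[k]]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        aa1 <- Biostrings::GENETIC_CODE[[cur]]
        aa2 <- Biostrings::GENETIC_CODE[[nxt]]
        if (identical(aa1, aa2)) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      tally[k, ] <- c(sy, ns)
    }
    rep(TRUE, length(perms))
  } else !blocked
  out <- c(syn = mean(tally[use, 1L]), nonsyn = mean(tally[use, 2L]))
  if (is.null(.polycap_env$paths)) .polycap_env$paths <- list()
  .polycap_env$paths[[key]] <- out
  out
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  if (p == 0) return(0)
  -0.75 * log(1 - 4 / 3 * p)
}

#' Ka and Ks by Nei-Gojobori style counting
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon from the
#' universal genetic code, averaged over both sequences; counts
#' synonymous (Sd) and nonsynonymous (Nd) differences by averaging over
#' all minimal mutational pathways between differing codons (pathways
#' through stop codons excluded); applies the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)` to both proportions.  Symmetric in its
#' two inputs.  Gapped codon columns (a `-` in either sequence) are
#' stripped before counting.
#'
#' @param cds_a,cds_b aligned CDS strings of equal length (multiple of 3
#'   after gap stripping, no internal stop codons)
#' @param label optional pair label carried through
#' @return object of class `cds_pair_divergence`: list with `S`, `N`,
#'   `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `Ka_Ks`, `saturated` (p >= 3/4,
#'   correction undefined), `codons`, `label`
#' @export
kaks_counting <- function(cds_a, cds_b, label = NA_character_) {
  stopifnot(length(cds_a) == 1L, length(cds_b) == 1L)
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("aligned sequences differ in length: ", nchar(cds_a), " vs ",
         nchar(cds_b))
  }
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  gapped <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  ca <- ca[!gapped]; cb <- cb[!gapped]
  if (!length(ca)) stop("no ungapped codons to compare")
  internal_a <- ca[-length(ca)] %in% STOP_CODONS
  internal_b <- cb[-length(cb)] %in% STOP_CODONS
  if (any(internal_a) || any(internal_b)) {
    stop("internal stop codon at codon ",
         which(internal_a | internal_b)[1])
  }
  # terminal stops carry no site information; drop if present in either
  if (ca[length(ca)] %in% STOP_CODONS || cb[length(cb)] %in% STOP_CODONS) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  Sa <- sum(vapply(ca, ng86_codon_syn_sites, numeric(1)))
  Sb <- sum(vapply(cb, ng86_codon_syn_sites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  cnt <- vapply(seq_along(ca), function(i) codon_path_counts(ca[i], cb[i]),
                numeric(2))
  Sd <- sum(cnt[1L, ]); Nd <- sum(cnt[2L, ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  structure(list(label = label, codons = length(ca),
                 S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka,
                 Ka_Ks = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks
                 else NA_real_,
                 saturated = pS >= 0.75 || pN >= 0.75),
            class = "cds_pair_divergence")
}

#' @export
print.cds_pair_divergence <- function(x, ...) {
  cat(sprintf(paste0("<cds_pair_divergence>%s %d codons | S=%.1f N=%.1f",
                     " Sd=%.2f Nd=%.2f | Ks=%.4g Ka=%.4g Ka/Ks=%.3g%s\n"),
              if (is.na(x$label)) "" else paste0(" ", x$label),
              x$codons, x$S, x$N, x$Sd, x$Nd, x$Ks, x$Ka,
              if (is.na(x$Ka_Ks)) NA else x$Ka_Ks,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Divergence time from Ks
#'
#' `T = Ks / (2 * rate)` years, with the default per-site per-year
#' synonymous substitution rate for the grass lineage, 6.9e-9 (so Ks =
#' 0.0138 dates to 1.0 million years).
#'
#' @param ks synonymous substitution rate per site (>= 0)
#' @param rate substitution rate per site per year (> 0)
#' @return divergence time in years (vectorized)
#' @export
divergence_time <- function(ks, rate = 6.9e-9) {
  stopifnot(all(ks >= 0, na.rm = TRUE), rate > 0)
  ks / (2 * rate)
}
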