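# cached nearest-neighbor table
.polycap_env <- new.env(parent = emptyenv())

nn_table <- function() {
  if (is.null(.polycap_env$nn)) {
    path <- system.file("extdata", "nn_rna_dna_hybrid.csv",
                        package = "polycap")
    tab <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    .polycap_env$nn <- tab
  }
  .polycap_env$nn
}

# ΔH (kcal/mol) and ΔS (cal/mol/K) of the probe/target hybrid duplex,
# probe sequence interpreted as the RNA strand (T -> U)
hybrid_dh_ds <- function(seq) {
  tab <- nn_table()
  dh <- stats::setNames(tab$dH_kcal, tab$step)
  ds <- stats::setNames(tab$dS_cal, tab$step)
  rna <- chartr("T", "U", seq)
  n <- nchar(rna)
  steps <- substring(rna, 1:(n - 1), 2:n)
  c(dH = dh[["init"]] + sum(dh[steps]),
    dS = ds[["init"]] + sum(ds[steps]))
}

#' Thermodynamic and sequence features of capture probes
#'
#' For each probe sequence computes: GC content (%); melting temperature
#' Tm (deg C) of the probe/target RNA/DNA hybrid by nearest-neighbor sums
#' at 1 M Na+ and strand concentration `ct`; PMFE (self-folding minimum
#' energy from a weighted pairing recursion, minimum loop 3, weights
#' GC -3 / AT -2 / GT -1; negative = stable); PHFE (probe hybridization
#' free energy: nearest-neighbor dG at `temperature` deg C); hairpin score
#' (longest self-complementary stem with loop >= 3); dimer score (maximum
#' contiguous complementary duplex between two antiparallel copies).
#'
#' @param seqs named character vector of probe sequences (ACGT, length >=
#'   20), or a `Biostrings::DNAStringSet`
#' @param read_counts optional numeric vector of uniquely mapped reads per
#'   probe (recycled into the result)
#' @param temperature hybridization temperature for PHFE in deg C
#'   (default 65)
#' @param ct total strand concentration (M) for Tm (default 1e-4)
#' @return data.frame: probe_id, length, gc, tm, pmfe, phfe, hairpin,
#'   dimer (+ reads when supplied)
#' @export
compute_features <- function(seqs, read_counts = NULL, temperature = 65,
                             ct = 1e-4) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs))) names(seqs) <- sprintf("probe%d", seq_along(seqs))
  n <- nchar(seqs)
  if (any(n < 20L)) stop("probe sequences must be >= 20 nt")
  for (i in seq_along(seqs)) check_acgt(seqs[i], names(seqs)[i])
  R_gas <- 1.987  # cal / (mol K)
  feats <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    gc <- 100 * (nchar(gsub("[^GC]", "", s))) / nchar(s)
    th <- hybrid_dh_ds(s)
    tm <- th[["dH"]] * 1000 / (th[["dS"]] + R_gas * log(ct / 4)) - 273.15
    phfe <- th[["dH"]] - (273.15 + temperature) * th[["dS"]] / 1000
    data.frame(probe_id = names(seqs)[i], length = nchar(s), gc = gc,
               tm = tm, pmfe = pmfe_dp_cpp(s), phfe = phfe,
               hairpin = hairpin_score_cpp(s), dimer = dimer_score_cpp(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  if (!is.null(read_counts)) {
    stopifnot(length(read_counts) == nrow(out), all(read_counts >= 0))
    out$reads <- read_counts
  }
  out
}

#' Select successful probes by read-count window
#'
#' Successful probes have uniquely mapped read counts strictly above 10%
#' of the mean count and strictly below the 99th percentile of the count
#' distribution (e.g. a mean of 260 reads/probe gives the classic lower
#' bound of 26).
#'
#' @param features data.frame with a `reads` column (see
#'   [compute_features()])
#' @param lower_fraction lower bound as a fraction of the mean (default
#'   0.10)
#' @param upper_percentile upper bound percentile (default 99)
#' @return the selected subset, with attributes `lower` and `upper`
#' @export
select_successful_probes <- function(features, lower_fraction = 0.10,
                                     upper_percentile = 99) {
  if (!nrow(features)) stop("empty probe table")
  if (is.null(features$reads)) stop("features table has no 'reads' column")
  lower <- lower_fraction * mean(features$reads)
  upper <- stats::quantile(features$reads, upper_percentile / 100,
                           names = FALSE, type = 7)
  keep <- features$reads > lower & features$reads < upper
  if (!any(keep)) {
    warning("no probes inside the (", signif(lower, 4), ", ",
            signif(upper, 4), ") read-count window")
  }
  out <- features[keep, , drop = FALSE]
  attr(out, "lower") <- lower
  attr(out, "upper") <- upper
  out
}

#' Prune highly correlated features
#'
#' Builds a graph over feature columns with edges where `|r| >
#' threshold`, and keeps one representative per connected component,
#' chosen by the documented priority order GC > Tm > PHFE > PMFE >
#' hairpin > dimer (unknown features follow, in column order).  Constant
#' features (undefined correlation) are excluded with a warning.
#'
#' @param features numeric data.frame/matrix of feature columns
#' @param threshold absolute correlation threshold (default 0.95)
#' @param priority character vector defining representative preference
#' @return list with `keep` (representative column names), `dropped`,
#'   `components` (list of character vectors), `cor` (the correlation
#'   matrix)
#' @export
prune_correlated <- function(features, threshold = 0.95,
                             priority = c("gc", "tm", "phfe", "pmfe",
                                          "hairpin", "dimer")) {
  x <- as.data.frame(features)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[num]
  if (ncol(x) < 2L) stop("need at least 2 numeric features")
  const <- vapply(x, function(col) {
    s <- stats::sd(col)
    !is.finite(s) || s == 0
  }, logical(1))
  if (any(const)) {
    warning("constant feature(s) excluded: ",
            paste(names(x)[const], collapse = ", "))
    x <- x[!const]
  }
  cm <- stats::cor(x)
  nm <- colnames(cm)
  adj <- abs(cm) > threshold
  diag(adj) <- FALSE
  # connected components by repeated expansion
  comp <- rep(NA_integer_, length(nm))
  cid <- 0L
  for (i in seq_along(nm)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cid
      nb <- which(apply(adj[frontier, , drop = FALSE], 2L, any) &
                    is.na(comp))
      frontier <- nb
    }
  }
  rank_of <- function(f) {
    r <- match(f, priority)
    ifelse(is.na(r), length(priority) + match(f, nm), r)
  }
  keep <- vapply(split(nm, comp), function(members) {
    members[which.min(rank_of(members))]
  }, character(1))
  list(keep = unname(keep), dropped = setdiff(nm, keep),
       components = unname(split(nm, comp)), cor = cm)
}
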