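#' Target-region coverage summary
#'
#' Target regions are the probe intervals extended by `flank` bp up- and
#' downstream, merged where overlapping.  For each target the median
#' per-base sequence depth (MSD) is computed from a per-base depth table;
#' positions absent from the table count as depth 0 (with a warning when a
#' whole target lies outside the table).  A cumulative curve reports the
#' fraction of targets with MSD at least each value of a depth grid.
#'
#' @param depth data.frame with columns `chrom`, `pos` (0-based) and
#'   `depth`
#' @param probes data.frame with `chrom`, `start`, `end` (0-based
#'   half-open)
#' @param flank bp added on both sides of each probe (default 100)
#' @param grid depth grid for the cumulative curve (default `seq(0, 200,
#'   by = 10)`)
#' @return list with `targets` (chrom, start, end, msd), `cumulative`
#'   (depth, fraction_at_least)
#' @export
coverage_summary <- function(depth, probes, flank = 100,
                             grid = seq(0, 200, by = 10)) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth)),
            all(c("chrom", "start", "end") %in% names(probes)))
  targets <- do.call(rbind, lapply(split(probes, probes$chrom), function(p) {
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(0L, p$start - flank) + 1L,  # IRanges is 1-based closed
      end = p$end + flank))
    data.frame(chrom = p$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }))
  rownames(targets) <- NULL
  dd <- data.table::as.data.table(depth)
  key <- paste(dd$chrom, dd$pos)
  lookup <- stats::setNames(dd$depth, key)
  warned <- FALSE
  msd <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    pos <- targets$start[i]:(targets$end[i] - 1L)
    d <- lookup[paste(targets$chrom[i], pos)]
    if (all(is.na(d)) && !warned) {
      warning("target(s) outside the depth table treated as zero depth")
      warned <- TRUE
    }
    d[is.na(d)] <- 0
    msd[i] <- stats::median(d)
  }
  targets$msd <- msd
  cumulative <- data.frame(
    depth = grid,
    fraction_at_least = vapply(grid, function(g) mean(msd >= g), numeric(1)))
  list(targets = targets, cumulative = cumulative)
}
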