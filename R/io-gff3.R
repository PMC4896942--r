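#' Genomic intervals and gene models
#'
#' Internally all coordinates are 0-based half-open (`start` inclusive,
#' `end` exclusive), converted once at each format boundary: GFF3 is
#' 1-based inclusive, VCF positions stay 1-based, BED is already 0-based
#' half-open.
#'
#' @param chrom sequence name (non-empty string)
#' @param start 0-based inclusive start
#' @param end 0-based exclusive end (`start < end`)
#' @param strand one of `"+"`, `"-"`, `"."`
#' @return a one-row `data.frame` with class `genomic_interval` columns
#'   `chrom`, `start`, `end`, `strand`
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == length(start),
            length(start) == length(end))
  if (any(start < 0L) || any(start >= end)) {
    stop("invalid interval: need 0 <= start < end")
  }
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  structure(data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(end), strand = strand,
                       stringsAsFactors = FALSE),
            class = c("genomic_interval", "data.frame"))
}

#' Construct a gene model
#'
#' A gene model is one transcript: ordered, non-overlapping exons, CDS
#' segments each contained in an exon, optional UTRs, and the phase of the
#' first CDS segment.  Total CDS length is conventionally a multiple of 3;
#' violations are flagged via the `cds_frame_ok` field, not fatal.
#'
#' @param gene_id gene identifier
#' @param chrom,start,end,strand gene span (0-based half-open)
#' @param exons,cds,utr5,utr3 data.frames with `start`,`end` columns
#' @param phase phase of the first CDS segment (0, 1 or 2)
#' @return an object of class `gene_model`
#' @export
gene_model <- function(gene_id, chrom, start, end, strand,
                       exons, cds = NULL, utr5 = NULL, utr3 = NULL,
                       phase = 0L) {
  empty <- data.frame(start = integer(), end = integer())
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  cds <- if (is.null(cds)) empty else cds[order(cds$start), , drop = FALSE]
  cds_len <- sum(cds$end - cds$start)
  structure(list(
    gene_id = gene_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand,
    exons = exons, cds = cds,
    utr5 = utr5 %||% empty, utr3 = utr3 %||% empty,
    phase = as.integer(phase),
    cds_frame_ok = (cds_len %% 3L == 0L)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d exon(s), CDS %d bp%s\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), sum(x$cds$end - x$cds$start),
              if (x$cds_frame_ok) "" else " [frame!]"))
  invisible(x)
}

parse_gff3_attrs <- function(attr, lineno) {
  if (attr == "." || attr == "") return(list())
  parts <- strsplit(attr, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(lengths(kv) < 2L)) {
    stop("malformed GFF3 attribute column at line ", lineno, ": ", attr)
  }
  stats::setNames(vapply(kv, function(p) paste(p[-1], collapse = "="),
                         character(1)),
                  vapply(kv, `[[`, character(1), 1L))
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 subset (gene / mRNA / exon / CDS / five_prime_UTR /
#' three_prime_UTR features; one transcript per gene) into a list of
#' [gene_model()] objects.  GFF3 1-based inclusive coordinates are
#' converted to internal 0-based half-open.  Validation problems that are
#' not fatal (CDS outside any exon, CDS length not a multiple of 3) are
#' collected in the `"report"` attribute of the result.
#'
#' @param path path to a GFF3 file
#' @return list of `gene_model`, with attribute `report` (character vector
#'   of validation warnings)
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  report <- character()
  if (!length(keep)) {
    return(structure(list(), report = report))
  }
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("malformed GFF3 record at line ", ln, ": expected 9 columns, got ",
           length(f))
    }
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || start1 < 1L || end1 < start1) {
      stop("out-of-range coordinates in GFF3 at line ", ln, ": ",
           f[4], "..", f[5])
    }
    attrs <- parse_gff3_attrs(f[9], ln)
    rows[[i]] <- list(chrom = f[1], type = f[3],
                      start = start1 - 1L, end = end1,  # to 0-based half-open
                      strand = f[7], phase = f[8],
                      id = if ("ID" %in% names(attrs)) attrs[["ID"]]
                        else NA_character_,
                      parent = if ("Parent" %in% names(attrs))
                        attrs[["Parent"]] else NA_character_)
  }
  feat <- data.table::rbindlist(rows)
  genes <- feat[feat$type == "gene", ]
  models <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gid <- genes$id[g]
    # children: direct (Parent=gene) or via one mRNA level
    mrna_ids <- feat$id[feat$type == "mRNA" & !is.na(feat$parent) &
                          feat$parent == gid]
    kids <- feat[!is.na(feat$parent) & feat$parent %in% c(gid, mrna_ids), ]
    seg <- function(ftype) {
      s <- as.data.frame(kids)
      s <- s[s$type == ftype, c("start", "end")]
      s[order(s$start), , drop = FALSE]
    }
    exons <- seg("exon")
    cds <- seg("CDS")
    if (nrow(exons) == 0L && nrow(cds) > 0L) exons <- cds
    if (nrow(exons) == 0L) {
      exons <- data.frame(start = genes$start[g], end = genes$end[g])
    }
    # CDS containment check
    for (k in seq_len(nrow(cds))) {
      inside <- any(exons$start <= cds$start[k] & cds$end[k] <= exons$end)
      if (!inside) {
        report <- c(report, sprintf("gene %s: CDS segment %d-%d outside exons",
                                    gid, cds$start[k], cds$end[k]))
      }
    }
    ph <- kids$phase[kids$type == "CDS"]
    ph <- if (length(ph) && ph[1] %in% c("0", "1", "2")) as.integer(ph[1]) else 0L
    m <- gene_model(gid, genes$chrom[g], genes$start[g], genes$end[g],
                    genes$strand[g], exons = exons, cds = cds,
                    utr5 = seg("five_prime_UTR"), utr3 = seg("three_prime_UTR"),
                    phase = ph)
    if (!m$cds_frame_ok) {
      report <- c(report, sprintf("gene %s: CDS length not a multiple of 3", gid))
    }
    models[[g]] <- m
  }
  names(models) <- genes$id
  structure(models, report = report)
}

#' Write gene models to GFF3
#'
#' @param models list of [gene_model()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    row <- function(type, start, end, id = NULL, parent = NULL, phase = ".") {
      attrs <- c(if (!is.null(id)) paste0("ID=", id),
                 if (!is.null(parent)) paste0("Parent=", parent))
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              m$chrom, "polycap", type, start + 1L, end, m$strand, phase,
              paste(attrs, collapse = ";"))
    }
    out <- row("gene", m$start, m$end, id = m$gene_id)
    mid <- paste0(m$gene_id, ".1")
    out <- c(out, row("mRNA", m$start, m$end, id = mid, parent = m$gene_id))
    for (i in seq_len(nrow(m$exons))) {
      out <- c(out, row("exon", m$exons$start[i], m$exons$end[i], parent = mid))
    }
    for (i in seq_len(nrow(m$cds))) {
      out <- c(out, row("CDS", m$cds$start[i], m$cds$end[i], parent = mid,
                        phase = if (i == 1L) as.character(m$phase) else "."))
    }
    for (i in seq_len(nrow(m$utr5))) {
      out <- c(out, row("five_prime_UTR", m$utr5$start[i], m$utr5$end[i],
                        parent = mid))
    }
    for (i in seq_len(nrow(m$utr3))) {
      out <- c(out, row("three_prime_UTR", m$utr3$start[i], m$utr3$end[i],
                        parent = mid))
    }
    writeLines(out, con)
  }
  invisible(path)
}
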