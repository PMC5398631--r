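#' Segmented copy-number I/O
#'
#' Profiles are exchanged on disk in SEG format (tab-separated with a
#' header: Sample, Chromosome, Start, End, Num_Probes, Segment_Mean),
#' where Segment_Mean is a log2 ratio with diploid = 0 and coordinates
#' are 1-based inclusive. In memory the package works on one long data
#' frame per cohort with columns `sample`, `chrom`, `start`, `end`,
#' `n_markers`, `value`, where `value` is on the linear copy scale
#' (diploid = 2.0) and coordinates are 0-based half-open. The conversion
#' `value = 2 * 2^seg_mean` happens only at this boundary, because the
#' admixture model and all calling thresholds are linear in copies.
#'
#' @name seg-io
NULL

#' Read a SEG file into a cohort segment table
#'
#' @param path SEG file path.
#' @return data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `n_markers`, `value` (linear copies, diploid = 2), sorted by sample
#'   and position; segments per sample/chromosome are checked to be
#'   non-overlapping.
#' @export
read_seg <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 6L)
    stop_fmt("SEG format error: expected 6 columns, found %d in %s", ncol(raw), path)
  raw <- raw[, 1:6]
  names(raw) <- c("sample", "chrom", "start", "end", "n_markers", "seg_mean")
  num <- suppressWarnings(as.numeric(raw$seg_mean))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1L]
    stop_fmt("SEG parse error: non-numeric Segment_Mean %s at line %d",
             raw$seg_mean[bad], bad + 1L)
  }
  segs <- data.frame(
    sample = raw$sample,
    chrom = norm_chrom(raw$chrom),
    start = as.numeric(raw$start) - 1,   # disk 1-based inclusive -> 0-based half-open
    end = as.numeric(raw$end),
    n_markers = as.integer(raw$n_markers),
    value = 2 * 2^num,
    stringsAsFactors = FALSE
  )
  validate_segments(segs)
}

validate_segments <- function(segs) {
  if (any(segs$start >= segs$end)) stop_fmt("segment format error: start must be < end")
  if (any(segs$n_markers < 1L)) stop_fmt("segment format error: n_markers must be >= 1")
  if (any(segs$value < 0)) stop_fmt("segment format error: negative copy value")
  segs <- segs[order(segs$sample, suppressWarnings(as.numeric(segs$chrom)),
                     segs$chrom, segs$start), , drop = FALSE]
  key <- paste(segs$sample, segs$chrom)
  same <- key[-1] == key[-length(key)]
  olap <- same & segs$start[-1] < segs$end[-nrow(segs)]
  if (any(olap)) {
    i <- which(olap)[1L] + 1L
    stop_fmt("segment format error: overlapping segments for sample %s on chromosome %s",
             segs$sample[i], segs$chrom[i])
  }
  rownames(segs) <- NULL
  segs
}

#' Write a cohort segment table as a SEG file
#'
#' Inverse of [read_seg()]: linear copy values become log2 ratios
#' (`seg_mean = log2(value / 2)`, with values floored at 1e-6 copies so
#' homozygous deletions remain representable) and coordinates revert to
#' 1-based inclusive. Numbers are printed at full double precision so the
#' read/write round trip is lossless and byte-deterministic.
#'
#' @param segs segment data frame (see [read_seg()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segs, path) {
  v <- pmax(segs$value, 1e-6)
  lines <- sprintf("%s\t%s\t%.0f\t%.0f\t%d\t%.17g",
                   segs$sample, segs$chrom, segs$start + 1, segs$end,
                   segs$n_markers, log2(v / 2))
  writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean", lines), path)
  invisible(path)
}

#' Read a germline genotype matrix
#'
#' @param path TSV with one row per SNP: first column SNP id, remaining
#'   columns per-sample allele dosages in {0, 1, 2, NA}.
#' @return integer matrix (SNPs x samples, dimnames set) with NA for
#'   missing entries; attribute `monomorphic` flags SNPs with zero
#'   variance across non-missing entries (retained, not dropped).
#' @export
read_genotypes <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = character(0))
  if (ncol(raw) < 2L) stop_fmt("genotype format error: no sample columns in %s", path)
  ids <- raw[[1L]]
  g <- as.matrix(raw[, -1L, drop = FALSE])
  is_na <- g == "NA" | g == ""
  ok <- is_na | g %in% c("0", "1", "2")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_fmt("genotype parse error: entry '%s' (SNP %s, sample %s) not in {0,1,2,NA}",
             g[bad[1L], bad[2L]], ids[bad[1L]], colnames(g)[bad[2L]])
  }
  G <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = list(ids, colnames(g)))
  G[!is_na] <- as.integer(g[!is_na])
  mono <- apply(G, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) == 0L || all(r == r[1L])
  })
  attr(G, "monomorphic") <- unname(mono)
  G
}

#' Write a genotype matrix
#' @param G integer matrix (SNPs x samples) with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  body <- apply(G, 1L, function(r) paste(ifelse(is.na(r), "NA", r), collapse = "\t"))
  writeLines(c(paste(c("snp", colnames(G)), collapse = "\t"),
               paste(rownames(G), body, sep = "\t")), path)
  invisible(path)
}

#' Read / write the per-sample purity-ploidy table
#'
#' Columns: `sample_id`, `alpha` (tumor purity in (0,1]), `tau` (tumor
#' ploidy > 0), `confident` (logical; FALSE marks samples excluded from
#' purity-corrected analyses).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_purity_table <- function(path) {
  pp <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "alpha", "tau", "confident") %in% names(pp)))
  pp$confident <- as.logical(pp$confident)
  if (any(!is.na(pp$alpha) & (pp$alpha <= 0 | pp$alpha > 1)))
    stop_fmt("purity table error: alpha must lie in (0, 1]")
  if (any(!is.na(pp$tau) & pp$tau <= 0))
    stop_fmt("purity table error: tau must be positive")
  pp
}

#' @rdname read_purity_table
#' @param pp purity-ploidy data frame.
#' @export
write_purity_table <- function(pp, path) {
  lines <- sprintf("%s\t%.17g\t%.17g\t%s", pp$sample_id, pp$alpha, pp$tau,
                   ifelse(pp$confident, "TRUE", "FALSE"))
  writeLines(c("sample_id\talpha\ttau\tconfident", lines), path)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Columns: `sample_id`, `cohort_label` in {EAST, WEST, UNCLASSIFIED,
#' UNKNOWN}, `subtype_label` in {CIN, NON_CIN, UNKNOWN}; further columns
#' are carried through as covariates.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "cohort_label", "subtype_label") %in% names(md)))
  if (!all(md$cohort_label %in% c("EAST", "WEST", "UNCLASSIFIED", "UNKNOWN")))
    stop_fmt("metadata error: cohort_label outside {EAST, WEST, UNCLASSIFIED, UNKNOWN}")
  if (!all(md$subtype_label %in% c("CIN", "NON_CIN", "UNKNOWN")))
    stop_fmt("metadata error: subtype_label outside {CIN, NON_CIN, UNKNOWN}")
  md
}

#' @rdname read_metadata
#' @param md metadata data frame.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a cohort-comparison results table
#'
#' Columns: `event_id`, `rate_east`, `rate_west`, `statistic` (rate
#' difference West - East), `p_perm`, `q_bh` (NA for unpowered events),
#' `powered`. Rows are sorted by q then p; floats are written at full
#' precision so the round trip is lossless.
#'
#' @param results results data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  req <- c("event_id", "rate_east", "rate_west", "statistic", "p_perm", "q_bh", "powered")
  stopifnot(all(req %in% names(results)))
  if (nrow(results) == 0L) {
    warn_fmt("write_results_table: empty results, writing header only")
    writeLines(paste(req, collapse = "\t"), path)
    return(invisible(path))
  }
  results <- results[order(results$q_bh, results$p_perm, results$event_id,
                           na.last = TRUE), req, drop = FALSE]
  fg <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
                   results$event_id, fg(results$rate_east), fg(results$rate_west),
                   fg(results$statistic), fg(results$p_perm), fg(results$q_bh),
                   ifelse(results$powered, "TRUE", "FALSE"))
  writeLines(c(paste(req, collapse = "\t"), lines), path)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric", "numeric", "numeric",
                                   "numeric", "numeric", "logical"))
}

#' Read a gene annotation BED file
#'
#' @param path BED path (0-based half-open; columns chrom, start, end,
#'   name; extra columns ignored).
#' @return data frame with columns `chrom`, `start`, `end`, `name`,
#'   sorted by position.
#' @export
read_gene_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 4L) stop_fmt("BED format error: need at least 4 columns in %s", path)
  b <- b[, 1:4]
  names(b) <- c("chrom", "start", "end", "name")
  b$chrom <- norm_chrom(b$chrom)
  b <- b[order(b$chrom, b$start, b$end), ]
  rownames(b) <- NULL
  b
}

#' Read / write focal-region BED files
#'
#' Regions carry a name, a type (AMP or DEL) and optionally a q-value and
#' associated genes in extra columns.
#'
#' @param path BED path.
#' @return data frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `type`, and where present `qvalue` and `genes`.
#' @export
read_regions_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 5L) stop_fmt("region BED error: need columns chrom,start,end,name,type")
  out <- data.frame(region_id = b[[4]], chrom = norm_chrom(b[[1]]),
                    start = as.numeric(b[[2]]), end = as.numeric(b[[3]]),
                    type = toupper(b[[5]]), stringsAsFactors = FALSE)
  if (!all(out$type %in% c("AMP", "DEL")))
    stop_fmt("region BED error: type must be AMP or DEL")
  if (ncol(b) >= 6L) out$qvalue <- suppressWarnings(as.numeric(b[[6]]))
  if (ncol(b) >= 7L) out$genes <- as.character(b[[7]])
  out
}

#' @rdname read_regions_bed
#' @param regions region data frame.
#' @export
write_regions_bed <- function(regions, path) {
  q <- if ("qvalue" %in% names(regions)) sprintf("%.17g", regions$qvalue) else "NA"
  g <- if ("genes" %in% names(regions)) regions$genes else "."
  lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%s\t%s\t%s", regions$chrom, regions$start,
                   regions$end, regions$region_id, regions$type, q, g)
  writeLines(lines, path)
  invisible(path)
}
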