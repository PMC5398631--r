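#' Chromosome-arm definitions
#'
#' Arm tables are plain data frames with columns `arm` (e.g. "8q"),
#' `chrom`, `start`, `end`. Coordinates are 0-based half-open in memory,
#' matching BED; SEG and cytoBand conventions are converted at the I/O
#' boundary. The default autosomal analysis universe has 39 arms: 22
#' autosomes x 2 arms minus the five acrocentric short arms (13p, 14p,
#' 15p, 21p, 22p) that carry no unique sequence on SNP arrays.
#'
#' @name arm-definitions
NULL

ACROCENTRIC_P <- c("13p", "14p", "15p", "21p", "22p")

#' Read chromosome arms from a UCSC cytoBand file
#'
#' Aggregates cytogenetic bands to arms by the p/q prefix of the band
#' name: each arm spans from its first band start to its last band end.
#'
#' @param path cytoBand.txt-style file (tab-separated, no header, columns
#'   chrom, start, end, band, stain; 0-based half-open).
#' @param drop_acrocentric drop the acrocentric short arms 13p, 14p, 15p,
#'   21p, 22p from the result (default TRUE).
#' @return data frame with columns `arm`, `chrom`, `start`, `end`.
#' @export
read_arm_definitions <- function(path, drop_acrocentric = TRUE) {
  bands <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "band", "stain"),
                             fill = TRUE)
  bands$chrom <- norm_chrom(bands$chrom)
  letter <- substr(bands$band, 1L, 1L)
  if (!all(letter %in% c("p", "q")))
    stop_fmt("cytoBand format error: band names must start with p or q")
  for (ch in unique(bands$chrom)) {
    if (!any(letter[bands$chrom == ch] == "q"))
      stop_fmt("cytoBand format error: chromosome %s has no q bands", ch)
  }
  key <- paste0(bands$chrom, letter)
  arms <- data.frame(
    arm   = unique(key),
    stringsAsFactors = FALSE
  )
  arms$chrom <- bands$chrom[match(arms$arm, key)]
  arms$start <- as.numeric(tapply(bands$start, key, min)[arms$arm])
  arms$end   <- as.numeric(tapply(bands$end,   key, max)[arms$arm])
  if (drop_acrocentric) arms <- arms[!(arms$arm %in% ACROCENTRIC_P), ]
  arms <- arms[order(suppressWarnings(as.numeric(arms$chrom)), arms$chrom, arms$start), ]
  rownames(arms) <- NULL
  validate_arms(arms)
  arms
}

validate_arms <- function(arms) {
  stopifnot(all(c("arm", "chrom", "start", "end") %in% names(arms)))
  if (any(arms$start >= arms$end)) stop_fmt("arm definitions: start must be < end")
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)]))
      stop_fmt("arm definitions: overlapping arms on chromosome %s", ch)
  }
  invisible(arms)
}

#' Synthetic genome arm definitions
#'
#' A self-contained synthetic autosomal genome for simulation and testing:
#' 22 chromosomes with linearly decreasing lengths (about 3 Gb total), a
#' centromere at 40% of each chromosome, and acrocentric short arms
#' (no p arm) for chromosomes 13, 14, 15, 21 and 22 - giving the standard
#' 39-arm autosomal universe. It is not a real genome build; all
#' coordinates are synthetic.
#'
#' @param n_chrom number of autosomes (default 22).
#' @param total_length total genome length in bp (default 3e9).
#' @param centromere_frac centromere position as a fraction of chromosome
#'   length (default 0.4).
#' @return arm data frame (see [read_arm_definitions()]).
#' @export
synthetic_arm_definitions <- function(n_chrom = 22L, total_length = 3e9,
                                      centromere_frac = 0.4) {
  rel <- seq(2.5, 0.8, length.out = n_chrom)
  len <- round(rel / sum(rel) * total_length)
  acro <- intersect(c(13L, 14L, 15L, 21L, 22L), seq_len(n_chrom))
  rows <- list()
  for (i in seq_len(n_chrom)) {
    cen <- round(len[i] * centromere_frac)
    if (!(i %in% acro))
      rows[[length(rows) + 1L]] <- data.frame(
        arm = paste0(i, "p"), chrom = as.character(i),
        start = 0, end = cen, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      arm = paste0(i, "q"), chrom = as.character(i),
      start = cen, end = len[i], stringsAsFactors = FALSE)
  }
  arms <- do.call(rbind, rows)
  rownames(arms) <- NULL
  arms
}

#' Restrict an arm table to autosomes
#'
#' @param arms arm data frame.
#' @return arm data frame without sex chromosomes.
#' @export
autosomal_arms <- function(arms) {
  arms[!(toupper(arms$chrom) %in% c("X", "Y")), , drop = FALSE]
}

#' Lay a fixed pseudo-marker grid over the genome
#'
#' Markers are spread over arms proportionally to arm length, evenly
#' spaced within each arm (at least one marker per arm). The grid is the
#' shared coordinate system for G-score recurrence scans and for deriving
#' per-segment marker counts in simulation.
#'
#' @param arms arm data frame.
#' @param n_markers approximate total marker count (default 10000).
#' @return data frame with columns `idx`, `chrom`, `arm`, `pos`, plus a
#'   `step` attribute (mean inter-marker spacing in bp).
#' @export
marker_grid <- function(arms, n_markers = 10000L) {
  stopifnot(n_markers >= nrow(arms))
  total <- sum(arms$end - arms$start)
  out <- vector("list", nrow(arms))
  for (i in seq_len(nrow(arms))) {
    len <- arms$end[i] - arms$start[i]
    k <- max(1L, round(n_markers * len / total))
    pos <- arms$start[i] + (seq_len(k) - 0.5) * len / k
    out[[i]] <- data.frame(chrom = arms$chrom[i], arm = arms$arm[i], pos = pos,
                           stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, out)
  g <- data.frame(idx = seq_len(nrow(g)), g, stringsAsFactors = FALSE)
  attr(g, "step") <- total / nrow(g)
  g
}

#' Split segments at chromosome-arm boundaries
#'
#' Intersects a cohort segment table with an arm table so every returned
#' segment lies within exactly one arm (an `arm` column is added).
#' Segments outside the arm universe (e.g. sex chromosomes when `arms` is
#' autosomal) are dropped.
#'
#' @param segs segment data frame (columns sample, chrom, start, end,
#'   n_markers, value; 0-based half-open).
#' @param arms arm data frame.
#' @return segment data frame with an added `arm` column.
#' @export
split_segments_at_arms <- function(segs, arms) {
  pieces <- vector("list", nrow(arms))
  for (i in seq_len(nrow(arms))) {
    s <- segs[segs$chrom == arms$chrom[i] &
                segs$start < arms$end[i] & segs$end > arms$start[i], , drop = FALSE]
    if (nrow(s) == 0L) next
    frac_len <- pmin(s$end, arms$end[i]) - pmax(s$start, arms$start[i])
    nm <- pmax(1L, as.integer(round(s$n_markers * frac_len / (s$end - s$start))))
    s$start <- pmax(s$start, arms$start[i])
    s$end <- pmin(s$end, arms$end[i])
    s$n_markers <- nm
    s$arm <- arms$arm[i]
    pieces[[i]] <- s
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- segs[0, , drop = FALSE]
    out$arm <- character(0)
  }
  out <- out[order(out$sample, suppressWarnings(as.numeric(out$chrom)),
                   out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
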