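#' Marker-level recurrence G-scores
#'
#' For one direction (AMP or DEL) the G-score of a grid marker is the sum
#' over samples of the marker's above-noise amplitude,
#' `max(0, d * (value - arm_median) - noise_floor)` with d = +1 for
#' AMP and -1 for DEL and a 0.1-copy noise floor, restricted to segments
#' of FOCAL scope. The deviation is measured against the segment's own
#' arm median - the local background - so a focal event nested inside an
#' arm-level alteration keeps its amplitude; arm-level alterations
#' themselves contribute nothing: this is a scan for recurrent focal
#' events.
#'
#' @param segs (corrected) cohort segment table.
#' @param arms arm data frame.
#' @param grid marker grid from [marker_grid()] (shared by all samples).
#' @param direction "AMP" or "DEL".
#' @param noise_floor amplitude floor in copy units (default 0.1).
#' @param focal_cutoff arm-fraction focal cutoff (default 0.5).
#' @param merge_tol value tolerance for merging adjacent segments when
#'   judging scope (default 0.3).
#' @return object of class `gscore`: list with `scores` (per-marker
#'   numeric), `contrib` (per-sample sparse contributions, for the
#'   permutation null), `grid`, `direction`.
#' @export
gscore_profiles <- function(segs, arms, grid, direction = c("AMP", "DEL"),
                            noise_floor = 0.1, focal_cutoff = 0.5,
                            merge_tol = 0.3) {
  direction <- match.arg(direction)
  if (length(unique(segs$sample)) == 0L) stop_fmt("gscore_profiles: empty cohort")
  d <- if (direction == "AMP") 1 else -1
  sp <- arm_split_with_scope(segs, arms, focal_cutoff, merge_tol)
  scope <- sp$scope
  amp <- pmax(0, d * sp$dev_arm - noise_floor)
  keep <- which(scope == "FOCAL" & amp > 0)
  m <- nrow(grid)
  scores <- numeric(m)
  contrib <- list()
  for (i in keep) {
    idx <- which(grid$chrom == sp$chrom[i] & grid$pos >= sp$start[i] &
                   grid$pos < sp$end[i])
    if (length(idx) == 0L) next
    s <- sp$sample[i]
    cs <- contrib[[s]]
    contrib[[s]] <- list(idx = c(cs$idx, idx),
                         val = c(cs$val, rep(amp[i], length(idx))))
    scores[idx] <- scores[idx] + amp[i]
  }
  structure(list(scores = scores, contrib = contrib, grid = grid,
                 direction = direction, n_samples = length(unique(segs$sample))),
            class = "gscore")
}

#' Permutation significance of G-scores
#'
#' The null preserves each sample's focal event burden and amplitude
#' spectrum while destroying positional recurrence: every sample's
#' marker-level contribution vector is cyclically shifted along the
#' genome by an independent uniform offset, and shifted contributions are
#' re-summed. Marker p-values are empirical against the null score
#' distribution pooled across all markers and permutations,
#' `p(m) = (1 + #{null >= score(m)}) / (1 + n_perm * n_markers)`
#' (pooling across positions is what gives the scan resolution below
#' 1/n_perm, as permutation-based recurrence scans require), followed by
#' Benjamini-Hochberg correction across markers.
#'
#' @param gs `gscore` object from [gscore_profiles()].
#' @param n_perm number of cyclic-shift permutations (default 1000,
#'   minimum 100).
#' @param seed integer seed.
#' @return numeric vector of per-marker q-values; attributes `pvalues`
#'   and `n_perm`.
#' @export
significance_by_permutation <- function(gs, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(gs, "gscore"), n_perm >= 100L)
  m <- length(gs$scores)
  if (m < 2L) stop_fmt("significance_by_permutation: grid shorter than 2 markers")
  set.seed(derive_seed(seed, 0L))
  nz_null <- vector("list", n_perm)
  n_contrib <- length(gs$contrib)
  if (n_contrib > 0L) {
    idx0 <- unlist(lapply(gs$contrib, `[[`, "idx"), use.names = FALSE)
    vals <- unlist(lapply(gs$contrib, `[[`, "val"), use.names = FALSE)
    lens <- vapply(gs$contrib, function(c) length(c$idx), integer(1))
    for (b in seq_len(n_perm)) {
      off <- sample.int(m, n_contrib, replace = TRUE) - 1L
      shifted <- (idx0 - 1L + rep(off, lens)) %% m + 1L
      nz <- rowsum(vals, shifted)
      nz_null[[b]] <- as.numeric(nz)
    }
  }
  null_nz <- sort(unlist(nz_null, use.names = FALSE))
  n_null <- as.numeric(n_perm) * m
  n_zero <- n_null - length(null_nz)
  # count of null values >= s, for each observed marker score s
  ge <- length(null_nz) - findInterval(gs$scores - 1e-12, null_nz)
  ge[gs$scores <= 1e-12] <- ge[gs$scores <= 1e-12] + n_zero
  p <- (1 + ge) / (1 + n_null)
  q <- stats::p.adjust(p, method = "BH")
  attr(q, "pvalues") <- p
  attr(q, "n_perm") <- n_perm
  q
}

#' Extract significant regions from marker q-values
#'
#' Maximal runs of contiguous markers (within one chromosome arm) with
#' q < alpha become candidate regions; the reported interval is the
#' run's minimum-q sub-segment, with tied minimal markers merged (the
#' analogue of peak sub-region reporting in recurrence scans). The full
#' run is retained in `run_start` / `run_end`.
#'
#' @param qvalues per-marker q-values (from
#'   [significance_by_permutation()]).
#' @param grid marker grid.
#' @param type region type to stamp, "AMP" or "DEL".
#' @param alpha significance threshold (default 0.05).
#' @return region data frame (`region_id`, `chrom`, `start`, `end`,
#'   `type`, `qvalue`, `run_start`, `run_end`); zero rows when nothing is
#'   significant.
#' @export
extract_regions <- function(qvalues, grid, type = c("AMP", "DEL"), alpha = 0.05) {
  type <- match.arg(type)
  sig <- qvalues < alpha
  step <- attr(grid, "step") %||% stats::median(diff(grid$pos))
  runs <- list()
  run_block <- paste(grid$arm, cumsum(!sig))
  for (blk in split(which(sig), run_block[sig])) {
    if (length(blk) == 0L) next
    runs[[length(runs) + 1L]] <- blk
  }
  if (length(runs) == 0L)
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), type = character(0),
                      qvalue = numeric(0), run_start = numeric(0),
                      run_end = numeric(0), stringsAsFactors = FALSE))
  runs <- runs[order(vapply(runs, min, integer(1)))]
  out <- lapply(seq_along(runs), function(k) {
    ii <- runs[[k]]
    qmin <- min(qvalues[ii])
    peak <- ii[qvalues[ii] <= qmin + 1e-15]
    data.frame(
      region_id = sprintf("%s_%s_%d", tolower(type), grid$arm[ii[1L]], k),
      chrom = grid$chrom[ii[1L]],
      start = min(grid$pos[peak]) - step / 2,
      end = max(grid$pos[peak]) + step / 2,
      type = type, qvalue = qmin,
      run_start = min(grid$pos[ii]) - step / 2,
      run_end = max(grid$pos[ii]) + step / 2,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Associate genes with a peak region
#'
#' All genes whose footprint overlaps the region by at least 1 bp; if
#' none overlaps, the single nearest gene by bp distance on the same
#' chromosome (a tie returns both, flagged ambiguous).
#'
#' @param region one region (list/row with `chrom`, `start`, `end`).
#' @param genes gene table from [read_gene_bed()].
#' @return character vector of gene names; attribute `ambiguous` TRUE
#'   when a nearest-gene tie occurred.
#' @export
associate_genes <- function(region, genes) {
  if (nrow(genes) == 0L) {
    warn_fmt("associate_genes: empty gene annotation")
    return(character(0))
  }
  g <- genes[genes$chrom == region$chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  olap <- g$start < region$end & g$end > region$start
  if (any(olap)) return(structure(g$name[olap], ambiguous = FALSE))
  dist <- pmax(g$start - region$end, region$start - g$end, 0)
  nearest <- which(dist == min(dist))
  structure(g$name[nearest], ambiguous = length(nearest) > 1L)
}

#' Full recurrence scan (both directions)
#'
#' Convenience wrapper: G-scores, permutation q-values and region
#' extraction for AMP and DEL, with optional gene association.
#'
#' @inheritParams gscore_profiles
#' @inheritParams significance_by_permutation
#' @param alpha FDR threshold (default 0.05).
#' @param genes optional gene table for [associate_genes()].
#' @return region data frame for both directions (possibly zero rows),
#'   with a `genes` column when annotation was supplied.
#' @export
detect_recurrent_regions <- function(segs, arms, grid, n_perm = 1000L, seed = 1L,
                                     alpha = 0.05, noise_floor = 0.1,
                                     focal_cutoff = 0.5, genes = NULL) {
  out <- lapply(c("AMP", "DEL"), function(dir) {
    gs <- gscore_profiles(segs, arms, grid, dir, noise_floor, focal_cutoff)
    q <- significance_by_permutation(gs, n_perm,
                                     seed = derive_seed(seed, match(dir, c("AMP", "DEL"))))
    extract_regions(q, grid, dir, alpha)
  })
  regions <- do.call(rbind, out)
  if (!is.null(genes) && nrow(regions) > 0L)
    regions$genes <- vapply(seq_len(nrow(regions)), function(i)
      paste(associate_genes(regions[i, ], genes), collapse = ","), character(1))
  rownames(regions) <- NULL
  regions
}
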