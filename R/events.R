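#' Focal versus arm-level scope of a segment
#'
#' A segment (already split at arm boundaries) is ARM_LEVEL when it
#' covers at least `focal_cutoff` of its chromosome arm's length (default
#' 0.5, ties resolve to ARM_LEVEL), otherwise FOCAL. This length-fraction
#' rule is a deliberate simplification of iterative amplitude
#' deconstruction approaches: nested same-sign focal-on-arm events may be
#' under-counted.
#'
#' @param seg_length segment length(s) in bp.
#' @param arm_length matching arm length(s) in bp.
#' @param focal_cutoff fraction of the arm (default 0.5).
#' @return character vector, "FOCAL" or "ARM_LEVEL".
#' @export
classify_segment_scope <- function(seg_length, arm_length, focal_cutoff = 0.5) {
  if (any(seg_length > arm_length + 1e-9))
    stop_fmt("classify_segment_scope: segment longer than its arm (not split at arm boundaries?)")
  ifelse(seg_length >= focal_cutoff * arm_length, "ARM_LEVEL", "FOCAL")
}

# Effective scope length per arm-split segment row: the extent of the
# alteration the segment belongs to, not of the segment itself. For a
# segment deviating upward from the sample median, adjacent same-arm
# segments are absorbed while their value stays >= (value - merge_tol)
# (downward deviations mirror this with <= value + merge_tol). This
# one-level deconstruction keeps arm-level scope for the flanking pieces
# of a broad event that was split by a nested focal event, instead of
# the flanks masquerading as focal.
scope_lengths <- function(sp, dev, merge_tol = 0.3) {
  run_len <- sp$end - sp$start
  for (ii in split(seq_len(nrow(sp)), paste(sp$sample, sp$arm))) {
    ii <- ii[order(sp$start[ii])]
    v <- sp$value[ii]
    len <- sp$end[ii] - sp$start[ii]
    n <- length(ii)
    for (j in seq_len(n)) {
      inc <- if (dev[ii[j]] >= 0) v >= v[j] - merge_tol else v <= v[j] + merge_tol
      lo <- j; hi <- j
      while (lo > 1L && inc[lo - 1L]) lo <- lo - 1L
      while (hi < n && inc[hi + 1L]) hi <- hi + 1L
      run_len[ii[j]] <- sum(len[lo:hi])
    }
  }
  run_len
}

# Shared helper: split at arms, compute per-sample medians and deviation,
# classify scope on directional merged extents. dev is the deviation from
# the sample median (used for arm-level calling); dev_arm is the deviation
# from the segment's own arm median, the local background against which
# focal events are measured - a focal deletion nested inside a gained arm
# deviates from its arm, not necessarily from the genome-wide median.
arm_split_with_scope <- function(segs, arms, focal_cutoff = 0.5, merge_tol = 0.3) {
  sp <- split_segments_at_arms(segs, arms)
  med <- vapply(split(seq_len(nrow(sp)), sp$sample),
                function(ii) weighted_median(sp$value[ii], sp$end[ii] - sp$start[ii]),
                numeric(1))
  sp$dev <- sp$value - med[sp$sample]
  arm_med <- numeric(nrow(sp))
  for (ii in split(seq_len(nrow(sp)), paste(sp$sample, sp$arm)))
    arm_med[ii] <- weighted_median(sp$value[ii], sp$end[ii] - sp$start[ii])
  sp$dev_arm <- sp$value - arm_med
  arm_len <- stats::setNames(arms$end - arms$start, arms$arm)
  sp$scope <- classify_segment_scope(scope_lengths(sp, sp$dev_arm, merge_tol),
                                     arm_len[sp$arm], focal_cutoff)
  sp
}

#' Call per-arm gain/loss events
#'
#' For each sample and arm, the length-weighted median copy level of the
#' segments on the arm is compared to the sample's overall
#' length-weighted median: GAIN if above by strictly more than
#' `threshold` copies, LOSS if below, else NEUTRAL. Arms with no covering
#' segments are NEUTRAL (with a warning).
#'
#' @param segs (corrected) cohort segment table.
#' @param arms arm data frame.
#' @param threshold copy-unit threshold (default 0.2, strict).
#' @return data frame with columns `sample_id`, `arm`, `call`,
#'   `arm_median`, `sample_median`.
#' @export
call_arm_events <- function(segs, arms, threshold = 0.2) {
  sp <- split_segments_at_arms(segs, arms)
  samples <- unique(segs$sample)
  out <- vector("list", length(samples))
  uncovered <- 0L
  for (k in seq_along(samples)) {
    ii <- which(sp$sample == samples[k])
    w <- sp$end[ii] - sp$start[ii]
    med <- weighted_median(sp$value[ii], w)
    armmed <- rep(NA_real_, nrow(arms))
    for (j in seq_len(nrow(arms))) {
      jj <- ii[sp$arm[ii] == arms$arm[j]]
      if (length(jj) == 0L) { uncovered <- uncovered + 1L; next }
      armmed[j] <- weighted_median(sp$value[jj], sp$end[jj] - sp$start[jj])
    }
    call <- rep("NEUTRAL", nrow(arms))
    call[!is.na(armmed) & armmed - med > threshold + 1e-9] <- "GAIN"
    call[!is.na(armmed) & med - armmed > threshold + 1e-9] <- "LOSS"
    out[[k]] <- data.frame(sample_id = samples[k], arm = arms$arm, call = call,
                           arm_median = armmed, sample_median = med,
                           stringsAsFactors = FALSE)
  }
  if (uncovered > 0L)
    warn_fmt("call_arm_events: %d sample-arm pairs had no covering segments (NEUTRAL)", uncovered)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the boolean sample-by-event matrix
#'
#' Events are per-arm gains and losses (`"8q:gain"`, `"17p:loss"`, ...)
#' plus focal amplifications/deletions within supplied regions
#' (`"<region_id>:amp"` / `":del"`). A sample carries a focal event at a
#' region when some FOCAL-scope segment deviating from its own arm's
#' median copy level by more than `call_threshold` in the matching
#' direction (up for AMP regions, down for DEL) overlaps the region by at
#' least 1 bp; the arm median is the local background, so focal events
#' nested inside arm-level alterations are still seen. Per-sample focal
#' event counts (row sums over focal columns) are attached.
#'
#' @param segs (corrected) cohort segment table.
#' @param arms arm data frame.
#' @param regions focal region data frame (`region_id`, `chrom`, `start`,
#'   `end`, `type` AMP/DEL), or NULL for arm events only.
#' @param call_threshold copy-unit SCNA call threshold (default 0.2).
#' @param focal_cutoff arm-fraction focal cutoff (default 0.5).
#' @param merge_tol value tolerance for merging adjacent segments when
#'   judging scope (default 0.3).
#' @return object of class `event_matrix`: list with `matrix` (logical,
#'   samples x events), `events` (data frame describing columns),
#'   `focal_count` (named integer vector).
#' @export
build_event_matrix <- function(segs, arms, regions = NULL,
                               call_threshold = 0.2, focal_cutoff = 0.5,
                               merge_tol = 0.3) {
  samples <- unique(segs$sample)
  arm_calls <- call_arm_events(segs, arms, call_threshold)
  arm_events <- data.frame(
    event_id = c(paste0(arms$arm, ":gain"), paste0(arms$arm, ":loss")),
    kind = "arm",
    stringsAsFactors = FALSE
  )
  M_arm <- matrix(FALSE, length(samples), nrow(arm_events),
                  dimnames = list(samples, arm_events$event_id))
  gi <- arm_calls$call == "GAIN"
  li <- arm_calls$call == "LOSS"
  M_arm[cbind(match(arm_calls$sample_id[gi], samples),
              match(paste0(arm_calls$arm[gi], ":gain"), arm_events$event_id))] <- TRUE
  M_arm[cbind(match(arm_calls$sample_id[li], samples),
              match(paste0(arm_calls$arm[li], ":loss"), arm_events$event_id))] <- TRUE

  if (!is.null(regions) && nrow(regions) > 0L) {
    suffix <- ifelse(regions$type == "AMP", "amp", "del")
    foc_ids <- paste0(regions$region_id, ":", suffix)
    if (anyDuplicated(foc_ids))
      stop_fmt("build_event_matrix: duplicate event ids in regions")
    # focal-scope segments called against their arm background
    sp <- arm_split_with_scope(segs, arms, focal_cutoff, merge_tol)
    scope <- sp$scope
    dev <- sp$dev_arm
    M_foc <- matrix(FALSE, length(samples), length(foc_ids),
                    dimnames = list(samples, foc_ids))
    eps <- 1e-9   # strict thresholds, guarded against double rounding
    for (r in seq_len(nrow(regions))) {
      want <- if (regions$type[r] == "AMP") dev > call_threshold + eps else
        dev < -call_threshold - eps
      hit <- scope == "FOCAL" & want &
        sp$chrom == regions$chrom[r] &
        sp$start < regions$end[r] & sp$end > regions$start[r]
      M_foc[match(unique(sp$sample[hit]), samples), r] <- TRUE
    }
    M <- cbind(M_arm, M_foc)
    events <- rbind(arm_events,
                    data.frame(event_id = foc_ids, kind = "focal",
                               stringsAsFactors = FALSE))
  } else {
    M <- M_arm
    events <- arm_events
  }
  focal_cols <- events$kind == "focal"
  structure(list(
    matrix = M,
    events = events,
    focal_count = stats::setNames(as.integer(rowSums(M[, focal_cols, drop = FALSE])),
                                  samples)
  ), class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix: %d samples x %d events (%d arm, %d focal)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$events$kind == "arm"), sum(x$events$kind == "focal")))
  invisible(x)
}
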