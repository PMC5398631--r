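#' In-silico admixture removal (ISAR)
#'
#' A tumor specimen with purity alpha is modeled as a linear mixture of
#' tumor cells with copy level q and normal diploid cells:
#' `c_mix = alpha * q + (1 - alpha) * 2`. Array profiles are normalized so
#' the sample's length-weighted mean copy level reads as diploid, which
#' divides the mixture by `D = (alpha * tau + 2 * (1 - alpha)) / 2`, with
#' tau the tumor ploidy (length-weighted mean of q). Given alpha and tau
#' the correction inverts this: `q = (c * D - 2 * (1 - alpha)) / alpha`.
#' With alpha = 1 and tau = 2 the correction is the identity; it is the
#' unique linear inversion consistent with admixed normal cells being
#' diploid. Negative corrected values are clipped to 0 (counted in the
#' `n_clipped` attribute).
#'
#' @param segs cohort segment table (see [read_seg()]), observed values.
#' @param purity purity-ploidy data frame (see [read_purity_table()]).
#' @param purity_floor samples with `alpha` below this are treated as not
#'   confidently correctable and excluded (default 0.2).
#' @return corrected segment table covering the confident samples only,
#'   with attributes `excluded` (sample ids refused), `alpha`, `tau`
#'   (named vectors of the values used) and `n_clipped`.
#' @export
isar_correct <- function(segs, purity, purity_floor = 0.2) {
  stopifnot(all(c("sample_id", "alpha", "tau", "confident") %in% names(purity)))
  samples <- unique(segs$sample)
  missing <- setdiff(samples, purity$sample_id)
  i <- match(samples, purity$sample_id)
  conf <- !is.na(i) & purity$confident[i] & !is.na(purity$alpha[i]) &
    purity$alpha[i] >= purity_floor
  conf[is.na(conf)] <- FALSE
  if (any(!is.na(i) & purity$alpha[i] <= 0, na.rm = TRUE))
    stop_fmt("isar_correct: alpha must be positive")
  keep <- samples[conf]
  out <- segs[segs$sample %in% keep, , drop = FALSE]
  alpha <- stats::setNames(purity$alpha[i][conf], keep)
  tau <- stats::setNames(purity$tau[i][conf], keep)
  n_clipped <- 0L
  for (s in keep) {
    sel <- out$sample == s
    a <- alpha[[s]]
    D <- (a * tau[[s]] + 2 * (1 - a)) / 2
    q <- (out$value[sel] * D - 2 * (1 - a)) / a
    n_clipped <- n_clipped + sum(q < 0)
    out$value[sel] <- pmax(q, 0)
  }
  if (n_clipped > 0L)
    warn_fmt("isar_correct: clipped %d negative corrected values to 0", n_clipped)
  rownames(out) <- NULL
  attr(out, "excluded") <- c(missing, samples[!conf & !(samples %in% missing)])
  attr(out, "alpha") <- alpha
  attr(out, "tau") <- tau
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Forward admixture model
#'
#' The simulation-side counterpart of [isar_correct()]: mixes a true
#' tumor profile with diploid normal cells at purity `alpha` and
#' renormalizes so the length-weighted mean maps to 2.
#'
#' @param segs segment table with true tumor copy values.
#' @param alpha named vector (by sample) or scalar purity.
#' @return segment table of observed values; attribute `tau` records the
#'   length-weighted mean tumor ploidy per sample.
#' @export
admix_profile <- function(segs, alpha) {
  samples <- unique(segs$sample)
  if (length(alpha) == 1L && is.null(names(alpha)))
    alpha <- stats::setNames(rep(alpha, length(samples)), samples)
  tau <- numeric(0)
  for (s in samples) {
    sel <- segs$sample == s
    w <- segs$end[sel] - segs$start[sel]
    t_s <- sum(w * segs$value[sel]) / sum(w)
    a <- alpha[[s]]
    D <- (a * t_s + 2 * (1 - a)) / 2
    segs$value[sel] <- (a * segs$value[sel] + 2 * (1 - a)) / D
    tau[s] <- t_s
  }
  attr(segs, "tau") <- tau
  segs
}

#' Genomic disruption score
#'
#' The fraction of the genome whose copy level differs from the sample's
#' length-weighted median by strictly more than `threshold` copies
#' (default 0.1). `focal_fraction` restricts the numerator to segments of
#' FOCAL scope (shorter than `focal_cutoff` of their chromosome arm).
#'
#' @param segs (corrected) cohort segment table.
#' @param arms arm data frame; only segments within these arms count.
#' @param threshold copy-unit deviation threshold (default 0.1, strict).
#' @param focal_cutoff arm-fraction cutoff separating focal from
#'   arm-level segments (default 0.5).
#' @param merge_tol adjacent segments with copy values within this
#'   tolerance are treated as one alteration when judging scope
#'   (default 0.3).
#' @return data frame with columns `sample_id`, `fraction`,
#'   `focal_fraction`.
#' @export
genomic_disruption <- function(segs, arms, threshold = 0.1, focal_cutoff = 0.5,
                               merge_tol = 0.3) {
  if (nrow(segs) == 0L) stop_fmt("genomic_disruption: empty profile set")
  sp <- arm_split_with_scope(segs, arms, focal_cutoff, merge_tol)
  scope <- sp$scope
  out <- lapply(split(seq_len(nrow(sp)), sp$sample), function(ii) {
    w <- sp$end[ii] - sp$start[ii]
    if (sum(w) <= 0) stop_fmt("genomic_disruption: zero-length genome")
    med <- weighted_median(sp$value[ii], w)
    dev <- abs(sp$value[ii] - med) > threshold + 1e-9  # strict, rounding-guarded
    data.frame(sample_id = sp$sample[ii][1L],
               fraction = sum(w[dev]) / sum(w),
               focal_fraction = sum(w[dev & scope[ii] == "FOCAL"]) / sum(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call SCNA segments against the sample median
#'
#' A segment is a GAIN when its copy level exceeds the sample's
#' length-weighted median by strictly more than `threshold` copies
#' (default 0.2), a LOSS when it falls below by more than `threshold`;
#' all other segments are uncalled.
#'
#' @param segs (corrected) cohort segment table.
#' @param threshold copy-unit call threshold (default 0.2, strict).
#' @return data frame of called segments with `direction` (GAIN/LOSS) and
#'   `magnitude` (absolute deviation from the sample median).
#' @export
call_scna_segments <- function(segs, threshold = 0.2) {
  if (nrow(segs) == 0L) stop_fmt("call_scna_segments: empty profile set")
  out <- lapply(split(seq_len(nrow(segs)), segs$sample), function(ii) {
    w <- segs$end[ii] - segs$start[ii]
    med <- weighted_median(segs$value[ii], w)
    dev <- segs$value[ii] - med
    called <- abs(dev) > threshold + 1e-9  # strict, rounding-guarded
    s <- segs[ii, , drop = FALSE][called, , drop = FALSE]
    s$direction <- ifelse(dev[called] > 0, "GAIN", "LOSS")
    s$magnitude <- abs(dev[called])
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
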