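#' Stratum assignment for the permutation test
#'
#' Default strata are the CIN class crossed with within-class quantile
#' bins of focal genomic disruption, the confound structure the
#' differential test controls for; any other discrete covariate column
#' can be substituted. Bins collapse automatically when disruption is
#' constant within a class.
#'
#' @param metadata metadata data frame; every tested sample needs a
#'   non-UNKNOWN `subtype_label` (or `cin_labels` supplied).
#' @param disruption disruption data frame from [genomic_disruption()]
#'   (used when `covariate` is "focal_disruption").
#' @param n_bins number of quantile bins within each CIN class
#'   (default 4).
#' @param cin_labels optional named vector of CIN/NON_CIN labels
#'   overriding the metadata (e.g. SVM predictions).
#' @param covariate "focal_disruption" (default) or the name of a
#'   metadata column to stratify on instead of disruption bins.
#' @return data frame with columns `sample_id`, `stratum`.
#' @export
assign_strata <- function(metadata, disruption = NULL, n_bins = 4L,
                          cin_labels = NULL, covariate = "focal_disruption") {
  ids <- metadata$sample_id
  cin <- if (!is.null(cin_labels)) as.character(cin_labels[ids]) else metadata$subtype_label
  if (any(is.na(cin) | cin == "UNKNOWN"))
    stop_fmt("assign_strata: samples without CIN labels: %s",
             paste(utils::head(ids[is.na(cin) | cin == "UNKNOWN"], 5L), collapse = ", "))
  if (covariate == "focal_disruption") {
    stopifnot(!is.null(disruption))
    fd <- disruption$focal_fraction[match(ids, disruption$sample_id)]
    if (anyNA(fd)) stop_fmt("assign_strata: missing disruption scores")
    bin <- rep(1L, length(ids))
    for (cl in unique(cin)) {
      ii <- cin == cl
      br <- unique(stats::quantile(fd[ii], probs = seq(0, 1, length.out = n_bins + 1L),
                                   type = 7))
      if (length(br) > 2L) {
        bin[ii] <- as.integer(cut(fd[ii], br, include.lowest = TRUE))
      }
    }
    stratum <- paste(cin, bin, sep = ":")
  } else {
    if (!covariate %in% names(metadata))
      stop_fmt("assign_strata: no metadata column '%s'", covariate)
    stratum <- paste(cin, metadata[[covariate]], sep = ":")
  }
  data.frame(sample_id = ids, stratum = stratum, stringsAsFactors = FALSE)
}

#' Stratified permutation test for a cohort-differential event
#'
#' Tests whether an event's rate differs between the Western and Eastern
#' cohorts, controlling for stratum structure: the statistic is the raw
#' rate difference `T = rate_west - rate_east`, and the null is built by
#' shuffling cohort labels independently within each stratum (equivalent
#' to drawing, per stratum, a hypergeometric count of event carriers
#' assigned to the Western labels - the implementation samples these
#' counts directly, which is exact and fast). Two-sided empirical p-value
#' with the add-one estimator: `p = (1 + #{|T*| >= |T|}) / (1 + n_perm)`,
#' so p is never below `1/(n_perm + 1)`. Strata containing only one
#' cohort contribute no permutations.
#'
#' @param event logical vector, one entry per sample (event present).
#' @param cohort character/factor of "EAST"/"WEST", same order.
#' @param strata stratum ids, same order (a single stratum gives the
#'   naive unstratified shuffle).
#' @param n_perm number of permutations (default 49000).
#' @param seed integer seed (deterministic results).
#' @return list with `statistic`, `p_perm`, `rate_east`, `rate_west`,
#'   `n_perm`.
#' @export
stratified_permutation_test <- function(event, cohort, strata,
                                        n_perm = 49000L, seed = 1L) {
  stopifnot(length(event) == length(cohort), length(event) == length(strata))
  event <- as.logical(event)
  west <- cohort == "WEST"
  Nw <- sum(west); Ne <- sum(!west)
  if (Nw == 0L || Ne == 0L) stop_fmt("stratified_permutation_test: both cohorts required")
  rate_w <- mean(event[west]); rate_e <- mean(event[!west])
  T_obs <- rate_w - rate_e
  E_tot <- sum(event)
  if (E_tot == 0L)
    return(list(statistic = 0, p_perm = 1, rate_east = 0, rate_west = 0,
                n_perm = n_perm))
  set.seed(derive_seed(seed, 0L))
  Kw <- numeric(n_perm)
  for (s in unique(strata)) {
    ii <- strata == s
    e_s <- sum(event[ii]); n_s <- sum(ii); w_s <- sum(west[ii])
    if (e_s == 0L || w_s == 0L || w_s == n_s) {
      Kw <- Kw + if (w_s == n_s) e_s else 0
    } else {
      Kw <- Kw + stats::rhyper(n_perm, e_s, n_s - e_s, w_s)
    }
  }
  T_null <- Kw / Nw - (E_tot - Kw) / Ne
  p <- (1 + sum(abs(T_null) >= abs(T_obs) - 1e-12)) / (1 + n_perm)
  list(statistic = T_obs, p_perm = p, rate_east = rate_e, rate_west = rate_w,
       n_perm = n_perm)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities of tables (at the observed margins)
#' no more probable than the observed one. Backed by [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop_fmt("fisher_exact_2x2: negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact for combined sample sizes up to 20 without ties; otherwise the
#' normal approximation with tie correction (no continuity correction).
#' Backed by [stats::wilcox.test()].
#'
#' @param x,y non-empty numeric vectors.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop_fmt("wilcoxon_rank_sum: both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)$p.value)
}

#' Benjamini-Hochberg FDR over powered tests only
#'
#' The step-up procedure is applied only to events flagged `powered`;
#' underpowered events - those that could not reach significance under
#' any label assignment - receive `NA` and do not inflate the multiple
#' testing burden (m = number of powered tests).
#'
#' @param pvalues p-values in [0, 1].
#' @param powered logical mask, same length (default all powered).
#' @return q-values, `NA` where unpowered.
#' @export
bh_fdr <- function(pvalues, powered = rep(TRUE, length(pvalues))) {
  stopifnot(length(pvalues) == length(powered))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_fmt("bh_fdr: p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvalues))
  q[powered] <- stats::p.adjust(pvalues[powered], method = "BH")
  q
}

#' Power filter for a cohort-differential event
#'
#' An event with k carriers is powered when the minimum achievable
#' two-sided p-value - the probability, under the within-stratum
#' hypergeometric null, of the most extreme possible allocation (all
#' carriers pushed into one cohort within each stratum), doubled and
#' capped at 1 - is at most `alpha`. Events with zero carriers are
#' always unpowered.
#'
#' @inheritParams stratified_permutation_test
#' @param alpha significance level the event must be able to reach
#'   (default 0.05).
#' @return logical; attribute `min_p` carries the minimum achievable p.
#' @export
powered_filter <- function(event, cohort, strata, alpha = 0.05) {
  event <- as.logical(event)
  if (sum(event) == 0L) return(structure(FALSE, min_p = 1))
  west <- cohort == "WEST"
  lp_w <- 0; lp_e <- 0
  for (s in unique(strata)) {
    ii <- strata == s
    e_s <- sum(event[ii]); n_s <- sum(ii); w_s <- sum(west[ii])
    if (e_s == 0L) next
    k_w <- min(e_s, w_s)                       # all carriers pushed West
    k_e <- e_s - min(e_s, n_s - w_s)           # all carriers pushed East
    lp_w <- lp_w + stats::dhyper(k_w, e_s, n_s - e_s, w_s, log = TRUE)
    lp_e <- lp_e + stats::dhyper(k_e, e_s, n_s - e_s, w_s, log = TRUE)
  }
  min_p <- min(1, 2 * exp(min(lp_w, lp_e)))
  structure(min_p <= alpha, min_p = min_p)
}

#' Compare event rates between cohorts
#'
#' Runs the stratified permutation test, the power filter and BH FDR
#' over every event column of an event matrix. Per-event seeds are
#' derived from the master seed and the event index, so each event's
#' result is reproducible independently of evaluation order.
#'
#' @param em `event_matrix` from [build_event_matrix()] (or a plain
#'   logical matrix with column names).
#' @param metadata metadata with `cohort_label` EAST/WEST for every
#'   tested sample (others are dropped).
#' @param strata stratum assignment from [assign_strata()].
#' @param n_perm permutations per event (default 49000).
#' @param seed master seed.
#' @param alpha FDR threshold used by the power filter (default 0.05).
#' @return results data frame (columns `event_id`, `rate_east`,
#'   `rate_west`, `statistic`, `p_perm`, `q_bh`, `powered`), sorted by q
#'   then p.
#' @export
compare_cohorts <- function(em, metadata, strata, n_perm = 49000L, seed = 1L,
                            alpha = 0.05) {
  M <- if (inherits(em, "event_matrix")) em$matrix else em
  keep <- metadata$sample_id[metadata$cohort_label %in% c("EAST", "WEST")]
  keep <- intersect(rownames(M), keep)
  M <- M[keep, , drop = FALSE]
  cohort <- metadata$cohort_label[match(keep, metadata$sample_id)]
  st <- strata$stratum[match(keep, strata$sample_id)]
  if (anyNA(st)) stop_fmt("compare_cohorts: samples missing stratum assignment")
  res <- lapply(seq_len(ncol(M)), function(j) {
    tst <- stratified_permutation_test(M[, j], cohort, st, n_perm,
                                       seed = derive_seed(seed, j))
    pow <- powered_filter(M[, j], cohort, st, alpha)
    data.frame(event_id = colnames(M)[j], rate_east = tst$rate_east,
               rate_west = tst$rate_west, statistic = tst$statistic,
               p_perm = tst$p_perm, powered = as.logical(pow),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_bh <- bh_fdr(res$p_perm, res$powered)
  res <- res[order(res$q_bh, res$p_perm, res$event_id, na.last = TRUE),
             c("event_id", "rate_east", "rate_west", "statistic", "p_perm",
               "q_bh", "powered")]
  rownames(res) <- NULL
  res
}
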