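#' EIGENSTRAT-style genotype PCA
#'
#' Principal components of a germline dosage matrix under the standard
#' EIGENSTRAT normalization: each SNP j is centered by twice its sample
#' allele frequency and scaled by `sqrt(p_j (1 - p_j))`, where
#' `p_j = (1 + sum_i g_ij) / (2 + 2 n)` is the posterior allele-frequency
#' estimate; missing entries become 0 after standardization (mean
#' imputation); monomorphic SNPs are dropped. Eigen-decomposition of the
#' sample-by-sample covariance `X'X / M` (M = SNPs used) yields
#' eigenvalues (non-increasing) and per-sample projections
#' (eigenvectors). LD pruning and iterative outlier-removal rounds are
#' intentionally omitted; a single outlier pass lives in
#' [classify_two_clusters()].
#'
#' @param G integer matrix, SNPs x samples, dosages in {0,1,2}, NA for
#'   missing (see [read_genotypes()]).
#' @param n_components number of components to return (default 10).
#' @return object of class `eigenstrat_pca`: list with `eigenvalues`,
#'   `projections` (samples x components, rownames = sample ids) and
#'   `snps_used`.
#' @export
eigenstrat_pca <- function(G, n_components = 10L) {
  stopifnot(is.matrix(G), ncol(G) >= 2L)
  n <- ncol(G)
  nonmiss <- !is.na(G)
  poly <- apply(G, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0L && any(r != r[1L])
  })
  if (!any(poly)) stop_fmt("eigenstrat_pca: all SNPs are monomorphic")
  Gp <- G[poly, , drop = FALSE]
  m <- nrow(Gp)
  rs <- rowSums(Gp, na.rm = TRUE)
  nn <- rowSums(!is.na(Gp))
  p_post <- (1 + rs) / (2 + 2 * nn)
  p_hat <- rs / (2 * nn)
  X <- (Gp - 2 * p_hat) / sqrt(p_post * (1 - p_post))
  X[is.na(X)] <- 0
  C <- crossprod(X) / m
  eg <- eigen(C, symmetric = TRUE)
  k <- min(n_components, n)
  structure(list(
    eigenvalues = eg$values[seq_len(k)],
    projections = matrix(eg$vectors[, seq_len(k)], nrow = n,
                         dimnames = list(colnames(G), paste0("PC", seq_len(k)))),
    snps_used = m
  ), class = "eigenstrat_pca")
}

#' @export
print.eigenstrat_pca <- function(x, ...) {
  cat(sprintf("eigenstrat_pca: %d samples, %d SNPs used\n", nrow(x$projections),
              x$snps_used))
  cat("eigenvalues:", paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Two-cluster ancestry assignment on PC1
#'
#' One-dimensional two-means clustering of the primary component
#' (exhaustive over split points of the sorted projections, so exact and
#' deterministic), followed by a single outlier pass: a sample is
#' UNCLASSIFIED when its distance to its cluster's median exceeds
#' `outlier_k` times that cluster's robust spread (1.4826 x median
#' absolute deviation; median and MAD so that a far-flung point cannot
#' drag along the location and spread used to judge it). Cluster-to-cohort orientation is fixed
#' by `anchors`, samples of known ancestry; without anchors the cluster
#' with the lower PC1 center is labeled EAST (the PC sign is arbitrary,
#' so supply anchors whenever the orientation matters).
#'
#' @param pc1 numeric vector of PC1 projections, named by sample id (or
#'   an `eigenstrat_pca` object, whose PC1 is used).
#' @param outlier_k outlier multiplier (default 3).
#' @param anchors named character vector mapping anchor sample ids to
#'   "EAST"/"WEST" (optional).
#' @return data frame with columns `sample_id`, `label` (EAST, WEST or
#'   UNCLASSIFIED) and `pc1_projection`.
#' @export
classify_two_clusters <- function(pc1, outlier_k = 3, anchors = NULL) {
  if (inherits(pc1, "eigenstrat_pca"))
    pc1 <- stats::setNames(pc1$projections[, 1L], rownames(pc1$projections))
  stopifnot(length(pc1) >= 4L)
  ids <- names(pc1) %||% as.character(seq_along(pc1))
  x <- as.numeric(pc1)
  if (max(x) - min(x) < 1e-15) {
    warn_fmt("classify_two_clusters: degenerate PC1 (all equal); all UNCLASSIFIED")
    return(data.frame(sample_id = ids, label = "UNCLASSIFIED", pc1_projection = x,
                      stringsAsFactors = FALSE))
  }
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  wss <- vapply(seq_len(n - 1L), function(k) {
    (cs2[k] - cs[k]^2 / k) +
      ((cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k))
  }, numeric(1))
  k <- which.min(wss)
  lower <- ord[seq_len(k)]
  upper <- ord[(k + 1L):n]
  centers <- c(mean(x[lower]), mean(x[upper]))
  meds <- c(stats::median(x[lower]), stats::median(x[upper]))
  spread <- c(1.4826 * stats::median(abs(x[lower] - meds[1L])),
              1.4826 * stats::median(abs(x[upper] - meds[2L])))
  cl <- ifelse(abs(x - centers[1L]) <= abs(x - centers[2L]), 1L, 2L)
  # judged against the cluster median, which a far outlier cannot drag along
  outlier <- abs(x - meds[cl]) > outlier_k * spread[cl]
  cluster_names <- c("EAST", "WEST")          # lower center -> EAST by default
  if (!is.null(anchors)) {
    a_idx <- match(names(anchors), ids)
    if (all(is.na(a_idx))) warn_fmt("classify_two_clusters: no anchors found among samples")
    votes <- table(factor(anchors[!is.na(a_idx)], c("EAST", "WEST")),
                   factor(cl[a_idx[!is.na(a_idx)]], 1:2))
    if (sum(votes) > 0) {
      east_cluster <- if (votes["EAST", "1"] + votes["WEST", "2"] >=
                          votes["EAST", "2"] + votes["WEST", "1"]) 1L else 2L
      cluster_names <- if (east_cluster == 1L) c("EAST", "WEST") else c("WEST", "EAST")
    }
  }
  label <- ifelse(outlier, "UNCLASSIFIED", cluster_names[cl])
  data.frame(sample_id = ids, label = label, pc1_projection = x,
             stringsAsFactors = FALSE)
}
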