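# In-code fixtures shared across tests. Everything is generated, nothing
# is read from disk except through the package's own writers.

# A small two-chromosome arm table: chr1 with p and q, chr2 acrocentric (q only).
tiny_arms <- function() {
  data.frame(
    arm = c("1p", "1q", "2q"),
    chrom = c("1", "1", "2"),
    start = c(0, 100e6, 30e6),
    end = c(100e6, 250e6, 180e6),
    stringsAsFactors = FALSE
  )
}

# Flat diploid profile over an arm table for the given samples.
flat_profiles <- function(sample_ids, arms = tiny_arms(), value = 2) {
  do.call(rbind, lapply(sample_ids, function(s)
    data.frame(sample = s, chrom = arms$chrom, start = arms$start,
               end = arms$end, n_markers = pmax(1L, as.integer((arms$end - arms$start) / 1e6)),
               value = value, stringsAsFactors = FALSE)))
}

# Random segmented profiles: each arm is split into 1-4 segments with
# copy values drawn from a mixture centered on 2.
random_profiles <- function(sample_ids, arms = tiny_arms()) {
  rows <- list()
  for (s in sample_ids) {
    for (i in seq_len(nrow(arms))) {
      k <- sample(1:4, 1)
      cuts <- sort(c(arms$start[i], arms$end[i],
                     if (k > 1) round(stats::runif(k - 1, arms$start[i], arms$end[i]))))
      cuts <- unique(cuts)
      for (j in seq_len(length(cuts) - 1L)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = arms$chrom[i], start = cuts[j], end = cuts[j + 1L],
          n_markers = max(1L, as.integer((cuts[j + 1L] - cuts[j]) / 1e6)),
          value = max(0.2, 2 + sample(c(-1, 0, 0, 1), 1) + stats::rnorm(1, 0, 0.02)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Exhaustive two-sided p-value oracle for a single-stratum label shuffle:
# enumerate all ways to choose which samples are labeled WEST.
enumerate_perm_p <- function(event, n_west) {
  n <- length(event)
  sets <- utils::combn(n, n_west)
  T_obs <- mean(event[seq_len(n_west)]) - mean(event[-seq_len(n_west)])
  Ts <- apply(sets, 2, function(w) mean(event[w]) - mean(event[-w]))
  mean(abs(Ts) >= abs(T_obs) - 1e-12)
}

# Exhaustive two-sided Fisher oracle: sum hypergeometric probabilities of
# all tables with the observed margins that are no more probable.
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive two-sided Wilcoxon rank-sum oracle (distinct values).
enumerate_wilcoxon_p <- function(x, y) {
  n <- length(x) + length(y)
  ranks <- rank(c(x, y))
  W_obs <- sum(ranks[seq_along(x)])
  sets <- utils::combn(n, length(x))
  Ws <- apply(sets, 2, function(ii) sum(rank(c(x, y))[ii]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
}
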