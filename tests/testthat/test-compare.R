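test_that("strata cross CIN classes with within-class disruption quartiles", {
  md <- data.frame(sample_id = sprintf("S%02d", 1:16),
                   cohort_label = rep(c("EAST", "WEST"), 8),
                   subtype_label = rep(c("CIN", "NON_CIN"), each = 8),
                   stringsAsFactors = FALSE)
  d <- data.frame(sample_id = md$sample_id, fraction = 0.5,
                  focal_fraction = seq(0.01, 0.16, by = 0.01))
  st <- assign_strata(md, d, n_bins = 4)
  expect_equal(length(unique(st$stratum)), 8L)
  expect_true(all(table(st$stratum) == 2L))
  # constant disruption collapses bins to the CIN classes alone
  d$focal_fraction <- 0.05
  st2 <- assign_strata(md, d, n_bins = 4)
  expect_setequal(unique(st2$stratum), c("CIN:1", "NON_CIN:1"))
  md$subtype_label[1] <- "UNKNOWN"
  expect_error(assign_strata(md, d), "without CIN labels.*S01")
})

test_that("the stratified permutation p matches exhaustive enumeration", {
  # several single-stratum configurations with a finite outcome space
  configs <- list(
    list(event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), n_west = 4),
    list(event = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
         n_west = 5),
    list(event = c(TRUE, rep(FALSE, 6)), n_west = 3)
  )
  for (cf in configs) {
    n <- length(cf$event)
    cohort <- c(rep("WEST", cf$n_west), rep("EAST", n - cf$n_west))
    p_exact <- enumerate_perm_p(cf$event, cf$n_west)
    r <- stratified_permutation_test(cf$event, cohort, rep("s", n),
                                     n_perm = 30000, seed = 11)
    se <- sqrt(p_exact * (1 - p_exact) / 30000)
    expect_lt(abs(r$p_perm - p_exact), 3 * se + 2 / 30000)
  }
})

test_that("two-stratum permutation p matches enumeration over both strata", {
  event <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  cohort <- c("WEST", "EAST", "WEST", "EAST", "WEST", "WEST", "EAST", "EAST")
  strata <- rep(c("a", "b"), each = 4)
  # enumerate all within-stratum west-set choices
  w_a <- utils::combn(1:4, 2); w_b <- utils::combn(5:8, 2)
  Ts <- c()
  for (i in seq_len(ncol(w_a))) for (j in seq_len(ncol(w_b))) {
    west <- c(w_a[, i], w_b[, j])
    Ts <- c(Ts, mean(event[west]) - mean(event[-west]))
  }
  T_obs <- mean(event[cohort == "WEST"]) - mean(event[cohort == "EAST"])
  p_exact <- mean(abs(Ts) >= abs(T_obs) - 1e-12)
  r <- stratified_permutation_test(event, cohort, strata, n_perm = 30000, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 30000)
  expect_lt(abs(r$p_perm - p_exact), 3 * se + 2 / 30000)
})

test_that("degenerate events give p = 1 and the add-one floor holds", {
  cohort <- rep(c("EAST", "WEST"), each = 10)
  st <- rep("s", 20)
  allev <- stratified_permutation_test(rep(TRUE, 20), cohort, st, 1000, 1)
  expect_equal(allev$statistic, 0)
  expect_equal(allev$p_perm, 1)
  none <- stratified_permutation_test(rep(FALSE, 20), cohort, st, 1000, 1)
  expect_equal(none$p_perm, 1)
  extreme <- stratified_permutation_test(c(rep(FALSE, 10), rep(TRUE, 10)),
                                         cohort, st, 1000, 1)
  expect_gte(extreme$p_perm, 1 / 1001)
})

test_that("identical seeds reproduce the permutation p exactly", {
  event <- rep(c(TRUE, FALSE, FALSE), length.out = 30)
  cohort <- rep(c("EAST", "WEST"), 15)
  st <- rep(c("a", "b"), each = 15)
  r1 <- stratified_permutation_test(event, cohort, st, 2000, seed = 9)
  r2 <- stratified_permutation_test(event, cohort, st, 2000, seed = 9)
  expect_identical(r1, r2)
})

test_that("Fisher p-values agree with hypergeometric enumeration everywhere", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(0, 3, 0, 4), 2)), 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
  for (a in 0:4) for (b in 0:3) for (c in 0:3) for (d in 0:3) {
    tab <- matrix(c(a, c, b, d), 2)
    expect_equal(fisher_exact_2x2(tab), enumerate_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("Wilcoxon p-values agree with rank enumeration for small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)
  set.seed(21)
  for (n1 in 2:5) for (n2 in 2:5) {
    x <- sample(seq_len(100), n1); y <- sample(setdiff(seq_len(100), x), n2)
    expect_equal(wilcoxon_rank_sum(x, y), enumerate_wilcoxon_p(x, y),
                 tolerance = 1e-9)
    expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("BH is applied to powered tests only", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  q <- bh_fdr(c(0.01, 0.5, 0.5, 0.5), powered = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(q, c(0.01, NA, NA, NA))
  # manual step-up: q_i = min_{j >= i} p_(j) * m / j
  p <- c(0.30, 0.01, 0.04, 0.20, 0.03)
  o <- order(p); m <- 5
  qs <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(bh_fdr(p), qs)
})

test_that("the power filter tracks the most extreme achievable allocation", {
  cohort <- rep(c("EAST", "WEST"), each = 100)
  st <- rep("s", 200)
  ev1 <- c(TRUE, rep(FALSE, 199))
  expect_false(powered_filter(ev1, cohort, st))
  expect_equal(attr(powered_filter(ev1, cohort, st), "min_p"), 1.0)
  ev10 <- c(rep(TRUE, 10), rep(FALSE, 190))
  pw <- powered_filter(ev10, cohort, st)
  expect_true(pw)
  expect_equal(attr(pw, "min_p"), 2 * choose(100, 10) / choose(200, 10),
               tolerance = 1e-9)
  expect_false(powered_filter(rep(FALSE, 200), cohort, st))
})

test_that("the power filter min-p matches counting over label assignments", {
  # two small strata; oracle counts, over all equally likely west-sets,
  # the probability of the most extreme within-stratum allocation
  event <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  cohort <- c(rep(c("WEST", "EAST"), 2), "WEST",
              rep(c("WEST", "EAST"), 2), "EAST")
  strata <- rep(c("a", "b"), each = 5)
  min_p <- attr(powered_filter(event, cohort, strata), "min_p")
  count_extreme <- function(push_west) {
    prob <- 1
    for (s in unique(strata)) {
      ii <- strata == s
      e <- sum(event[ii]); n <- sum(ii); w <- sum(cohort[ii] == "WEST")
      k <- if (push_west) min(e, w) else e - min(e, n - w)
      sets <- utils::combn(n, w)
      carriers <- which(event[ii])
      hits <- sum(apply(sets, 2, function(ss) sum(carriers %in% ss) == k))
      prob <- prob * hits / ncol(sets)
    }
    prob
  }
  expect_equal(min_p, min(1, 2 * min(count_extreme(TRUE), count_extreme(FALSE))),
               tolerance = 1e-9)
})

test_that("compare_cohorts assembles rates, p, q and power flags per event", {
  set.seed(8)
  n <- 60
  ids <- sprintf("S%02d", 1:n)
  md <- data.frame(sample_id = ids,
                   cohort_label = rep(c("EAST", "WEST"), each = n / 2),
                   subtype_label = "CIN", stringsAsFactors = FALSE)
  strata <- data.frame(sample_id = ids, stratum = "s", stringsAsFactors = FALSE)
  M <- cbind(strong = c(rep(FALSE, 28), TRUE, TRUE, rep(TRUE, 18), rep(FALSE, 12)),
             null_ev = rep(c(TRUE, FALSE), n / 2),
             absent = rep(FALSE, n))
  rownames(M) <- ids
  res <- compare_cohorts(M, md, strata, n_perm = 4000, seed = 2)
  expect_identical(sort(res$event_id), c("absent", "null_ev", "strong"))
  strong <- res[res$event_id == "strong", ]
  expect_equal(strong$rate_west - strong$rate_east, strong$statistic)
  expect_lt(strong$p_perm, 0.01)
  expect_true(strong$powered)
  expect_false(res$powered[res$event_id == "absent"])
  expect_true(is.na(res$q_bh[res$event_id == "absent"]))
  # per-event seeds: rerun reproduces exactly
  expect_identical(res, compare_cohorts(M, md, strata, n_perm = 4000, seed = 2))
})
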