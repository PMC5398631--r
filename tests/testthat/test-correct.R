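test_that("weighted median follows the midpoint convention at 50% mass", {
  expect_equal(weighted_median(c(2.0, 2.3), c(1, 1)), 2.15)
  expect_equal(weighted_median(c(2, 2, 2), c(1, 5, 3)), 2)
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 2)), 2.5)  # mass hits 0.5 at 2
  expect_equal(weighted_median(c(1, 2, 3), c(1, 2, 1)), 2)
})

test_that("ISAR correction is the identity for a pure diploid-scaled sample", {
  segs <- flat_profiles("S1", value = 2)
  segs$value <- c(2, 3, 2)
  pp <- data.frame(sample_id = "S1", alpha = 1,
                   tau = sum((segs$end - segs$start) * segs$value) /
                     sum(segs$end - segs$start), confident = TRUE)
  # observed profile renormalized to mean 2, then corrected back
  obs <- admix_profile(segs, 1)
  corr <- isar_correct(obs, pp)
  expect_equal(corr$value, segs$value, tolerance = 1e-12)
})

test_that("an all-diploid tumor is a fixed point of the admixture model", {
  segs <- flat_profiles("S1", value = 2)
  obs <- admix_profile(segs, 0.5)
  expect_equal(obs$value, rep(2, nrow(segs)))
  pp <- data.frame(sample_id = "S1", alpha = 0.5, tau = 2, confident = TRUE)
  expect_equal(isar_correct(obs, pp)$value, rep(2, nrow(segs)))
})

test_that("forward admixture then correction recovers true copies across alpha", {
  set.seed(7)
  for (alpha in c(0.06, 0.2, 0.5, 0.8, 1)) {
    segs <- random_profiles(c("A", "B"))
    obs <- admix_profile(segs, alpha)
    tau <- attr(obs, "tau")
    pp <- data.frame(sample_id = c("A", "B"), alpha = alpha, tau = tau[c("A", "B")],
                     confident = TRUE)
    corr <- isar_correct(obs, pp, purity_floor = 0.05)
    expect_lt(max(abs(corr$value - segs$value)), 1e-9)
  }
})

test_that("non-confident or low-purity samples are refused and reported", {
  segs <- flat_profiles(c("S1", "S2", "S3"))
  pp <- data.frame(sample_id = c("S1", "S2", "S3"), alpha = c(0.9, 0.1, 0.9),
                   tau = 2, confident = c(TRUE, TRUE, FALSE))
  corr <- isar_correct(segs, pp)
  expect_identical(unique(corr$sample), "S1")
  expect_setequal(attr(corr, "excluded"), c("S2", "S3"))
  pp$alpha[1] <- -0.2
  expect_error(isar_correct(segs, pp), "alpha must be positive")
})

test_that("genomic disruption counts strict exceedance of the threshold", {
  arms <- tiny_arms()
  flat <- flat_profiles("S1", arms)
  expect_equal(genomic_disruption(flat, arms)$fraction, 0)
  # two equal-length segments at 2.0 and 2.3: median 2.15, both deviate by 0.15
  segs <- data.frame(sample = "S1", chrom = "1", start = c(0, 100e6),
                     end = c(100e6, 200e6), n_markers = 100L, value = c(2.0, 2.3))
  arms1 <- data.frame(arm = c("1p", "1q"), chrom = "1", start = c(0, 100e6),
                      end = c(100e6, 200e6))
  expect_equal(genomic_disruption(segs, arms1)$fraction, 1.0)
  # a deviation of exactly 0.1 is not "more than 0.1"
  segs$value <- c(2.0, 2.0)
  segs$value[2] <- 2.0 + 0.1
  segs2 <- rbind(segs, data.frame(sample = "S1", chrom = "2", start = 30e6,
                                  end = 180e6, n_markers = 150L, value = 2.0))
  d <- genomic_disruption(segs2, arms)
  expect_equal(d$fraction, 0)
})

test_that("disruption is invariant under segment subdivision", {
  set.seed(11)
  segs <- random_profiles("S1")
  arms <- tiny_arms()
  base <- genomic_disruption(segs, arms)
  i <- which.max(segs$end - segs$start)
  mid <- round((segs$start[i] + segs$end[i]) / 2)
  split <- rbind(segs[-i, ],
                 transform(segs[i, ], end = mid),
                 transform(segs[i, ], start = mid))
  expect_equal(genomic_disruption(split, arms), base)
})

test_that("SCNA segment calls use a strict 0.2-copy threshold from the median", {
  arms <- tiny_arms()
  segs <- flat_profiles("S1", arms)
  expect_equal(nrow(call_scna_segments(segs)), 0L)
  segs$value <- c(2, 2, 2.21)
  calls <- call_scna_segments(segs)
  expect_equal(calls$direction, "GAIN")
  expect_equal(calls$magnitude, 0.21, tolerance = 1e-12)
  segs$value <- c(2, 2, 2.2)   # exactly at threshold: no call
  expect_equal(nrow(call_scna_segments(segs)), 0L)
  segs$value <- c(2, 2, 1.7)
  expect_equal(call_scna_segments(segs)$direction, "LOSS")
})

test_that("lowering purity shrinks uncorrected disruption while corrected stays put", {
  set.seed(3)
  arms <- tiny_arms()
  segs <- flat_profiles("S1", arms)
  segs$value <- c(2.3, 2, 1.7)   # low-amplitude gained and lost arms
  uncorr <- corr <- numeric(0)
  for (alpha in c(1, 0.8, 0.6, 0.4, 0.2)) {
    obs <- admix_profile(segs, alpha)
    pp <- data.frame(sample_id = "S1", alpha = alpha,
                     tau = attr(obs, "tau")[["S1"]], confident = TRUE)
    uncorr <- c(uncorr, genomic_disruption(obs, arms)$fraction)
    corr <- c(corr, genomic_disruption(isar_correct(obs, pp), arms)$fraction)
  }
  expect_true(all(diff(uncorr) <= 1e-12))
  expect_gt(uncorr[1], 0)
  expect_equal(uncorr[length(uncorr)], 0)  # admixture pushes deviations under 0.1
  expect_equal(corr, rep(corr[1], length(corr)))
  expect_equal(corr[1], 0.625)
})
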