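test_that("segment scope follows the half-arm cutoff with ties to ARM_LEVEL", {
  expect_equal(classify_segment_scope(100, 100), "ARM_LEVEL")
  expect_equal(classify_segment_scope(40, 100), "FOCAL")
  expect_equal(classify_segment_scope(50, 100), "ARM_LEVEL")  # exactly 0.5
  expect_equal(classify_segment_scope(c(10, 80), c(100, 100)),
               c("FOCAL", "ARM_LEVEL"))
  expect_error(classify_segment_scope(120, 100), "longer than its arm")
})

test_that("arm event calls use length-weighted arm medians against the sample median", {
  arms <- tiny_arms()
  segs <- flat_profiles("S1", arms)
  expect_true(all(call_arm_events(segs, arms)$call == "NEUTRAL"))
  segs$value <- c(2.6, 2, 2)   # whole-arm gain on 1p
  ac <- call_arm_events(segs, arms)
  expect_equal(ac$call[ac$arm == "1p"], "GAIN")
  expect_equal(ac$call[ac$arm != "1p"], rep("NEUTRAL", 2))
  # half the arm at median + 0.6, half at median: arm median = median + 0.3
  segs2 <- rbind(
    data.frame(sample = "S1", chrom = "1", start = c(0, 50e6), end = c(50e6, 100e6),
               n_markers = 50L, value = c(2.6, 2.0)),
    flat_profiles("S1", arms)[-1, ])
  ac2 <- call_arm_events(segs2, arms)
  expect_equal(ac2$arm_median[ac2$arm == "1p"], 2.3)
  expect_equal(ac2$call[ac2$arm == "1p"], "GAIN")
})

test_that("event matrix captures planted focal events and their scope", {
  arms <- tiny_arms()
  region <- data.frame(region_id = "r1", chrom = "1", start = 10e6, end = 15e6,
                       type = "DEL", stringsAsFactors = FALSE)
  segs <- flat_profiles(c("S1", "S2", "S3"), arms)
  # S1: focal deletion inside r1; S2: arm-level loss of 1p spanning r1; S3: flat
  s1 <- segs[segs$sample == "S1", ]
  s1 <- plant_focal_event(s1, region, -1, 0.6, arms)
  segs <- rbind(s1, segs[segs$sample != "S1", ])
  segs$value[segs$sample == "S2" & segs$chrom == "1" & segs$start == 0] <- 1.0
  em <- build_event_matrix(segs, arms, region)
  expect_true(em$matrix["S1", "r1:del"])
  expect_false(em$matrix["S2", "r1:del"])   # arm-level scope does not count as focal
  expect_true(em$matrix["S2", "1p:loss"])
  expect_false(any(em$matrix["S3", ]))
  expect_equal(unname(em$focal_count), c(1L, 0L, 0L))
})

test_that("event matrix is invariant to subdivision and sample order", {
  set.seed(5)
  arms <- tiny_arms()
  region <- data.frame(region_id = "r1", chrom = "2", start = 50e6, end = 60e6,
                       type = "AMP", stringsAsFactors = FALSE)
  segs <- flat_profiles(c("A", "B"), arms)
  segs <- rbind(plant_focal_event(segs[segs$sample == "A", ], region, 1, 0.8),
                segs[segs$sample == "B", ])
  em1 <- build_event_matrix(segs, arms, region)
  i <- which(segs$sample == "B" & segs$chrom == "1")[1]
  mid <- round((segs$start[i] + segs$end[i]) / 2)
  segs2 <- rbind(segs[-i, ], transform(segs[i, ], end = mid),
                 transform(segs[i, ], start = mid))
  segs2 <- segs2[order(match(segs2$sample, c("B", "A"))), ]
  em2 <- build_event_matrix(segs2, arms, region)
  expect_identical(em1$matrix, em2$matrix[rownames(em1$matrix), ])
})

test_that("duplicate region event ids are rejected", {
  arms <- tiny_arms()
  regions <- data.frame(region_id = c("r", "r"), chrom = "1",
                        start = c(1e6, 20e6), end = c(2e6, 21e6),
                        type = "AMP", stringsAsFactors = FALSE)
  expect_error(build_event_matrix(flat_profiles("S1", arms), arms, regions),
               "duplicate event ids")
})

test_that("planted events round-trip exactly through the calling pipeline", {
  # noiseless, fully pure cohort: realized event frequencies equal planted ones
  p <- simulation_params(n_east = 15, n_west = 15, marker_noise_sd = 0,
                         fixed_purity = 1, arm_rate_cin = 0, arm_rate_noncin = 0,
                         n_snps = 10, n_markers = 2000, seed = 99)
  sim <- simulate_cohort(p)
  arms <- autosomal_arms(sim$arms)
  em <- build_event_matrix(sim$profiles, arms, sim$regions)
  truth <- sim$truth$focal_events
  for (r in seq_len(nrow(sim$regions))) {
    id <- paste0(sim$regions$region_id[r], ":",
                 ifelse(sim$regions$type[r] == "AMP", "amp", "del"))
    expect_setequal(rownames(em$matrix)[em$matrix[, id]],
                    truth$sample_id[truth$region_id == sim$regions$region_id[r]])
  }
})

test_that("CIN samples accumulate more arm events than non-CIN samples", {
  p <- simulation_params(n_east = 25, n_west = 25, seed = 31, n_snps = 10,
                         n_markers = 2000, marker_noise_sd = 0, fixed_purity = 1)
  sim <- simulate_cohort(p)
  arms <- autosomal_arms(sim$arms)
  em <- build_event_matrix(sim$profiles, arms, NULL)
  counts <- rowSums(em$matrix)
  cin <- sim$truth$samples$cin[match(rownames(em$matrix),
                                     sim$truth$samples$sample_id)]
  expect_gt(mean(counts[cin]), mean(counts[!cin]))
})
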