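test_that("G-scores sum above-noise focal amplitudes across samples", {
  arms <- tiny_arms()
  grid <- marker_grid(arms, 500)
  ids <- sprintf("S%02d", 1:20)
  segs <- flat_profiles(ids, arms)
  expect_true(all(gscore_profiles(segs, arms, grid, "AMP")$scores == 0))
  region <- list(chrom = "1", start = 110e6, end = 130e6)
  carriers <- ids[1:10]
  planted <- do.call(rbind, lapply(split(segs, segs$sample), function(s)
    if (s$sample[1] %in% carriers) plant_focal_event(s, region, 1, 0.6) else s))
  gs <- gscore_profiles(planted, arms, grid, "AMP")
  inside <- grid$chrom == "1" & grid$pos >= 110e6 & grid$pos < 130e6
  # amplitude above the 0.1 noise floor: 10 samples x (0.6 - 0.1)
  expect_equal(unique(gs$scores[inside]), 5.0, tolerance = 1e-9)
  expect_true(all(gs$scores[!inside] == 0))
  # deletions do not contribute to the AMP direction
  expect_true(all(gscore_profiles(planted, arms, grid, "DEL")$scores == 0))
})

test_that("arm-level-only cohorts give zero focal scores", {
  arms <- tiny_arms()
  grid <- marker_grid(arms, 300)
  segs <- flat_profiles(c("A", "B"), arms)
  segs$value[segs$sample == "A" & segs$chrom == "1" & segs$start == 0] <- 3
  gs <- gscore_profiles(segs, arms, grid, "AMP")
  expect_true(all(gs$scores == 0))
})

test_that("zero scores give q = 1 and identical seeds identical q-values", {
  arms <- tiny_arms()
  grid <- marker_grid(arms, 200)
  segs <- flat_profiles(c("A", "B"), arms)
  gs <- gscore_profiles(segs, arms, grid, "AMP")
  q <- significance_by_permutation(gs, 200, seed = 1)
  expect_true(all(q == 1))
  region <- list(chrom = "2", start = 60e6, end = 80e6)
  planted <- rbind(plant_focal_event(segs[segs$sample == "A", ], region, 1, 0.9),
                   segs[segs$sample == "B", ])
  gs2 <- gscore_profiles(planted, arms, grid, "AMP")
  q1 <- significance_by_permutation(gs2, 300, seed = 42)
  q2 <- significance_by_permutation(gs2, 300, seed = 42)
  expect_identical(as.numeric(q1), as.numeric(q2))
})

test_that("a strongly recurrent planted region reaches q < 0.05", {
  arms <- tiny_arms()
  grid <- marker_grid(arms, 1000)
  ids <- sprintf("S%02d", 1:40)
  segs <- flat_profiles(ids, arms)
  region <- list(chrom = "1", start = 120e6, end = 135e6)
  segs <- do.call(rbind, lapply(split(segs, segs$sample), function(s)
    if (match(s$sample[1], ids) <= 20) plant_focal_event(s, region, 1, 0.8) else s))
  gs <- gscore_profiles(segs, arms, grid, "AMP")
  q <- significance_by_permutation(gs, 1000, seed = 3)
  inside <- grid$chrom == "1" & grid$pos >= 120e6 & grid$pos < 135e6
  expect_true(all(q[inside] < 0.05))
  regions <- extract_regions(q, grid, "AMP")
  expect_equal(nrow(regions), 1L)
  step <- attr(grid, "step")
  expect_lt(abs(regions$start - 120e6), 2 * step)
  expect_lt(abs(regions$end - 135e6), 2 * step)
})

test_that("G-scores are additive over disjoint sample subsets", {
  set.seed(12)
  arms <- tiny_arms()
  grid <- marker_grid(arms, 300)
  segs <- random_profiles(sprintf("S%d", 1:6), arms)
  all_s <- gscore_profiles(segs, arms, grid, "DEL")$scores
  half1 <- gscore_profiles(segs[segs$sample %in% c("S1", "S2", "S3"), ],
                           arms, grid, "DEL")$scores
  half2 <- gscore_profiles(segs[segs$sample %in% c("S4", "S5", "S6"), ],
                           arms, grid, "DEL")$scores
  expect_equal(all_s, half1 + half2, tolerance = 1e-12)
})

test_that("region extraction reports min-q sub-segments and splits runs", {
  arms <- tiny_arms()
  grid <- marker_grid(arms, 100)
  q <- rep(1, nrow(grid))
  expect_equal(nrow(extract_regions(q, grid, "AMP")), 0L)
  # two runs separated by one non-significant marker
  q[10:14] <- 0.01; q[12] <- 0.001
  q[16:18] <- 0.02
  regs <- extract_regions(q, grid, "DEL")
  expect_equal(nrow(regs), 2L)
  expect_equal(regs$qvalue, c(0.001, 0.02))
  # first region's reported interval is its unique minimum marker
  step <- attr(grid, "step")
  expect_equal(regs$start[1], grid$pos[12] - step / 2)
  expect_equal(regs$end[1], grid$pos[12] + step / 2)
  expect_equal(regs$run_start[1], grid$pos[10] - step / 2)
})

test_that("gene association uses overlap, then nearest, with tie flagging", {
  genes <- data.frame(chrom = "1", start = c(100, 5000, 9000),
                      end = c(200, 6000, 9500),
                      name = c("A", "B", "C"), stringsAsFactors = FALSE)
  expect_identical(as.character(associate_genes(
    list(chrom = "1", start = 150, end = 180), genes)), "A")
  hit <- associate_genes(list(chrom = "1", start = 7000, end = 7500), genes)
  expect_identical(as.character(hit), "B")   # 1000 bp away vs 1500 bp
  tie <- associate_genes(list(chrom = "1", start = 7000, end = 8000), genes)
  expect_setequal(as.character(tie), c("B", "C"))
  expect_true(attr(tie, "ambiguous"))
  expect_warning(none <- associate_genes(list(chrom = "1", start = 1, end = 2),
                                         genes[0, ]), "empty")
  expect_length(none, 0)
})
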