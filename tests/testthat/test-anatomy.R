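ont <- load_ontology()

test_that("the bundled ontology is a valid rooted tree", {
  expect_s3_class(ont, "region_ontology")
  expect_identical(sum(is.na(ont$parent_id)), 1L)
})

test_that("hierarchy aggregation conserves counts and reports rejects", {
  cells <- data.frame(
    acronym = c("VISp", "VISpm", "VISam", "SUB", "AD", "NOPE"),
    target = c("anterior", "anterior", "posterior", "posterior",
               "anterior", "anterior"))
  agg <- aggregate_counts(cells, ont, level = c("VIS", "HPF", "ATN"))
  expect_identical(sum(agg$counts$count), 5L)      # one unresolvable reject
  expect_identical(agg$rejects$acronym, "NOPE")
  vis_ant <- agg$counts$count[agg$counts$region == "VIS" &
                              agg$counts$target == "anterior"]
  expect_identical(vis_ant, 2L)
  # conservation across levels: leaf-level total equals group-level total
  agg2 <- aggregate_counts(cells, ont, level = c("Isocortex", "HPF", "TH"))
  expect_identical(sum(agg2$counts$count), sum(agg$counts$count))
  empty <- aggregate_counts(cells[0, ], ont, level = "VIS")
  expect_true(all(empty$counts$count == 0))
})

test_that("input fractions normalize per target", {
  cnt <- data.frame(region = c("A", "B", "A", "B"),
                    target = c("anterior", "anterior", "posterior", "posterior"),
                    count = c(300, 700, 50, 50))
  fr <- input_fractions(cnt)
  expect_equal(fr$fraction, c(0.3, 0.7, 0.5, 0.5))
  expect_error(input_fractions(data.frame(region = "A", target = "x",
                                          count = 0)), "zero")
})

test_that("volume density divides counts by aggregated leaf volumes", {
  cnt <- data.frame(region = c("RSPd", "VIS"), target = "anterior",
                    count = c(100, 190))
  vd <- volume_density(cnt, ont)
  expect_equal(vd$density_per_mm3[1], 100 / 2.2)
  vis_leaf_vol <- sum(ont$volume_mm3[ont$group == "VIS" &
                                     !is.na(ont$volume_mm3)])
  expect_equal(vd$volume_mm3[2], vis_leaf_vol)     # sum of leaf volumes
  expect_equal(volume_density(data.frame(region = "VISp", target = "a",
                                         count = 0), ont)$density_per_mm3, 0)
})

test_that("within-group fractions sum to 1 per target", {
  cnt <- data.frame(region = rep(c("VISp", "VISpm", "VISam", "VISa"), 2),
                    target = rep(c("anterior", "posterior"), each = 4),
                    count = c(10, 10, 10, 10, 5, 0, 0, 15))
  gf <- group_fractions(cnt, ont, "VIS")
  expect_equal(gf$group_fraction[gf$target == "anterior"], rep(0.25, 4))
  expect_equal(sum(gf$group_fraction[gf$target == "posterior"]), 1)
  solo <- group_fractions(data.frame(region = "VISp", target = "anterior",
                                     count = 7), ont, "VIS")
  expect_equal(solo$group_fraction, 1)
})

test_that("bias index follows the log2 ratio and is antisymmetric", {
  expect_equal(bias_index(0.25, 0.25), 0)
  expect_equal(bias_index(0.4, 0.1), 2)
  f1 <- runif(10); f2 <- runif(10)
  expect_equal(bias_index(f1, f2), -bias_index(f2, f1), tolerance = 1e-12)
  expect_true(is.na(bias_index(0, 0)))
})

test_that("bias-index table applies the pseudocount only when zeros occur", {
  cnt <- data.frame(region = rep(c("A", "B"), 2),
                    target = rep(c("anterior", "posterior"), each = 2),
                    count = c(400, 600, 100, 900))
  bt <- bias_index_table(cnt)
  expect_equal(bt$bias_index, log2(c(0.1 / 0.4, 0.9 / 0.6)), tolerance = 1e-12)
  cnt0 <- cnt; cnt0$count[1] <- 0
  bt0 <- bias_index_table(cnt0)
  expect_true(all(is.finite(bt0$bias_index)))
  expect_identical(bt0$count_anterior, c(0, 600))  # raw counts still reported
})

test_that("DV profiles compare targets with a KS statistic", {
  cells <- data.frame(acronym = "SUB",
                      target = rep(c("anterior", "posterior"), each = 50),
                      dv_mm = c(rnorm(50, 2), rnorm(50, 2)))
  cells$dv_mm[51:100] <- cells$dv_mm[1:50]         # identical sets
  dp <- dv_profile(cells, region = "SUB", ontology = ont)
  expect_equal(dp$ks$D, 0)
  cells2 <- cells
  cells2$dv_mm[51:100] <- cells2$dv_mm[1:50] + 100  # disjoint supports
  expect_equal(dv_profile(cells2)$ks$D, 1)
  # brute-force sup-difference oracle on shifted Gaussians
  set.seed(43)
  x <- rnorm(60, 2, 0.3); y <- rnorm(45, 2.4, 0.3)
  cells3 <- data.frame(acronym = "SUB",
                       target = rep(c("anterior", "posterior"), c(60, 45)),
                       dv_mm = c(x, y))
  grid <- sort(c(x, y))
  d_oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(dv_profile(cells3)$ks$D, d_oracle, tolerance = 1e-12)
})

test_that("injection density is scale-invariant with a percentile level", {
  set.seed(51)
  img <- matrix(0.1, 40, 40)
  xy <- expand.grid(1:40, 1:40)
  img[] <- img + 2 * exp(-((xy[[1]] - 20)^2 + (xy[[2]] - 20)^2) / 50)
  d1 <- injection_density(img)
  d10 <- injection_density(10 * img)
  expect_equal(d1$image_norm, d10$image_norm, tolerance = 1e-9)
  expect_equal(d1$level, quantile(d1$image_norm, 0.9, names = FALSE))
  # the 90th-percentile contour encloses the bright disc center
  expect_true(d1$contour_mask[20, 20])
  expect_false(d1$contour_mask[1, 1])
  flat <- injection_density(matrix(1, 5, 5))
  expect_true(flat$degenerate && is.na(flat$level))
})
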