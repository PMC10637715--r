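test_that("separated point masses split into their own clusters", {
  ir <- idx_raster(matrix(c(0, 0, 0, 1, 1, 1) / 10, 2, 3))
  cm <- isodata_classify(ir, tiny_iso(2))
  expect_equal(cm$means, c(0, 0.1))
  expect_equal(cm$sizes, c(3L, 3L))
  expect_true(cm$converged)
})

test_that("a constant raster degenerates to a single flagged cluster", {
  ir <- idx_raster(matrix(0.42, 5, 5))
  expect_warning(cm <- isodata_classify(ir, iso_params(k = 5)), "1 cluster")
  expect_equal(length(cm$means), 1)
  expect_true(cm$degenerate)
  expect_equal(cm$sizes, 25L)
})

test_that("final partitions match the exhaustive-enumeration optimum", {
  for (inst in clustering_instances()) {
    ir <- idx_raster(matrix(inst$x / max(abs(inst$x)), nrow = 1))
    cm <- isodata_classify(ir, tiny_iso(inst$k))
    wss_fit <- cluster_wss(cm, ir$values)
    wss_opt <- exhaustive_wss(as.vector(ir$values), inst$k)
    if (inst$separated) {
      expect_equal(wss_fit, wss_opt, tolerance = 1e-9)
    } else {
      expect_lte(wss_fit, wss_opt * 1.05 + 1e-12)
    }
  }
})

test_that("within-cluster sum of squares never increases across iterations", {
  set.seed(5)
  for (rep in 1:4) {
    ir <- idx_raster(matrix(runif(400, -1, 1), 20, 20))
    cm <- isodata_classify(ir, iso_params(k = 4, min_cluster_size = 1))
    expect_true(all(diff(cm$wss_trace) <= 1e-9))
  }
})

test_that("classification is deterministic and labels are sorted by mean", {
  set.seed(8)
  ir <- idx_raster(matrix(c(rnorm(300, -0.7, 0.05), rnorm(300, -0.3, 0.05),
                            rnorm(300, 0.3, 0.05)), 30, 30))
  a <- isodata_classify(ir, iso_params(k = 3))
  b <- isodata_classify(ir, iso_params(k = 3))
  expect_identical(a$labels, b$labels)
  expect_identical(a$means, b$means)
  expect_equal(a$means, sort(a$means))
  # recorded means equal the member means
  for (kk in seq_along(a$means)) {
    expect_equal(a$means[kk], mean(ir$values[!is.na(a$labels) & a$labels == kk]),
                 tolerance = 1e-9)
  }
  expect_equal(sum(a$sizes), sum(!ir$mask))
})

test_that("nodata pixels are excluded and never labelled", {
  vals <- matrix(runif(100, -1, 1), 10, 10)
  msk <- matrix(FALSE, 10, 10); msk[1, ] <- TRUE
  ir <- index_raster(vals, 1, mask = msk)
  cm <- isodata_classify(ir, iso_params(k = 3, min_cluster_size = 1))
  expect_true(all(is.na(cm$labels[1, ])))
  expect_equal(sum(cm$sizes), 90)
})

test_that("undersized clusters are merged into their nearest neighbour", {
  x <- c(rep(0, 50), rep(0.5, 3), rep(1, 50))
  ir <- idx_raster(matrix(x, nrow = 1))
  expect_warning(
    cm <- isodata_classify(ir, iso_params(k = 3, min_cluster_size = 20)),
    "merged")
  expect_equal(length(cm$means), 2)
  expect_true(all(cm$sizes >= 20))
})

test_that("cluster means map to classes on the field thresholds", {
  mk <- function(means) {
    structure(list(labels = matrix(seq_along(means), 1), means = means,
                   sizes = rep(1L, length(means)), iterations = 1L,
                   converged = TRUE, degenerate = FALSE, wss = 0,
                   wss_trace = 0, resolution = 1, origin = c(0, 1),
                   crs = "t"), class = "cluster_map")
  }
  cm <- assign_classes(mk(c(-0.70, -0.30, 0.00, 0.30)))
  expect_equal(cm$cluster_table$class,
               c("soil", "vegetation", "unclassified", "flower"))
  # boundary ownership: -0.45 is vegetation (closed), -0.15 vegetation,
  # 0.12 still in the gap, just above 0.12 flower
  cm2 <- assign_classes(mk(c(-0.45, -0.15, 0.12, 0.1200001)))
  expect_equal(cm2$cluster_table$class,
               c("vegetation", "vegetation", "unclassified", "flower"))
  # nearest-range gap policy splits the gap instead
  cm3 <- assign_classes(mk(c(-0.10, 0.10)),
                        class_thresholds(gap_policy = "nearest"))
  expect_equal(cm3$cluster_table$class, c("vegetation", "flower"))
})

test_that("class pixel counts are exact and unknown labels rejected", {
  vals <- matrix(c(rep(-0.7, 20), rep(-0.3, 6), rep(0.3, 37), rep(0.25, 1)),
                 nrow = 4)
  ir <- idx_raster(vals)
  cm <- assign_classes(isodata_classify(ir, tiny_iso(3)))
  expect_equal(count_class_pixels(cm, "flower"), 38)
  expect_equal(count_class_pixels(cm, "soil"), 20)
  expect_equal(count_class_pixels(cm, "vegetation"), 6)
  expect_equal(sum(cm$class_counts), sum(!ir$mask))
  expect_error(count_class_pixels(cm, "water"), "unknown")
  all_soil <- assign_classes(isodata_classify(
    idx_raster(matrix(c(rep(-0.8, 10), rep(-0.6, 10)), 2)), tiny_iso(2)))
  expect_equal(count_class_pixels(all_soil, "flower"), 0)
})

test_that("tidy and glance expose cluster structure", {
  ir <- idx_raster(matrix(c(rep(-0.5, 10), rep(0.5, 10)), 2))
  cm <- isodata_classify(ir, tiny_iso(2))
  td <- tidy(cm)
  expect_equal(td$size, c(10L, 10L))
  gl <- glance(cm)
  expect_true(gl$converged)
  expect_equal(gl$k, 2)
})
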