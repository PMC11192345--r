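test_that("landscape_spec validates class composition", {
  expect_error(
    landscape_spec(10, 10,
                   classes = data.frame(code = 1:2, name = c("a", "b"),
                                        proportion = c(0.6, 0.5)),
                   ndvi_targets = NULL),
    "sum to 1.*1\\.1", ignore.case = TRUE)
  expect_error(
    landscape_spec(10, 10,
                   classes = data.frame(code = c(1, 1), name = c("a", "b"),
                                        proportion = c(0.5, 0.5)),
                   ndvi_targets = NULL),
    "unique")
  expect_s3_class(two_class_spec(), "landscape_spec")
})

test_that("a one-class spec yields a constant raster with proportion 1", {
  spec <- landscape_spec(20, 30,
                         classes = data.frame(code = 5L, name = "only",
                                              proportion = 1),
                         ndvi_targets = NULL, seed = 11)
  r <- generate_landcover(spec)
  expect_true(all(r$grid == 5L))
  expect_equal(unname(class_proportions(class_areas(r))), 1)
})

test_that("generated landcover is seed-deterministic and seed-sensitive", {
  spec <- two_class_spec(100, seed = 21)
  r1 <- generate_landcover(spec)
  r2 <- generate_landcover(spec)
  expect_identical(r1$grid, r2$grid)
  spec_b <- two_class_spec(100, seed = 22)
  r3 <- generate_landcover(spec_b)
  expect_false(identical(r1$grid, r3$grid))
  # both realizations stay within 3 binomial SE of 0.5 (SE = sqrt(0.25/1e4))
  se <- sqrt(0.25 / 1e4)
  for (r in list(r1, r3)) {
    p <- class_proportions(class_areas(r))
    expect_lt(abs(p[["1"]] - 0.5), 3 * se)
  }
})

test_that("realized proportions recover the eight-class composition on a large grid", {
  spec <- landscape_spec(1000, 1000, seed = 7)
  r <- generate_landcover(spec)
  p <- class_proportions(class_areas(r))
  targets <- spec$classes$proportion
  n <- 1000 * 1000
  for (i in seq_along(targets)) {
    se <- sqrt(targets[i] * (1 - targets[i]) / n)
    expect_lt(abs(p[[as.character(spec$classes$code[i])]] - targets[i]), 3 * se)
  }
})

test_that("patchy generation preserves expected proportions and adds spatial structure", {
  spec <- two_class_spec(80, seed = 5, props = c(0.7, 0.3))
  # expected proportions unbiased: average realized share over repeated seeds
  shares <- vapply(1:40, function(s) {
    sp <- two_class_spec(40, seed = s, props = c(0.7, 0.3))
    class_proportions(class_areas(generate_landcover(sp, patch_size = 25)))[["1"]]
  }, numeric(1))
  # each draw has ~64 effective patches: SE of the mean share over 40 seeds
  se <- sqrt(0.7 * 0.3 / 64) / sqrt(40)
  expect_lt(abs(mean(shares) - 0.7), 4 * se)
  # patches make neighbours agree more often than i.i.d. cells do
  agree_frac <- function(g) mean(g[-1, ] == g[-nrow(g), ])
  r_iid <- generate_landcover(spec)
  r_patch <- generate_landcover(spec, patch_size = 25)
  expect_gt(agree_frac(r_patch$grid), agree_frac(r_iid$grid))
  expect_true(all(r_patch$grid %in% 1:2))
  # still seed-deterministic
  expect_identical(generate_landcover(spec, patch_size = 25)$grid, r_patch$grid)
})

test_that("band pair reproduces per-class NDVI targets", {
  one_class <- function(mean, sd, n = 200, seed = 3) {
    spec <- landscape_spec(n, n,
                           classes = data.frame(code = 1L, name = "c",
                                                proportion = 1),
                           ndvi_targets = data.frame(code = 1L, mean = mean,
                                                     sd = sd),
                           seed = seed)
    r <- generate_landcover(spec)
    b <- generate_band_pair(r, spec)
    list(raster = r, bands = b,
         stats = ndvi_class_stats(compute_ndvi(b$nir, b$red), r))
  }
  # zero target, zero spread: NIR equals red, NDVI identically 0
  z <- one_class(0, 0, n = 20)
  expect_equal(z$bands$nir$grid, z$bands$red$grid)
  expect_equal(z$stats$mean, 0)
  # published class means recovered within 0.02 on 40k pixels
  for (target in c(0.83, 0.53)) {
    s <- one_class(target, 0.02)
    expect_lt(abs(s$stats$mean - target), 0.02)
  }
  # bands strictly positive, NDVI strictly inside (-1, 1)
  s <- one_class(0.79, 0.3, n = 100)
  expect_true(all(s$bands$nir$grid > 0))
  expect_true(all(s$bands$red$grid > 0))
  nd <- compute_ndvi(s$bands$nir, s$bands$red)
  expect_true(all(nd > -1 & nd < 1))
})

test_that("band generation requires a target for every class present", {
  spec <- two_class_spec(30, seed = 2)
  spec$ndvi_targets <- data.frame(code = 1L, mean = 0.5, sd = 0.01)
  r <- generate_landcover(spec)
  expect_error(generate_band_pair(r, spec), "missing from ndvi_targets")
})

test_that("reference points follow the prescribed confusion structure", {
  spec <- two_class_spec(200, seed = 13)
  r <- generate_landcover(spec)
  cs <- confusion_spec(1:2, matrix(c(0.8, 0.3, 0.2, 0.7), 2),
                       points_per_class = 1000)
  pts <- generate_reference_points(r, cs, seed = 4)
  expect_equal(nrow(pts), 2000)
  expect_equal(unname(table(pts$true_class)), c(1000L, 1000L),
               ignore_attr = TRUE)
  # empirical label rates within 3 binomial SE of each confusion row
  for (i in 1:2) {
    sub <- pts[pts$true_class == i, ]
    for (j in 1:2) {
      p <- cs$confusion[i, j]
      phat <- mean(sub$mapped_class == j)
      expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 1000))
    }
  }
  # identity confusion: mapped equals true everywhere
  pts_id <- generate_reference_points(r, confusion_spec(1:2), seed = 4)
  expect_true(all(pts_id$mapped_class == pts_id$true_class))
  expect_equal(sum(pts_id$true_class == 1), 100)
  # recorded coordinates point at cells of the true class
  idx <- cbind(pts_id$row, pts_id$col)
  expect_true(all(r$grid[idx] == pts_id$true_class))
})

test_that("reference sampling errors when a class is too scarce", {
  spec <- two_class_spec(20, seed = 1, props = c(0.99, 0.01))
  r <- generate_landcover(spec)
  cs <- confusion_spec(1:2, points_per_class = 300)
  expect_error(generate_reference_points(r, cs, seed = 1), "class 2")
})

test_that("reference points survive a CSV round trip", {
  spec <- two_class_spec(50, seed = 8)
  r <- generate_landcover(spec)
  pts <- generate_reference_points(r, confusion_spec(1:2, points_per_class = 10),
                                   seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_points(pts, path)
  expect_equal(read_reference_points(path), pts)
})
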