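test_that("region masks conserve pixel counts and component filters work", {
  set.seed(1)
  labels <- matrix(sample(1:3, 400, TRUE), 20, 20)
  attr(labels, "n_regions") <- 3L
  for (id in 1:3) {
    expect_equal(sum(extract_region_mask(labels, id)), sum(labels == id))
  }
  expect_error(extract_region_mask(labels, 4), "region_id")
  # absent region -> empty mask
  lab2 <- matrix(1L, 10, 10); attr(lab2, "n_regions") <- 2L
  expect_equal(sum(extract_region_mask(lab2, 2)), 0)
  # top-1 component keeps only the larger lobe
  two <- matrix(1L, 12, 24)
  two[2:4, 2:6] <- 2L      # 15 px lobe
  two[7:11, 10:21] <- 2L   # 60 px lobe
  attr(two, "n_regions") <- 2L
  m1 <- extract_region_mask(two, 2, top_k = 1)
  expect_equal(sum(m1), 60)
  expect_equal(sum(extract_region_mask(two, 2, top_k = 2)), 75)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch: one component
  comp <- kapurseg:::label_components(m)
  expect_equal(max(comp), 1)
  m[5, 5] <- TRUE                   # separated
  expect_equal(max(kapurseg:::label_components(m)), 2)
})

test_that("area is the set-pixel count", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  expect_equal(region_area(sq), 100)
  expect_equal(region_area(matrix(FALSE, 5, 5)), 0)
})

test_that("Sobel perimeter matches a hand count on a point and the
           double-loop oracle on shapes", {
  pt <- matrix(FALSE, 9, 9); pt[5, 5] <- TRUE
  # an isolated pixel excites all 8 neighbours but not itself
  expect_equal(region_perimeter_sobel(pt), 8)
  expect_equal(region_perimeter_sobel(matrix(FALSE, 8, 8)), 0)
  shapes <- list(
    square = {m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE; m},
    bar    = {m <- matrix(FALSE, 9, 30); m[4:6, 3:28] <- TRUE; m},
    blob   = {set.seed(2); m <- matrix(FALSE, 15, 15)
              m[4:12, 4:12] <- matrix(runif(81) < 0.7, 9, 9); m})
  for (m in shapes) {
    expect_equal(region_perimeter_sobel(m), oracle_sobel_count(m))
  }
})

test_that("skeletons match the textbook thinning oracle and are thin
           subsets of the mask", {
  bar <- matrix(FALSE, 7, 25); bar[3:5, 3:23] <- TRUE
  sk <- skeletonize(bar)
  ork <- oracle_thin(bar)
  expect_identical(sk, ork)
  expect_true(all(!sk | bar))
  expect_equal(region_skeleton_length(bar), sum(ork))
  # a bar thins to a single-pixel-wide line
  expect_lte(max(rowSums(sk)), ncol(bar))
  expect_true(all(colSums(sk) <= 1 | colSums(sk) == 0))
  ring <- matrix(FALSE, 21, 21)
  d2 <- (row(ring) - 11)^2 + (col(ring) - 11)^2
  ring[d2 >= 25 & d2 <= 64] <- TRUE
  expect_identical(skeletonize(ring), oracle_thin(ring))
  expect_equal(region_skeleton_length(matrix(FALSE, 5, 5)), 0L)
  # geodesic length counts diagonal links as sqrt(2)
  diagm <- matrix(FALSE, 10, 10); diagm[cbind(2:8, 2:8)] <- TRUE
  expect_equal(region_skeleton_length(diagm, "geodesic"),
               7 + (sqrt(2) - 1) * 6)
})

test_that("perimeter and skeleton are translation invariant away from
           the border", {
  m <- matrix(FALSE, 30, 30); m[5:12, 6:17] <- TRUE
  m2 <- matrix(FALSE, 30, 30); m2[15:22, 10:21] <- TRUE
  expect_equal(region_perimeter_sobel(m), region_perimeter_sobel(m2))
  expect_equal(region_skeleton_length(m), region_skeleton_length(m2))
})

test_that("percentage differences use the gold denominator", {
  auto <- list(area_px = 104.12, perimeter_px = 50, skeleton_px = 10)
  gold <- list(area_px = 100, perimeter_px = 50, skeleton_px = 8)
  pct <- feature_difference_pct(auto, gold)
  expect_equal(unname(pct["area_px"]), 4.12)
  expect_equal(unname(pct["perimeter_px"]), 0)
  expect_equal(unname(pct["skeleton_px"]), 25)
  expect_equal(unname(feature_difference_pct(gold, gold)), rep(0, 3))
  expect_error(feature_difference_pct(auto, list(area_px = 0,
                                                 perimeter_px = 1,
                                                 skeleton_px = 1)),
               "positive")
})

test_that("features recover phantom ribbon truth on a noiseless phantom", {
  ph <- generate_phantom(256, 256, 4, texture_sd = 0, seed = 1)
  fit <- mlseg(ph$image, "otsu", 4)
  mask <- extract_region_mask(fit$labels, 3)
  fs <- region_features(mask)
  tr <- ph$truth
  expect_lt(abs(fs$area_px - tr$true_area) / tr$true_area, 0.03)
  expect_lt(abs(fs$perimeter_px - tr$true_perimeter) / tr$true_perimeter, 0.1)
  expect_lt(abs(fs$skeleton_px - tr$true_skeleton_length) /
              tr$true_skeleton_length, 0.1)
})
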