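test_that("histograms count intensities and normalize", {
  img <- matrix(7L, 10, 10)
  h <- compute_histogram(img)
  expect_equal(h$counts[8], 100)
  expect_equal(h$probs[8], 1)
  img2 <- matrix(c(rep(0L, 50), rep(255L, 50)), 10, 10)
  h2 <- compute_histogram(img2)
  expect_equal(h2$probs[c(1, 256)], c(0.5, 0.5))
  set.seed(1)
  img3 <- matrix(sample(0:255, 400, TRUE), 20, 20)
  expect_equal(sum(compute_histogram(img3)$probs), 1, tolerance = 1e-12)
})

test_that("hard thresholds partition with upper-exclusive intervals", {
  img <- matrix(c(0L, 255L), 8, 8)
  lab <- apply_hard_thresholds(img, 128)
  expect_setequal(unique(as.vector(lab)), c(1L, 2L))
  # intensity exactly at the threshold belongs to the upper region
  expect_equal(apply_hard_thresholds(matrix(128L, 8, 8), 128)[1, 1], 2L)
  ramp <- ramp_image()
  lab4 <- apply_hard_thresholds(ramp, c(64, 128, 192))
  expect_equal(unname(tabulate(lab4, 4)), rep(64 * 8, 4))
  # partition: every pixel gets exactly one label
  expect_equal(sum(tabulate(lab4, 4)), length(ramp))
})

test_that("kapur entropy matches closed forms and the direct-sum oracle", {
  h4 <- histogram_from_counts(c(rep(25, 4), rep(0, 252)))
  expect_equal(kapur_entropy(h4, 2), 2 * log(2), tolerance = 1e-12)
  expect_equal(kapur_entropy(histogram_from_counts(c(100, rep(0, 255))), 128), 0)
  hu <- histogram_from_counts(rep(1, 256))
  expect_equal(kapur_entropy(hu, 128), 2 * log(128), tolerance = 1e-9)
  # image-size invariance: depends only on probs
  expect_equal(kapur_entropy(histogram_from_counts(rep(7, 256)), 128),
               kapur_entropy(hu, 128))
  # ln(256) upper bound and agreement with the independent oracle
  for (s in 1:10) {
    h <- random_histogram(s, n_active = 40)
    tv <- sort(sample(1:255, 3))
    expect_equal(kapur_entropy(h, tv), oracle_kapur(h$probs, tv),
                 tolerance = 1e-12)
    # each region's entropy is at most the log of its bin width
    widths <- diff(c(0, tv, 256))
    expect_lte(kapur_entropy(h, tv), sum(log(widths)))
  }
})

test_that("exhaustive search finds the enumerated global optimum", {
  hu <- histogram_from_counts(rep(1, 256))
  es <- exhaustive_search(hu, 1, "kapur")
  expect_equal(es$thresholds, 128L)
  expect_equal(es$fitness, 2 * log(128), tolerance = 1e-9)

  hd <- histogram_from_counts(c(50, rep(0, 254), 50))
  es2 <- exhaustive_search(hd, 1, "between_class_variance")
  expect_equal(es2$thresholds, 1L)  # tie broken to the smallest T
  expect_equal(es2$fitness, 0.25 * 255^2)

  # n = 0 degenerates to the whole-histogram entropy
  h <- random_histogram(3, 30)
  es0 <- exhaustive_search(h, 0, "kapur")
  expect_equal(es0$thresholds, integer(0))
  expect_equal(es0$fitness, oracle_kapur(h$probs, integer(0)))

  # guard: many thresholds on a dense histogram are refused
  expect_error(exhaustive_search(hu, 4, "kapur"), "refused")

  # cross-check against naive enumeration on a tiny histogram
  ht <- histogram_from_counts({x <- rep(0, 256); x[c(3, 60, 130, 220)] <- c(10, 30, 25, 35); x})
  naive_best <- -Inf; naive_tv <- NULL
  for (a in 1:254) for (b in (a + 1):255) {
    f <- oracle_kapur(ht$probs, c(a, b))
    if (f > naive_best + 1e-12) { naive_best <- f; naive_tv <- c(a, b) }
  }
  es3 <- exhaustive_search(ht, 2, "kapur")
  expect_equal(es3$fitness, naive_best, tolerance = 1e-12)
  expect_equal(es3$thresholds, naive_tv)
})

test_that("multi-Otsu implements the equal-area scheme", {
  hd <- histogram_from_counts(c(50, rep(0, 254), 50))
  expect_equal(multi_otsu(hd, 1), 1L)
  # n = 1 is classic full-range Otsu: agrees with the textbook oracle
  for (s in 1:8) {
    h <- random_histogram(s, 50)
    expect_equal(multi_otsu(h, 1),
                 oracle_otsu1(h$probs)$threshold)
    expect_equal(multi_otsu(h, 1),
                 exhaustive_search(h, 1, "between_class_variance")$thresholds)
  }
  # 4 areas of width 64: each threshold stays inside its own area
  h <- random_histogram(2, 64)
  tv <- multi_otsu(h, 4)
  expect_equal(length(tv), 4)
  for (i in 1:4) expect_true(tv[i] > (i - 1) * 64 && tv[i] <= i * 64)
  # an empty area falls back to its midpoint
  hlow <- histogram_from_counts(c(rep(10, 32), rep(0, 224)))
  tv2 <- multi_otsu(hlow, 2)
  expect_equal(tv2[2], round((128 + 255) / 2))
})

test_that("merging two adjacent regions changes the entropy sum by at most
           the mixture entropy of their weights", {
  binary_entropy <- function(wa, wb) {
    w <- wa + wb
    if (wa == 0 || wb == 0) return(0)
    -(wa / w) * log(wa / w) - (wb / w) * log(wb / w)
  }
  for (s in 1:10) {
    set.seed(s)
    counts <- rep(0, 256)
    counts[sample(0:15, 16) + 1] <- rpois(16, 20) + 1
    h <- histogram_from_counts(counts)
    tv <- sort(sample(1:15, 3))
    full <- kapur_entropy(h, tv)
    bounds <- c(0, tv, 256)
    wreg <- vapply(seq_len(4), function(l)
      sum(h$probs[(bounds[l] + 1):bounds[l + 1]]), 0)
    for (drop in seq_along(tv)) {
      merged <- kapur_entropy(h, tv[-drop])
      # merging regions `drop` and `drop + 1`
      expect_lte(merged - full,
                 binary_entropy(wreg[drop], wreg[drop + 1]) + 1e-9)
      expect_gte(merged - full, -(full + 1e-9))  # cannot go below zero total
    }
  }
})
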