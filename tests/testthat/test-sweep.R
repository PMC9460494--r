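make_small_phantoms <- function(n = 2, size = 48) {
  imgs <- lapply(seq_len(n), function(i)
    generate_phantom(size, size, 4, texture_sd = 6, seed = 100 + i)$image)
  names(imgs) <- paste0("ph", seq_len(n))
  imgs
}

test_that("a sweep emits one record per image x method x kind x level", {
  imgs <- make_small_phantoms(1)
  recs <- run_robustness_sweep(imgs, methods = c("otsu", "kmeans"),
                               noise_kinds = "salt_pepper",
                               master_seed = 1)
  expect_equal(nrow(recs), 2 * 20)
  expect_setequal(unique(recs$method), c("otsu", "kmeans"))
  expect_setequal(unique(recs$level_index), 1:20)
  expect_true(all(c("ssim", "mse", "corr", "snr_db") %in% names(recs)))

  withnative <- run_robustness_sweep(imgs, methods = "otsu",
                                     noise_kinds = "salt_pepper",
                                     master_seed = 1, include_native = TRUE)
  lvl0 <- withnative[withnative$level_index == 0, ]
  expect_equal(nrow(lvl0), 1)
  expect_equal(lvl0$ssim, 1)
  expect_equal(lvl0$mse, 0)
})

test_that("sweeps are bit-reproducible for a fixed master seed", {
  imgs <- make_small_phantoms(1)
  a <- run_robustness_sweep(imgs, methods = c("otsu", "pso"),
                            noise_kinds = "gaussian", levels = c(1, 10, 20),
                            master_seed = 5,
                            control = optimizer_control(iterations = 15,
                                                        population = 10))
  b <- run_robustness_sweep(imgs, methods = c("otsu", "pso"),
                            noise_kinds = "gaussian", levels = c(1, 10, 20),
                            master_seed = 5,
                            control = optimizer_control(iterations = 15,
                                                        population = 10))
  expect_identical(a, b)
})

test_that("aggregation averages levels first, then the grand mean, and
           reports exclusions", {
  recs <- data.frame(
    image_id = rep(c("a", "b"), each = 2),
    method = "otsu", noise_kind = "rician",
    level_index = rep(1:2, 2), n_regions = 4L,
    ssim = c(0.9, 0.7, 0.5, 0.3),
    mse = c(2, 4, 2, 4),
    corr = c(1, 1, 1, 1),
    snr_db = c(4, NA, 4, Inf), note = NA_character_)
  agg <- aggregate_sweep(recs)
  expect_equal(agg$per_level$ssim, c(0.7, 0.5))  # means across images
  expect_equal(agg$grand$ssim, 0.6)
  expect_equal(agg$grand$mse, 3)
  # NA and Inf flags excluded, counts reported
  expect_equal(agg$per_level$snr_db, c(4, NA))
  expect_equal(agg$grand$snr_db, 4)
  expect_equal(agg$excluded$snr_db, 2)
  # single record aggregates to itself
  one <- recs[1, ]
  agg1 <- aggregate_sweep(one)
  expect_equal(agg1$grand$ssim, 0.9)
})

test_that("significance grids cover method x baseline x metric with valid
           p-values, near 0.5 for self-comparison", {
  imgs <- make_small_phantoms(2)
  recs <- run_robustness_sweep(imgs, methods = c("otsu", "kmeans", "pso"),
                               noise_kinds = "salt_pepper",
                               master_seed = 2,
                               control = optimizer_control(iterations = 15,
                                                           population = 10))
  sig <- significance_matrix(recs)
  expect_equal(nrow(sig), 1 * 2 * 1 * 4)  # 1 method, 2 baselines, 4 metrics
  expect_true(all(sig$p_value >= 0 & sig$p_value <= 1, na.rm = TRUE))
  # identical samples -> p approximately 0.5
  fake <- recs[recs$method == "otsu", ]
  fake$method <- "pso"
  sig0 <- significance_matrix(rbind(recs[recs$method != "pso", ], fake))
  self <- sig0[sig0$baseline == "otsu" & sig0$metric == "ssim", ]
  expect_equal(self$p_value, 0.5, tolerance = 0.05)
  expect_error(significance_matrix(recs[recs$method == "pso", ]),
               "baseline")
})

test_that("failed cells are recorded without aborting the sweep", {
  imgs <- list(tiny = matrix(5L, 48, 48))  # constant image: kmeans impossible
  recs <- run_robustness_sweep(imgs, methods = "kmeans",
                               noise_kinds = "gaussian", levels = 1:2,
                               master_seed = 3)
  expect_equal(nrow(recs), 2)
  expect_true(all(!is.na(recs$note)))
  expect_true(all(is.na(recs$ssim)))
})
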