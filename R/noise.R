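# Deterministic-parameter noise generators and the graded intensity sweeps
# used for robustness benchmarking. All noise arithmetic happens on the
# normalized [0, 1] scale (the steering parameters are unit-scale
# variances/densities); results are clipped and requantized to 8 bits.

NOISE_KINDS <- c("gaussian", "speckle", "salt_pepper", "rician")

# steering-parameter ranges for the 20-level sweeps, per noise kind
NOISE_RANGES <- list(
  gaussian    = c(0.01, 0.2),   # mean mu, with variance fixed at 0.01
  salt_pepper = c(0.17, 0.33),  # density d
  speckle     = c(0.01, 0.2),   # variance sigma^2
  rician      = c(0.02, 0.4)    # variance sigma^2
)

#' Graded noise-level grid for a robustness sweep
#'
#' Returns 20 noise specifications with the steering parameter linearly
#' spaced over the kind's standard range: Gaussian mean 0.01–0.2 (variance
#' fixed at 0.01), salt-and-pepper density 0.17–0.33, speckle variance
#' 0.01–0.2, Rician variance 0.02–0.4. The grid is the same for every
#' region count; level 0 (the native image) is represented by the sweep
#' driver, not by a spec.
#'
#' @param kind one of `"gaussian"`, `"speckle"`, `"salt_pepper"`,
#'   `"rician"`.
#' @param n_regions region count of the run the grid belongs to (kept in
#'   the specs for bookkeeping; does not alter the grid).
#' @param levels number of levels (default 20).
#' @return data.frame with columns `kind`, `level_index` (1..20), `mu`,
#'   `sigma2`, `d` (irrelevant parameters are `NA`).
#' @export
noise_level_grid <- function(kind, n_regions = 4L, levels = 20L) {
  kind <- match.arg(kind, NOISE_KINDS)
  rng <- NOISE_RANGES[[kind]]
  par <- seq(rng[1], rng[2], length.out = levels)
  out <- data.frame(kind = kind, level_index = seq_len(levels),
                    mu = NA_real_, sigma2 = NA_real_, d = NA_real_,
                    n_regions = as.integer(n_regions))
  switch(kind,
    gaussian    = { out$mu <- par; out$sigma2 <- 0.01 },
    speckle     = { out$sigma2 <- par },
    salt_pepper = { out$d <- par },
    rician      = { out$sigma2 <- par }
  )
  out
}

requantize <- function(x01) {
  img <- round_half_up(clip01(x01) * 255)
  storage.mode(img) <- "integer"
  img
}

#' Additive Gaussian noise
#'
#' Normalizes the image to `[0, 1]`, adds independent per-pixel
#' N(`mu`, `sigma2`) samples, clips and requantizes to 8 bits.
#'
#' @param img 8-bit grayscale matrix.
#' @param mu noise mean on the unit intensity scale.
#' @param sigma2 noise variance on the unit intensity scale.
#' @param seed RNG seed (NULL = current stream).
#' @return noisy 8-bit image, deterministic per seed.
#' @export
add_gaussian_noise <- function(img, mu = 0, sigma2 = 0.01, seed = NULL) {
  validate_gray_image(img, min_dim = 1L)
  if (sigma2 < 0) stopf("sigma2 must be >= 0")
  n <- with_opt_seed(seed, stats::rnorm(length(img), mu, sqrt(sigma2)))
  requantize(img / 255 + matrix(n, nrow(img)))
}

#' Multiplicative speckle noise
#'
#' `J = I + n*I` on the unit scale, with `n` drawn from the zero-mean
#' uniform distribution of variance `sigma2` (range `±sigma*sqrt(3)`),
#' the convention of the common imaging toolboxes this parameterization
#' mirrors.
#'
#' @inheritParams add_gaussian_noise
#' @return noisy 8-bit image.
#' @export
add_speckle_noise <- function(img, sigma2 = 0.04, seed = NULL) {
  validate_gray_image(img, min_dim = 1L)
  if (sigma2 < 0) stopf("sigma2 must be >= 0")
  half <- sqrt(3 * sigma2)
  n <- with_opt_seed(seed, stats::runif(length(img), -half, half))
  x <- img / 255
  requantize(x + matrix(n, nrow(img)) * x)
}

#' Salt-and-pepper impulse noise
#'
#' Exactly `round(d * N)` pixels, chosen without replacement, are each
#' independently replaced by 0 or 255 with probability 1/2. The exact
#' count (rather than per-pixel Bernoulli corruption) makes the corrupted
#' pixel count deterministic.
#'
#' @inheritParams add_gaussian_noise
#' @param d corruption density in `[0, 1]`.
#' @return noisy 8-bit image.
#' @export
add_salt_pepper_noise <- function(img, d = 0.2, seed = NULL) {
  validate_gray_image(img, min_dim = 1L)
  if (d < 0 || d > 1) stopf("density d must lie in [0, 1]")
  N <- length(img)
  k <- round(d * N)
  out <- img
  if (k > 0) {
    with_opt_seed(seed, {
      idx <- sample.int(N, k)
      out[idx] <- 255L * stats::rbinom(k, 1L, 0.5)
    })
  }
  out
}

#' Rician (MR magnitude) noise
#'
#' Per pixel on the unit scale, `M = sqrt((I + n1)^2 + n2^2)` with `n1`,
#' `n2` independent N(0, `sigma2`) — the magnitude of a complex signal
#' whose real and imaginary parts carry uncorrelated Gaussian noise.
#' Where the signal is zero the output is Rayleigh distributed with mean
#' `sigma * sqrt(pi/2)`.
#'
#' @inheritParams add_gaussian_noise
#' @return noisy 8-bit image.
#' @export
add_rician_noise <- function(img, sigma2 = 0.04, seed = NULL) {
  validate_gray_image(img, min_dim = 1L)
  if (sigma2 < 0) stopf("sigma2 must be >= 0")
  s <- sqrt(sigma2)
  x <- img / 255
  noisy <- with_opt_seed(seed, {
    n1 <- stats::rnorm(length(img), 0, s)
    n2 <- stats::rnorm(length(img), 0, s)
    sqrt((x + matrix(n1, nrow(img)))^2 + matrix(n2, nrow(img))^2)
  })
  requantize(noisy)
}

#' Apply a noise specification from [noise_level_grid()]
#'
#' @param img 8-bit grayscale matrix.
#' @param spec one row of a noise grid data.frame (or an equivalent list
#'   with `kind` and the relevant parameters).
#' @param seed RNG seed.
#' @return noisy 8-bit image.
#' @export
apply_noise <- function(img, spec, seed = NULL) {
  kind <- match.arg(spec$kind, NOISE_KINDS)
  switch(kind,
    gaussian    = add_gaussian_noise(img, spec$mu, spec$sigma2, seed),
    speckle     = add_speckle_noise(img, spec$sigma2, seed),
    salt_pepper = add_salt_pepper_noise(img, spec$d, seed),
    rician      = add_rician_noise(img, spec$sigma2, seed)
  )
}
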