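# Independent brute-force oracles and fixture builders. These are kept
# deliberately naive (scalar loops, direct formulas) so they share no code
# path with the package implementations they check.

# Kapur entropy by direct per-bin summation
oracle_kapur <- function(probs, tv) {
  bounds <- c(0, tv, 256)
  total <- 0
  for (l in seq_len(length(tv) + 1)) {
    bins <- (bounds[l]):(bounds[l + 1] - 1)
    p <- probs[bins + 1]
    w <- sum(p)
    if (w <= 0) next
    q <- p[p > 0] / w
    total <- total - sum(q * log(q))
  }
  total
}

# exhaustive single-threshold Otsu by scanning all T and the textbook
# two-class formula
oracle_otsu1 <- function(probs) {
  best_t <- NA; best_v <- -Inf
  mu_all <- sum((0:255) * probs)
  for (T in 1:255) {
    w0 <- sum(probs[1:T])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) v <- 0
    else {
      mu0 <- sum((0:(T - 1)) * probs[1:T]) / w0
      mu1 <- (mu_all - w0 * mu0) / w1
      v <- w0 * w1 * (mu0 - mu1)^2
    }
    if (v > best_v + 1e-12) { best_v <- v; best_t <- T }
  }
  list(threshold = best_t, variance = best_v)
}

# Sobel edge count by explicit double-loop 3x3 correlation on a padded mask
oracle_sobel_count <- function(mask) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dcol
  ky <- t(kx)
  m <- matrix(0, nrow(mask) + 4, ncol(mask) + 4)
  m[3:(nrow(mask) + 2), 3:(ncol(mask) + 2)] <- mask * 1
  cnt <- 0
  for (r in 2:(nrow(m) - 1)) for (c in 2:(ncol(m) - 1)) {
    win <- m[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (sum(win * kx) != 0 || sum(win * ky) != 0) cnt <- cnt + 1
  }
  cnt
}

# Zhang-Suen thinning, scalar-loop textbook transcription
oracle_thin <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  nb <- function(r, c) c(m[r - 1, c], m[r - 1, c + 1], m[r, c + 1],
                         m[r + 1, c + 1], m[r + 1, c], m[r + 1, c - 1],
                         m[r, c - 1], m[r - 1, c - 1])  # P2..P9
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      kill <- matrix(FALSE, nrow(m), ncol(m))
      for (r in 2:(nrow(m) - 1)) for (c in 2:(ncol(m) - 1)) {
        if (m[r, c] == 0L) next
        p <- nb(r, c)
        B <- sum(p)
        A <- sum(p == 0 & c(p[-1], p[1]) == 1)
        ok <- B >= 2 && B <= 6 && A == 1
        if (sub == 1) ok <- ok && p[1] * p[3] * p[5] == 0 && p[3] * p[5] * p[7] == 0
        else ok <- ok && p[1] * p[3] * p[7] == 0 && p[1] * p[5] * p[7] == 0
        if (ok) kill[r, c] <- TRUE
      }
      if (any(kill)) { m[kill] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] == 1L
}

# random histogram with a fixed number of active bins
random_histogram <- function(seed, n_active = 64) {
  set.seed(seed)
  bins <- sample(0:255, n_active)
  counts <- rep(0, 256)
  counts[bins + 1] <- stats::rpois(n_active, 50) + 1
  histogram_from_counts(counts)
}

# random strictly increasing vertex vector
random_vertices <- function(seed, L) {
  set.seed(seed)
  sort(sample(0:255, L))
}

# 8 x 256 image whose columns run through every intensity once
ramp_image <- function() matrix(rep(0:255, each = 8), nrow = 8)
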