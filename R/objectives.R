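# Histogram computation, hard-threshold application, Kapur-entropy and
# between-class-variance objectives, the exhaustive-search oracle and the
# equal-area multi-Otsu baseline.
#
# Threshold semantics: a threshold vector T1 < ... < Tn (integers in
# [1, 255]) partitions the intensity axis into half-open regions
# [T_{l-1}, T_l) with sentinels T_0 = 0 and T_{n+1} = 256; a pixel of
# intensity exactly T_l therefore belongs to region l+1.

#' Intensity histogram of an 8-bit image
#'
#' @param img 8-bit grayscale matrix.
#' @return list of class `intensity_histogram` with `counts` (256
#'   integers, bin j+1 counts intensity j) and `probs` (normalized).
#' @export
compute_histogram <- function(img) {
  validate_gray_image(img, min_dim = 1L)
  counts <- tabulate(as.vector(img) + 1L, nbins = 256L)
  histogram_from_counts(counts)
}

#' Build a histogram object from raw bin counts
#'
#' @param counts 256 nonnegative bin counts (bin j+1 = intensity j).
#' @return an `intensity_histogram`.
#' @export
histogram_from_counts <- function(counts) {
  if (length(counts) != 256 || any(counts < 0))
    stopf("counts must be 256 nonnegative values")
  total <- sum(counts)
  if (total <= 0) stopf("histogram is empty")
  structure(list(counts = as.integer(counts), probs = counts / total),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  act <- which(x$counts > 0)
  cat("Intensity histogram:", sum(x$counts), "pixels,",
      length(act), "active bins in [", min(act) - 1, ",", max(act) - 1, "]\n")
  invisible(x)
}

as_histogram <- function(h) {
  if (inherits(h, "intensity_histogram")) return(h)
  if (is.matrix(h) || (is.numeric(h) && length(h) != 256))
    return(compute_histogram(h))
  histogram_from_counts(h)
}

#' Segment an image by hard thresholds
#'
#' @param img 8-bit grayscale matrix.
#' @param tv integer thresholds, strictly increasing, in `[1, 255]`;
#'   an empty vector yields a single region.
#' @return integer label matrix (values `1..length(tv)+1`) with attribute
#'   `n_regions`.
#' @export
apply_hard_thresholds <- function(img, tv) {
  validate_gray_image(img, min_dim = 1L)
  tv <- validate_thresholds(tv)
  labels <- matrix(findInterval(as.vector(img), tv) + 1L, nrow(img))
  storage.mode(labels) <- "integer"
  attr(labels, "n_regions") <- length(tv) + 1L
  labels
}

validate_thresholds <- function(tv) {
  if (length(tv) == 0) return(integer(0))
  tv <- as.integer(tv)
  if (any(diff(tv) <= 0)) stopf("thresholds must be strictly increasing")
  if (any(tv < 1 | tv > 255)) stopf("thresholds must lie in [1, 255]")
  tv
}

# cumulative tables reused by the batch evaluators: cw[j+1] = sum of probs
# of intensities 0..j, cs likewise for p*log(p) (0 log 0 := 0)
kapur_tables <- function(h) {
  p <- h$probs
  plogp <- ifelse(p > 0, p * log(p), 0)
  list(cw = c(0, cumsum(p)), cs = c(0, cumsum(plogp)))
}

#' Kapur entropy of a thresholded histogram
#'
#' Sum over regions of the Shannon entropy (natural log) of the
#' within-region normalized intensity distribution:
#' `H_l = -sum_j (p_j/w_l) ln(p_j/w_l)` with `w_l` the region's total
#' probability. Empty regions and zero-probability bins contribute 0.
#' This is the fitness all the optimizers maximize.
#'
#' @param h an `intensity_histogram` (or image / 256 counts).
#' @param tv integer threshold vector (possibly empty).
#' @return entropy in nats.
#' @export
kapur_entropy <- function(h, tv) {
  h <- as_histogram(h)
  tv <- validate_thresholds(tv)
  drop(kapur_batch(kapur_tables(h),
                   matrix(tv, nrow = 1, ncol = length(tv))))
}

# Vectorized Kapur evaluation: TV is a matrix with one candidate threshold
# vector per row (possibly 0 columns). Uses H_l = ln(w) - S/w with
# w = sum p, S = sum p log p over the region's bins.
kapur_batch <- function(tab, TV) {
  n <- ncol(TV)
  m <- nrow(TV)
  bounds <- cbind(rep(1L, m), TV + 1L, rep(257L, m))  # table indices
  total <- numeric(m)
  for (l in seq_len(n + 1)) {
    w <- tab$cw[bounds[, l + 1]] - tab$cw[bounds[, l]]
    s <- tab$cs[bounds[, l + 1]] - tab$cs[bounds[, l]]
    pos <- w > 0
    total[pos] <- total[pos] + log(w[pos]) - s[pos] / w[pos]
  }
  total
}

# Generalized between-class variance sum_l w_l mu_l^2 - mu_T^2 (the
# quantity classic Otsu maximizes; for one threshold this equals
# w0 w1 (mu0 - mu1)^2).
bcv_tables <- function(h) {
  p <- h$probs
  list(cw = c(0, cumsum(p)), cm = c(0, cumsum(p * (0:255))))
}

bcv_batch <- function(tab, TV) {
  n <- ncol(TV)
  m <- nrow(TV)
  bounds <- cbind(rep(1L, m), TV + 1L, rep(257L, m))
  muT <- tab$cm[257] / tab$cw[257]
  total <- numeric(m)
  for (l in seq_len(n + 1)) {
    w <- (tab$cw[bounds[, l + 1]] - tab$cw[bounds[, l]])
    mu <- tab$cm[bounds[, l + 1]] - tab$cm[bounds[, l]]
    pos <- w > 0
    total[pos] <- total[pos] + mu[pos]^2 / w[pos]
  }
  total / tab$cw[257] - muT^2
}

#' Batch objective over integer threshold matrices
#'
#' Returns a function mapping a matrix of candidate threshold vectors
#' (one per row, sorted distinct integers) to their fitness values; the
#' interface every optimizer in the package consumes.
#'
#' @param h histogram (any form accepted by [kapur_entropy()]).
#' @param objective `"kapur"` or `"between_class_variance"`.
#' @return function(matrix) -> numeric vector.
#' @export
make_threshold_objective <- function(h, objective = c("kapur", "between_class_variance")) {
  h <- as_histogram(h)
  objective <- match.arg(objective)
  if (objective == "kapur") {
    tab <- kapur_tables(h)
    function(TV) kapur_batch(tab, TV)
  } else {
    tab <- bcv_tables(h)
    function(TV) bcv_batch(tab, TV)
  }
}

#' Exhaustive global search over threshold vectors
#'
#' Enumerates every ordered combination of candidate thresholds and
#' returns the global maximizer; the independent oracle the optimizers
#' are validated against. The candidate set is condensed to one
#' representative per active-bin gap (the objective only changes when a
#' threshold crosses an occupied bin), which also makes the returned
#' vector the lexicographically smallest optimum.
#'
#' @param h histogram.
#' @param n_thresholds number of thresholds (0 allowed).
#' @param objective `"kapur"` or `"between_class_variance"`.
#' @return list with `thresholds` and `fitness`.
#' @export
exhaustive_search <- function(h, n_thresholds,
                              objective = c("kapur", "between_class_variance")) {
  h <- as_histogram(h)
  objective <- match.arg(objective)
  fobj <- make_threshold_objective(h, objective)
  if (n_thresholds == 0) {
    return(list(thresholds = integer(0),
                fitness = fobj(matrix(integer(0), 1, 0))))
  }
  active <- which(h$counts > 0) - 1L   # intensities 0..255
  if (n_thresholds > 3 && length(active) > 64)
    stopf("exhaustive search refused: > 3 thresholds on a histogram with > 64 active bins")
  # the objective only depends on which active bins land in which region,
  # so thresholds within one inactive gap are interchangeable; keep the
  # n_thresholds smallest members of every gap class so that optima with
  # several thresholds in the same gap (empty regions) stay reachable and
  # the lexicographically smallest optimum is always enumerated
  starts <- sort(unique(pmax(c(1L, active + 1L), 1L)))
  starts <- starts[starts <= 255L]
  ends <- c(starts[-1] - 1L, 255L)
  cand <- unlist(lapply(seq_along(starts), function(k)
    starts[k]:min(starts[k] + n_thresholds - 1L, ends[k])))
  if (length(cand) < n_thresholds)
    stopf("not enough candidate thresholds for %d thresholds", n_thresholds)
  combos <- t(utils::combn(cand, n_thresholds))  # lexicographic order
  f <- numeric(nrow(combos))
  chunk <- 200000L
  for (start in seq(1L, nrow(combos), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(combos))
    f[idx] <- fobj(combos[idx, , drop = FALSE])
  }
  # lexicographically smallest vector within a 1e-12 tie band
  best <- which(f >= max(f) - 1e-12)[1]
  list(thresholds = as.integer(combos[best, ]), fitness = f[best])
}

#' Equal-area multi-Otsu thresholding
#'
#' The 256-bin intensity axis is split into `p = n_thresholds` equal-width
#' areas (width `256/p`); within each area the single threshold maximizing
#' the between-class variance of that area's renormalized sub-histogram is
#' selected, ties broken toward the smallest threshold. An area with no
#' pixels contributes its midpoint as a documented fallback. For
#' `n_thresholds = 1` this is classic full-range Otsu.
#'
#' @param h histogram.
#' @param n_thresholds number of thresholds (>= 1).
#' @return integer threshold vector, sorted (one threshold per area, so
#'   strictly increasing).
#' @export
multi_otsu <- function(h, n_thresholds) {
  h <- as_histogram(h)
  if (n_thresholds < 1) stopf("n_thresholds must be >= 1")
  p <- n_thresholds
  out <- integer(p)
  for (i in seq_len(p)) {
    lo <- floor(256 * (i - 1) / p)        # intensities [lo, hi]
    hi <- floor(256 * i / p) - 1
    sub <- h$counts[(lo + 1):(hi + 1)]
    if (sum(sub) == 0) {
      out[i] <- max(1L, as.integer(round((lo + hi) / 2)))
      next
    }
    # classic Otsu on the area's sub-histogram: T splits [lo,T-1] | [T,hi]
    pj <- sub / sum(sub)
    v <- lo:hi
    cw <- cumsum(pj); cm <- cumsum(pj * v)
    muT <- cm[length(cm)]
    Tvals <- (lo + 1):hi                  # split [lo, T-1] | [T, hi]
    if (length(Tvals) == 0 || hi < lo + 1) { out[i] <- max(1L, hi); next }
    w0 <- cw[Tvals - lo]; m0 <- cm[Tvals - lo]
    sigma <- ifelse(w0 > 0 & w0 < 1,
                    (muT * w0 - m0)^2 / (w0 * (1 - w0)), -Inf)
    out[i] <- as.integer(Tvals[which.max(sigma)])
  }
  sort(out)
}
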