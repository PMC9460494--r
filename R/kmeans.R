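# One-dimensional K-means on the intensity axis: the conventional
# clustering baseline the optimized thresholding methods are compared
# against. Operates on the 256-bin histogram (weighted Lloyd iterations),
# which is exactly equivalent to clustering the pixels and far cheaper.

#' K-means intensity segmentation
#'
#' Assigns every pixel to the nearest of `k` intensity centroids
#' (1-D Euclidean distance = absolute difference), recomputes centroids
#' as within-class means, and repeats until no pixel changes class or
#' `max_iter` is reached. Initialization spreads `k` distinct intensities
#' over the image's intensity quantiles, with seeded random resolution of
#' quantile collisions; an emptied cluster is re-seeded at the intensity
#' farthest from its centroid. Labels are renumbered 1..k by ascending
#' centroid so the output ordering is deterministic.
#'
#' @param img 8-bit grayscale matrix.
#' @param k number of clusters (must not exceed the number of distinct
#'   intensities).
#' @param seed RNG seed for initialization.
#' @param max_iter iteration cap.
#' @return list with `labels` (integer matrix, attribute `n_regions`) and
#'   `state` (class `kmeans_state`): `centroids`, `assignment` (256-long
#'   bin-to-class lookup), `iteration`, `inertia`, and the per-iteration
#'   `inertia_history` (non-increasing).
#' @export
kmeans_segment <- function(img, k, seed = NULL, max_iter = 100L) {
  validate_gray_image(img, min_dim = 1L)
  h <- compute_histogram(img)
  counts <- h$counts
  present <- which(counts > 0) - 1L   # distinct intensities
  if (k > length(present))
    stopf("k = %d exceeds the %d distinct intensities", k, length(present))
  if (k < 2) stopf("k must be >= 2")

  centroids <- with_opt_seed(seed, {
    qs <- stats::quantile(rep(present, counts[present + 1L]),
                          probs = (seq_len(k) - 0.5) / k, type = 1)
    init <- unique(as.integer(qs))
    while (length(init) < k) {   # collision: draw unused intensities
      pool <- setdiff(present, init)
      init <- c(init, pool[sample.int(length(pool), 1L)])
    }
    sort(as.numeric(init))
  })

  bins <- 0:255
  lut <- integer(256)
  inertia_hist <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- abs(outer(bins, centroids, "-"))
    new_lut <- max.col(-d, ties.method = "first")  # tie -> lower class
    # recompute centroids as weighted means; empty -> farthest intensity
    for (j in seq_len(k)) {
      sel <- new_lut == (j) & counts > 0
      if (any(sel)) {
        centroids[j] <- sum(bins[sel] * counts[sel]) / sum(counts[sel])
      } else {
        far <- which.max(abs(bins - centroids[j]) * (counts > 0))
        centroids[j] <- bins[far]
        new_lut[far] <- j
      }
    }
    inertia_hist <- c(inertia_hist,
                      sum(counts * (bins - centroids[new_lut])^2))
    if (identical(new_lut, lut) || iter >= max_iter) { lut <- new_lut; break }
    lut <- new_lut
  }

  ord <- order(centroids)
  relabel <- match(seq_len(k), ord)
  lut <- relabel[lut]
  centroids <- centroids[ord]

  labels <- matrix(lut[as.vector(img) + 1L], nrow(img))
  storage.mode(labels) <- "integer"
  attr(labels, "n_regions") <- k
  state <- structure(list(centroids = centroids, assignment = lut,
                          iteration = iter,
                          inertia = inertia_hist[length(inertia_hist)],
                          inertia_history = inertia_hist,
                          counts = counts),
                     class = "kmeans_state")
  list(labels = labels, state = state)
}

#' @export
print.kmeans_state <- function(x, ...) {
  cat("K-means state:", length(x$centroids), "clusters,",
      x$iteration, "iterations, inertia", format(x$inertia), "\n")
  cat("  centroids:", paste(round(x$centroids, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Modal intensity per K-means class
#'
#' The intensity of maximal within-class frequency, the alternative
#' "centroid" report for converged clusterings; always an intensity
#' actually present in the class.
#'
#' @param state a `kmeans_state` from [kmeans_segment()].
#' @return integer vector of modal intensities, one per class.
#' @export
kmeans_centroid_mode <- function(state) {
  k <- length(state$centroids)
  vapply(seq_len(k), function(j) {
    sel <- state$assignment == j
    cnt <- state$counts
    cnt[!sel] <- 0L
    as.integer(which.max(cnt) - 1L)
  }, integer(1))
}
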