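# Pseudo trapezoid-shaped (PTS) fuzzy membership construction over the
# intensity axis, defuzzification to a crisp label map, and the vertex
# fitness used for soft-thresholding optimization.

#' Build a PTS fuzzy membership model
#'
#' Given L strictly increasing vertices V1..VL in `[0, 255]`, constructs
#' the piecewise-linear membership functions: the first plateaus at 1 up
#' to V1 then falls linearly to 0 at V2; interior functions rise 0→1 on
#' `[V_{l-1}, V_l]` and fall 1→0 on `[V_l, V_{l+1}]`; the last rises to 1
#' at VL and plateaus to 255. Adjacent functions sum to 1 everywhere
#' (complete division), `mu_l(V_l) = 1` and other memberships vanish at a
#' vertex (consistency), and at most two functions are nonzero at any
#' intensity.
#'
#' @param vertices strictly increasing integers in `[0, 255]`, one per
#'   region.
#' @param n_regions number of regions; defaults to `length(vertices)`.
#' @return object of class `pts_model`: `vertices`, `n_regions`,
#'   `membership` (L x 256 matrix over intensities 0..255).
#' @export
build_pts_model <- function(vertices, n_regions = length(vertices)) {
  v <- as.integer(vertices)
  if (length(v) != n_regions) stopf("need exactly %d vertices", n_regions)
  if (n_regions < 2) stopf("a PTS model needs at least 2 regions")
  if (any(diff(v) <= 0)) stopf("vertices must be strictly increasing")
  if (any(v < 0 | v > 255)) stopf("vertices must lie in [0, 255]")
  x <- 0:255
  L <- n_regions
  mu <- matrix(0, L, 256)
  mu[1, ] <- clip01((v[2] - x) / (v[2] - v[1]))
  if (L > 2) {
    for (l in 2:(L - 1)) {
      up <- (x - v[l - 1]) / (v[l] - v[l - 1])
      down <- (v[l + 1] - x) / (v[l + 1] - v[l])
      mu[l, ] <- clip01(pmin(up, down))
    }
  }
  mu[L, ] <- clip01((x - v[L - 1]) / (v[L] - v[L - 1]))
  structure(list(vertices = v, n_regions = L, membership = mu),
            class = "pts_model")
}

#' @export
print.pts_model <- function(x, ...) {
  cat("PTS fuzzy model:", x$n_regions, "regions, vertices",
      paste(x$vertices, collapse = ", "), "\n")
  cat("  crisp-equivalent thresholds:",
      paste(pts_midpoints(x$vertices), collapse = ", "), "\n")
  invisible(x)
}

#' Crisp-equivalent thresholds of a vertex vector
#'
#' Defuzzification by maximal membership (ties to the lower region)
#' assigns intensity x to region l+1 exactly when x exceeds the midpoint
#' of V_l and V_{l+1}; under the package's upper-exclusive threshold
#' convention this corresponds to thresholds
#' `T_l = floor((V_l + V_{l+1})/2) + 1`.
#'
#' @param vertices strictly increasing integer vertices.
#' @return integer thresholds of length `length(vertices) - 1`.
#' @export
pts_midpoints <- function(vertices) {
  v <- as.integer(vertices)
  n <- length(v)
  as.integer(floor((v[-n] + v[-1]) / 2) + 1L)
}

#' Defuzzify an image under a PTS model
#'
#' Assigns every pixel the region of maximal membership at its intensity,
#' ties broken toward the lower region index. Equivalent to hard
#' thresholding at [pts_midpoints()].
#'
#' @param img 8-bit grayscale matrix.
#' @param model a `pts_model`.
#' @return integer label matrix with attribute `n_regions`.
#' @export
defuzzify <- function(img, model) {
  validate_gray_image(img, min_dim = 1L)
  lut <- apply(model$membership, 2, which.max)  # which.max: first = lower
  labels <- matrix(as.integer(lut[as.vector(img) + 1L]), nrow(img))
  attr(labels, "n_regions") <- model$n_regions
  labels
}

#' Kapur fitness of a vertex vector
#'
#' The fitness of a soft-thresholding candidate is the Kapur entropy of
#' its crisp-equivalent partition (the midpoint thresholds), so that hard
#' and soft methods are scored by one unified objective.
#'
#' @param h histogram (any form accepted by [kapur_entropy()]).
#' @param vertices strictly increasing integer vertices.
#' @return entropy in nats.
#' @export
vertex_fitness <- function(h, vertices) {
  kapur_entropy(h, pts_midpoints(vertices))
}

#' Batch Kapur objective over PTS vertex matrices
#'
#' Returns a function mapping a matrix of candidate vertex vectors (one
#' per row, sorted distinct integers in `[0, 255]`) to the Kapur entropy
#' of their crisp-equivalent partitions; the objective the bee colony
#' maximizes for soft thresholding.
#'
#' @param h histogram (any form accepted by [kapur_entropy()]).
#' @return function(matrix) -> numeric vector.
#' @export
make_vertex_objective <- function(h) {
  h <- as_histogram(h)
  tab <- kapur_tables(h)
  function(VM) {
    n <- ncol(VM)
    TV <- floor((VM[, -n, drop = FALSE] + VM[, -1, drop = FALSE]) / 2) + 1L
    kapur_batch(tab, TV)
  }
}
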