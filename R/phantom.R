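# Synthetic MR-like phantoms with known region structure and a
# cartilage-like ribbon (half-annulus) whose geometry is known analytically.

# pixel-center coordinate grids (0-based row/col)
coord_grids <- function(h, w) {
  list(r = matrix(0:(h - 1), h, w), c = matrix(0:(w - 1), h, w, byrow = TRUE))
}

#' Generate a synthetic tissue phantom
#'
#' Produces an 8-bit grayscale phantom with `n_regions` intensity classes
#' laid out as nested geometric structures: a background, a bone-like
#' ellipse, a cartilage-like ribbon (upper half-annulus, always region 3
#' when `n_regions >= 3`), a fluid-like horizontal band, and small discs
#' for any further regions. Per-region mean intensities are equally spaced
#' by `contrast`; Gaussian texture of standard deviation `texture_sd` is
#' added and the result clipped to `[0, 255]` (clipping, not wrapping,
#' mirrors 8-bit sensor saturation).
#'
#' The returned truth record stores the exact label map, the ribbon mask
#' and its rasterized area, perimeter and skeleton length. These truth
#' values are synthetic stand-ins for manual gold-standard annotation:
#' the perimeter is the two-sided boundary band (pixels whose 3x3
#' neighbourhood mixes ribbon and non-ribbon), which is what a Sobel edge
#' count measures on a thick region, and the skeleton length is the
#' Chebyshev digital length of the mid-radius arc (an 8-connected digital
#' curve carries one pixel per unit Chebyshev length).
#'
#' @param height,width image size in pixels (>= 32 recommended).
#' @param n_regions number of intensity classes, 2..10.
#' @param contrast intensity gap between consecutive region means;
#'   default fills the 8-bit range given `texture_sd`.
#' @param texture_sd per-pixel Gaussian texture standard deviation
#'   (intensity units).
#' @param seed integer RNG seed; the phantom is a pure function of its
#'   arguments including the seed.
#' @param ribbon_outer,ribbon_inner outer/inner radius of the ribbon
#'   half-annulus in pixels; defaults scale with image size (40 and 34 at
#'   256x256).
#' @return list with elements `image` (integer matrix) and `truth`
#'   (class `phantom_truth`): `truth_labels`, `region_means`,
#'   `ribbon_mask`, `true_area`, `true_perimeter`, `true_skeleton_length`,
#'   `seed`.
#' @export
generate_phantom <- function(height = 256L, width = 256L, n_regions = 4L,
                             contrast = NULL, texture_sd = 8,
                             seed = 1L,
                             ribbon_outer = NULL, ribbon_inner = NULL) {
  if (n_regions < 2 || n_regions > 10) stopf("n_regions must be in [2, 10]")
  if (height < 8 || width < 8) stopf("phantom must be at least 8x8")
  s <- min(height, width)
  if (is.null(contrast))
    contrast <- floor((255 - 4 * texture_sd) / (n_regions - 1))
  if (contrast * (n_regions - 1) + 4 * texture_sd > 255)
    stopf("infeasible: contrast*(n_regions-1) + 4*texture_sd exceeds 255")
  if (contrast < 1) stopf("contrast must be >= 1")
  if (is.null(ribbon_outer)) ribbon_outer <- round(0.156 * s)
  if (is.null(ribbon_inner)) ribbon_inner <- round(0.133 * s)
  if (ribbon_inner >= ribbon_outer) stopf("ribbon_inner must be < ribbon_outer")

  offset <- round((255 - contrast * (n_regions - 1)) / 2)
  means <- offset + (seq_len(n_regions) - 1) * contrast

  g <- coord_grids(height, width)
  labels <- matrix(1L, height, width)

  # bone-like ellipse, lower center
  ec <- c(0.65 * (height - 1), 0.5 * (width - 1))
  ea <- c(0.18 * height, 0.28 * width)
  in_ellipse <- ((g$r - ec[1]) / ea[1])^2 + ((g$c - ec[2]) / ea[2])^2 <= 1
  labels[in_ellipse] <- 2L

  # fluid-like band near the bottom
  if (n_regions >= 4) {
    band <- g$r >= 0.88 * height & g$r <= 0.94 * height
    labels[band] <- 4L
  }

  # extra small discs along the left margin for regions 5..n
  if (n_regions >= 5) {
    dr <- 0.045 * s
    for (k in 5:n_regions) {
      cc <- c((0.10 + 0.15 * (k - 5)) * (height - 1), 0.10 * (width - 1))
      disc <- (g$r - cc[1])^2 + (g$c - cc[2])^2 <= dr^2
      labels[disc] <- as.integer(k)
    }
  }

  # cartilage-like ribbon: upper half-annulus, painted last so region 3
  # coincides exactly with the ribbon mask
  ribbon <- matrix(FALSE, height, width)
  rc <- c(0.40 * (height - 1), 0.5 * (width - 1))
  if (n_regions >= 3) {
    d2 <- (g$r - rc[1])^2 + (g$c - rc[2])^2
    ribbon <- d2 >= ribbon_inner^2 & d2 <= ribbon_outer^2 & g$r <= rc[1]
    labels[ribbon] <- 3L
  }

  img <- with_opt_seed(seed, {
    base <- matrix(means[labels], height, width)
    if (texture_sd > 0)
      base <- base + matrix(stats::rnorm(height * width, 0, texture_sd),
                            height, width)
    base
  })
  img[img < 0] <- 0
  img[img > 255] <- 255
  img <- round_half_up(img)
  storage.mode(img) <- "integer"

  # skeleton truth: an 8-connected digital curve has one pixel per unit
  # Chebyshev length, so the mid-radius semicircular arc contributes
  # 2*sqrt(2)*mid pixels (integral of max(|sin|,|cos|) over a half turn)
  skel_len <- 0L
  if (n_regions >= 3) {
    mid <- (ribbon_outer + ribbon_inner) / 2
    skel_len <- as.integer(round(2 * sqrt(2) * mid) + 1)
  }

  truth <- structure(list(
    truth_labels = labels,
    region_means = means,
    ribbon_mask = ribbon,
    true_area = sum(ribbon),
    true_perimeter = boundary_band_count(ribbon),
    true_skeleton_length = as.integer(skel_len),
    seed = as.integer(seed),
    ribbon_outer = ribbon_outer,
    ribbon_inner = ribbon_inner,
    ribbon_center = rc
  ), class = "phantom_truth")

  list(image = img, truth = truth)
}

# two-sided boundary band: pixels whose 3x3 neighbourhood contains both
# mask and non-mask values (independent of the Sobel code path)
boundary_band_count <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  h <- nrow(m); w <- ncol(m)
  mx <- m[2:(h - 1), 2:(w - 1)]
  mn <- mx
  for (dr in -1:1) for (dc in -1:1) {
    sh <- m[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc)]
    mx <- pmax(mx, sh); mn <- pmin(mn, sh)
  }
  sum(mx != mn)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("Phantom truth:", max(x$truth_labels), "regions,",
      nrow(x$truth_labels), "x", ncol(x$truth_labels), "px\n")
  cat("  ribbon: area", x$true_area, "px, perimeter band",
      x$true_perimeter, "px, skeleton", x$true_skeleton_length, "px\n")
  cat("  region means:", paste(x$region_means, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize phantom truth to a JSON sidecar
#'
#' The ribbon mask is stored as run-length encoding over the
#' column-major flattened mask.
#'
#' @param truth a `phantom_truth` object.
#' @param path output path (conventionally `*.truth.json`).
#' @return invisibly, the path.
#' @export
write_phantom_truth <- function(truth, path) {
  r <- rle(as.vector(truth$ribbon_mask))
  obj <- list(
    dim = dim(truth$truth_labels),
    truth_labels = as.vector(truth$truth_labels),
    region_means = truth$region_means,
    ribbon_rle = list(lengths = r$lengths, values = as.integer(r$values)),
    true_area = truth$true_area,
    true_perimeter = truth$true_perimeter,
    true_skeleton_length = truth$true_skeleton_length,
    seed = truth$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom truth JSON sidecar
#'
#' @param path path written by [write_phantom_truth()].
#' @return a `phantom_truth` object.
#' @export
read_phantom_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dim
  mask <- matrix(inverse.rle(list(
    lengths = obj$ribbon_rle$lengths,
    values = as.logical(obj$ribbon_rle$values))), d[1], d[2])
  structure(list(
    truth_labels = matrix(as.integer(obj$truth_labels), d[1], d[2]),
    region_means = obj$region_means,
    ribbon_mask = mask,
    true_area = obj$true_area,
    true_perimeter = obj$true_perimeter,
    true_skeleton_length = obj$true_skeleton_length,
    seed = obj$seed
  ), class = "phantom_truth")
}
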