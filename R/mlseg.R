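# Model-style front-end: one fitting function returning a classed object
# with the usual accessor methods.

MLSEG_METHODS <- c("otsu", "kmeans", "abc", "pso", "fpso", "dpso", "ga",
                   "abc_fuzzy")

#' Fit a multilevel segmentation model to a grayscale image
#'
#' Segments an 8-bit grayscale image into `regions` intensity classes.
#' `"otsu"` uses equal-area multi-Otsu thresholding and `"kmeans"`
#' 1-D intensity clustering (the two conventional baselines); `"abc"`,
#' `"pso"`, `"fpso"`, `"dpso"` and `"ga"` maximize the Kapur entropy of
#' the hard-threshold partition with the named metaheuristic; and
#' `"abc_fuzzy"` optimizes the vertices of a fuzzy pseudo
#' trapezoid-shaped membership model with the bee colony and labels
#' pixels by maximal membership (soft thresholding).
#'
#' @param img 8-bit grayscale integer matrix (see
#'   [validate_gray_image()]); file paths are read with
#'   [read_gray_image()].
#' @param method segmentation method (see Details).
#' @param regions number of regions L (thresholding methods fit L-1
#'   thresholds).
#' @param control an [optimizer_control()]; its `seed` drives all
#'   stochastic methods.
#' @return object of class `mlseg` with components `method`, `n_regions`,
#'   `thresholds` (crisp or crisp-equivalent), `vertices` (fuzzy method
#'   only), `centroids` (kmeans only), `fitness` (Kapur entropy of the
#'   fitted partition), `history`, `labels` and `control`.
#' @seealso [predict.mlseg()], [coef.mlseg()], [plot.mlseg()]
#' @examples
#' ph <- generate_phantom(64, 64, n_regions = 4, texture_sd = 6, seed = 1)
#' fit <- mlseg(ph$image, method = "otsu", regions = 4)
#' coef(fit)
#' summary(fit)
#' @export
mlseg <- function(img, method = MLSEG_METHODS, regions = 4L,
                  control = optimizer_control()) {
  method <- match.arg(method)
  if (is.character(img)) img <- read_gray_image(img)
  validate_gray_image(img, min_dim = 1L)
  if (regions < 2 || regions > 255) stopf("regions must be in [2, 255]")
  h <- compute_histogram(img)

  thresholds <- NULL; vertices <- NULL; centroids <- NULL
  history <- NULL; labels <- NULL; res <- NULL

  if (method == "otsu") {
    thresholds <- multi_otsu(h, regions - 1L)
  } else if (method == "kmeans") {
    km <- kmeans_segment(img, regions, seed = control$seed)
    labels <- km$labels
    centroids <- km$state$centroids
    # crisp-equivalent thresholds: midpoints between adjacent centroids
    thresholds <- repair_rows(matrix(
      floor((centroids[-regions] + centroids[-1]) / 2) + 1, nrow = 1),
      1, 255)[1, ]
  } else if (method == "abc_fuzzy") {
    res <- optimize_abc(make_vertex_objective(h), dim = regions,
                        lower = 0, upper = 255, control = control)
    vertices <- res$best_vector
    model <- build_pts_model(vertices, regions)
    labels <- defuzzify(img, model)
    thresholds <- pts_midpoints(vertices)
    history <- res$history
  } else {
    res <- OPTIMIZERS[[method]](make_threshold_objective(h, "kapur"),
                                dim = regions - 1L, lower = 1, upper = 255,
                                control = control)
    thresholds <- res$best_vector
    history <- res$history
  }
  if (is.null(labels)) labels <- apply_hard_thresholds(img, thresholds)
  attr(labels, "n_regions") <- as.integer(regions)

  structure(list(
    method = method,
    n_regions = as.integer(regions),
    thresholds = thresholds,
    vertices = vertices,
    centroids = centroids,
    fitness = kapur_entropy(h, validate_thresholds(thresholds)),
    history = history,
    labels = labels,
    image_dim = dim(img),
    control = control,
    call = match.call()
  ), class = "mlseg")
}

#' @export
print.mlseg <- function(x, ...) {
  cat(sprintf("Multilevel segmentation (%s), %d regions, %dx%d px\n",
              x$method, x$n_regions, x$image_dim[1], x$image_dim[2]))
  cat("  thresholds:", paste(x$thresholds, collapse = ", "), "\n")
  if (!is.null(x$vertices))
    cat("  PTS vertices:", paste(x$vertices, collapse = ", "), "\n")
  if (!is.null(x$centroids))
    cat("  centroids:", paste(round(x$centroids, 2), collapse = ", "), "\n")
  cat(sprintf("  Kapur entropy: %.4f nats\n", x$fitness))
  invisible(x)
}

#' @export
summary.mlseg <- function(object, ...) {
  tab <- tabulate(object$labels, nbins = object$n_regions)
  out <- list(fit = object,
              region_share = tab / sum(tab),
              pixel_counts = tab)
  class(out) <- "summary.mlseg"
  out
}

#' @export
print.summary.mlseg <- function(x, ...) {
  print(x$fit)
  df <- data.frame(region = seq_along(x$pixel_counts),
                   pixels = x$pixel_counts,
                   share = round(x$region_share, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mlseg <- function(object, ...) object$thresholds

#' @export
fitted.mlseg <- function(object, ...) object$labels

#' Apply a fitted segmentation model to a new image
#'
#' Applies the fitted thresholds (or fuzzy model) to `newdata`, so a
#' model fitted on a noise-free image can label its corrupted versions.
#'
#' @param object an `mlseg` fit.
#' @param newdata 8-bit grayscale matrix; default re-labels the training
#'   image.
#' @param ... unused.
#' @return integer label matrix.
#' @export
predict.mlseg <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  if (is.character(newdata)) newdata <- read_gray_image(newdata)
  if (!is.null(object$vertices)) {
    defuzzify(newdata, build_pts_model(object$vertices, object$n_regions))
  } else {
    apply_hard_thresholds(newdata, object$thresholds)
  }
}

#' Plot a fitted segmentation as a color-coded label map
#'
#' @param x an `mlseg` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.mlseg <- function(x, ...) {
  L <- x$n_regions
  lab <- x$labels
  graphics::image(t(lab[nrow(lab):1, ]), col = label_palette(L),
                  axes = FALSE, asp = nrow(lab) / ncol(lab), ...)
  graphics::title(main = sprintf("%s, %d regions", x$method, L))
  invisible(x)
}
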