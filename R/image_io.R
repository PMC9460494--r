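# Reading and writing 8-bit grayscale images and label maps (PNG/TIFF).

read_raster <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported raster format '.%s' (PNG or TIFF expected)", ext)
  )
  if (length(arr) == 0) stopf("zero-sized image: %s", path)
  arr
}

#' Read an image as 8-bit grayscale
#'
#' Reads a PNG or TIFF raster and converts it to the package's 8-bit
#' grayscale representation:
#' * multi-channel (RGB/RGBA) inputs are reduced by the Rec. 709 luminance
#'   weights 0.2126 R + 0.7152 G + 0.0722 B, then rounded half-up;
#' * inputs with more than 8 bits per sample are min-max rescaled to
#'   `[0, 255]`;
#' * 8-bit grayscale passes through unchanged.
#'
#' @param path path to a PNG or TIFF file.
#' @return integer matrix with values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  arr <- read_raster(path)
  # readPNG/readTIFF return values on [0,1]; recover the native integer
  # scale, falling back to min-max rescale when the source exceeds 8 bits
  to_scale8 <- function(v) {
    v255 <- v * 255
    if (max(abs(v255 - round(v255))) < 1e-6) return(v255)  # true 8-bit
    rng <- range(v)
    if (rng[1] == rng[2]) return(v * 0)
    (v - rng[1]) / (rng[2] - rng[1]) * 255
  }
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc >= 3) {
      g <- 0.2126 * to_scale8(arr[, , 1]) +
           0.7152 * to_scale8(arr[, , 2]) +
           0.0722 * to_scale8(arr[, , 3])
    } else {
      g <- to_scale8(arr[, , 1])
    }
  } else {
    g <- to_scale8(arr)
  }
  img <- round_half_up(g)
  storage.mode(img) <- "integer"
  validate_gray_image(img, min_dim = 1L)
  img
}

#' Fixed color palette for label maps
#'
#' @param n number of regions.
#' @return character vector of `n` hex colors (distinct for n <= 12).
#' @export
label_palette <- function(n) {
  pal <- c("#000000", "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3",
           "#FF7F00", "#FFFF33", "#A65628", "#F781BF", "#17BECF",
           "#66C2A5", "#FFFFFF")
  rep_len(pal, n)
}

#' Write a label map to PNG or TIFF
#'
#' With `colorize = FALSE` the raster stores the region index itself
#' (losslessly round-trippable through [read_label_map()]); with
#' `colorize = TRUE` each region index is mapped to one fixed palette
#' color, so an L-region map contains exactly L distinct colors.
#'
#' @param labels integer matrix of region indices (1..L).
#' @param path output path (`.png`, `.tif`/`.tiff`).
#' @param colorize write an RGB rendering instead of the index raster.
#' @return invisibly, the path.
#' @export
write_label_map <- function(labels, path, colorize = FALSE) {
  validate_label_map(labels)
  ext <- tolower(tools::file_ext(path))
  writer <- switch(ext,
    png = png::writePNG,
    tif = ,
    tiff = tiff::writeTIFF,
    stopf("unsupported raster format '.%s'", ext)
  )
  if (colorize) {
    L <- max(labels)
    rgb <- grDevices::col2rgb(label_palette(L)) / 255
    arr <- array(0, c(nrow(labels), ncol(labels), 3))
    for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, labels], nrow(labels))
    writer(arr, path)
  } else {
    if (max(labels) > 255) stopf("index raster supports at most 255 regions")
    writer(labels / 255, path)
  }
  invisible(path)
}

#' Read an index-raster label map written by [write_label_map()]
#'
#' @param path path to the index raster.
#' @return integer matrix of region indices.
#' @export
read_label_map <- function(path) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  lab <- round_half_up(arr * 255)
  storage.mode(lab) <- "integer"
  lab
}
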