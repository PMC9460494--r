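# Internal helpers shared across modules.

# round-half-up: 0.5 always rounds away from zero toward +Inf
# (base round() is round-half-even, which would make 8-bit conversion
# depend on parity of the integer part)
round_half_up <- function(x) floor(x + 0.5)

clip01 <- function(x) {  # preserves dim attributes, unlike pmin(1, ...)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current global stream".
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Validate an 8-bit grayscale image matrix
#'
#' The package represents images as plain integer matrices with values in
#' `[0, 255]` (row = image row, column = image column, 0-based intensities,
#' pixel-center coordinate convention). This checks those invariants.
#'
#' @param img numeric matrix.
#' @param min_dim minimum number of rows and columns (default 8).
#' @return the image, invisibly, with storage mode integer.
#' @export
validate_gray_image <- function(img, min_dim = 8L) {
  if (!is.matrix(img) || !is.numeric(img))
    stopf("image must be a numeric matrix")
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stopf("image must be at least %dx%d pixels", min_dim, min_dim)
  if (anyNA(img)) stopf("image contains missing values")
  if (any(img < 0 | img > 255)) stopf("image intensities must lie in [0, 255]")
  if (any(img != floor(img))) stopf("image intensities must be integers")
  storage.mode(img) <- "integer"
  invisible(img)
}

validate_label_map <- function(labels, n_regions = NULL) {
  if (!is.matrix(labels) || !is.numeric(labels))
    stopf("label map must be a numeric matrix")
  if (anyNA(labels)) stopf("label map contains missing values")
  L <- n_regions %||% attr(labels, "n_regions") %||% max(labels)
  if (any(labels < 1 | labels > L))
    stopf("label values must lie in [1, %d]", L)
  invisible(labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-cell seed derivation for sweeps: fold arbitrary
# integer/character components into a positive 31-bit integer.
derive_seed <- function(master, ...) {
  parts <- list(...)
  h <- as.double(master) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p)) * 131
    for (v in as.double(p)) {
      h <- (h * 48271 + v + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483629 + 1)
}
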