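# Cartilage-region extraction from a label map and the three clinical
# morphology features: area (pixel count), perimeter (Sobel edge pixel
# count) and skeleton length (Zhang-Suen thinning, 8-connected).

# result(r, c) = m(r + dr, c + dc), zero-filled outside
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

pad_mask <- function(mask, n = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h + 2 * n, w + 2 * n)
  out[(n + 1):(n + h), (n + 1):(n + w)] <- mask * 1L
  out
}

# 8-connected component labelling (breadth-first); EBImage's labeller is
# 4-connected, and lobe selection needs diagonal connectivity.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  todo <- which(mask)
  cur <- 0L
  offsets <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offsets <- offsets[!(offsets[, 1] == 0 & offsets[, 2] == 0), ]
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier) > 0) {
      r <- ((frontier - 1L) %% h) + 1L
      c <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (o in seq_len(nrow(offsets))) {
        rr <- r + offsets[o, 1]; cc <- c + offsets[o, 2]
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        idx <- (cc[ok] - 1L) * h + rr[ok]
        idx <- idx[mask[idx] & lab[idx] == 0L]
        if (length(idx) > 0) { lab[idx] <- cur; nxt <- c(nxt, idx) }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Extract one region of a label map as a binary mask
#'
#' All other regions are suppressed. Optionally keeps only the `top_k`
#' largest 8-connected components (e.g. the two cartilage lobes).
#'
#' @param labels integer label matrix.
#' @param region_id region index to keep (1..L).
#' @param top_k keep only the `top_k` largest components (default: all).
#' @return logical matrix.
#' @export
extract_region_mask <- function(labels, region_id, top_k = NULL) {
  L <- attr(labels, "n_regions") %||% max(labels)
  if (region_id < 1 || region_id > L) stopf("region_id must be in [1, %d]", L)
  mask <- labels == region_id
  if (!is.null(top_k) && any(mask)) {
    comp <- label_components(mask)
    sizes <- tabulate(comp[comp > 0])
    keep <- order(sizes, decreasing = TRUE)[seq_len(min(top_k, length(sizes)))]
    mask <- matrix(comp %in% keep, nrow(mask))
  }
  mask
}

#' Region area in pixels
#'
#' @param mask logical matrix.
#' @return count of set pixels.
#' @export
region_area <- function(mask) sum(mask * 1L)

#' Region perimeter by Sobel edge counting
#'
#' Applies the 3x3 Sobel gradient to the 0/1 mask (padded by background
#' so image borders cause no artifacts) and counts pixels of nonzero
#' gradient magnitude. On a thick region this counts the two-sided
#' boundary band (edge pixels just inside and just outside the contour).
#'
#' @param mask logical matrix.
#' @return edge pixel count.
#' @export
region_perimeter_sobel <- function(mask) {
  if (!any(mask)) return(0L)
  m <- pad_mask(mask, 2L)
  gx <- -shift_mat(m, -1, -1) - 2L * shift_mat(m, 0, -1) - shift_mat(m, 1, -1) +
         shift_mat(m, -1,  1) + 2L * shift_mat(m, 0,  1) + shift_mat(m, 1,  1)
  gy <- -shift_mat(m, -1, -1) - 2L * shift_mat(m, -1, 0) - shift_mat(m, -1, 1) +
         shift_mat(m,  1, -1) + 2L * shift_mat(m,  1, 0) + shift_mat(m,  1, 1)
  sum(gx != 0L | gy != 0L)
}

#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iterative two-subiteration thinning to a one-pixel-wide, 8-connected
#' skeleton. The mask is padded by one background pixel first.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape (subset of the mask).
#' @export
skeletonize <- function(mask) {
  h0 <- nrow(mask); w0 <- ncol(mask)
  m <- pad_mask(mask, 1L)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(m, -1,  0); p3 <- shift_mat(m, -1,  1)
      p4 <- shift_mat(m,  0,  1); p5 <- shift_mat(m,  1,  1)
      p6 <- shift_mat(m,  1,  0); p7 <- shift_mat(m,  1, -1)
      p8 <- shift_mat(m,  0, -1); p9 <- shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (sub == 1) {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(h0 + 1), 2:(w0 + 1)] == 1L
}

#' Skeleton length of a region
#'
#' Thins the mask with [skeletonize()] and measures its length: either
#' the skeleton pixel count (default) or the geodesic length where each
#' diagonal 8-neighbor link contributes `sqrt(2)` instead of 1.
#'
#' @param mask logical matrix.
#' @param method `"pixels"` or `"geodesic"`.
#' @return length (integer pixel count, or real for geodesic).
#' @export
region_skeleton_length <- function(mask, method = c("pixels", "geodesic")) {
  method <- match.arg(method)
  if (!any(mask)) return(0L)
  sk <- skeletonize(mask)
  if (method == "pixels") return(sum(sk))
  s <- pad_mask(sk, 1L)
  straight <- sum(s * shift_mat(s, 0, 1)) + sum(s * shift_mat(s, 1, 0))
  diag_links <- sum(s * shift_mat(s, 1, 1)) + sum(s * shift_mat(s, 1, -1))
  sum(sk) + (sqrt(2) - 1) * diag_links
}

#' Compute the full morphology feature set of a mask
#'
#' @param mask logical matrix.
#' @return list: `area_px`, `perimeter_px`, `skeleton_px`.
#' @export
region_features <- function(mask) {
  list(area_px = region_area(mask),
       perimeter_px = region_perimeter_sobel(mask),
       skeleton_px = region_skeleton_length(mask))
}

#' Percentage feature differences against a gold standard
#'
#' `100 * |auto - gold| / gold` per feature; the gold features must be
#' positive (the gold denominator makes the measure asymmetric by
#' design).
#'
#' @param auto,gold feature sets from [region_features()] (or named
#'   numeric vectors with the same fields).
#' @return named numeric vector of percentages.
#' @export
feature_difference_pct <- function(auto, gold) {
  a <- unlist(auto); g <- unlist(gold)
  g <- g[names(a)]
  if (any(g <= 0)) stopf("gold features must be positive")
  100 * abs(a - g) / g
}
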