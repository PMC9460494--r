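# Label-map quality metrics and the statistical tests of the robustness
# protocol. All metrics compare integer region-index matrices (never raw
# intensities): the gold standard is the same method's segmentation of
# the noise-free image.

check_same_shape <- function(gold, test) {
  if (!all(dim(gold) == dim(test)))
    stopf("label maps must have identical shape")
}

#' Mean squared error between label maps
#'
#' Mean over pixels of the squared region-index difference.
#'
#' @param gold,test integer label matrices of identical shape.
#' @return nonnegative real; 0 iff the maps are identical.
#' @export
mse <- function(gold, test) {
  check_same_shape(gold, test)
  mean((as.numeric(gold) - as.numeric(test))^2)
}

#' Global structural similarity of label maps
#'
#' Single whole-image SSIM from global means, variances (n-1 convention)
#' and covariance, `C1 = C2 = (k * dynamic_range)^2`. No local windowing:
#' one global statistic per map pair.
#'
#' @param gold,test integer label matrices.
#' @param k stabilizing constant (conventionally 0.02).
#' @param dynamic_range dynamic range of the label indices; defaults to
#'   `L - 1` for the maps' largest index L.
#' @return SSIM in `[-1, 1]`; 1 is an absolute match.
#' @export
ssim_global <- function(gold, test, k = 0.02, dynamic_range = NULL) {
  check_same_shape(gold, test)
  x <- as.numeric(gold); y <- as.numeric(test)
  if (is.null(dynamic_range)) dynamic_range <- max(x, y) - 1
  if (dynamic_range <= 0) dynamic_range <- 1
  C1 <- (k * dynamic_range)^2
  C2 <- C1
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  cxy <- stats::cov(x, y)
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' Pearson correlation between label maps
#'
#' @param gold,test integer label matrices.
#' @return correlation in `[-1, 1]`, or `NA` (undefined flag, excluded
#'   from aggregation) when either map has zero variance.
#' @export
pearson_corr <- function(gold, test) {
  check_same_shape(gold, test)
  x <- as.numeric(gold); y <- as.numeric(test)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Signal-to-noise ratio between label maps (dB)
#'
#' `10 log10( sum(g^2 - f^2) / sum((g - f)^2) )`, taken literally with
#' its signed numerator: identical maps give `Inf` (zero noise power) and
#' a nonpositive numerator gives `NA` (undefined flag, excluded from
#' aggregation with its count reported). `conventional = TRUE` switches
#' the numerator to the standard `sum(g^2)` for sensitivity analysis.
#'
#' @param gold,test integer label matrices.
#' @param conventional use the conventional signal-power numerator.
#' @return SNR in dB, `Inf`, or `NA`.
#' @export
snr_db <- function(gold, test, conventional = FALSE) {
  check_same_shape(gold, test)
  g <- as.numeric(gold); f <- as.numeric(test)
  den <- sum((g - f)^2)
  num <- if (conventional) sum(g^2) else sum(g^2 - f^2)
  if (den == 0) return(Inf)
  if (num <= 0) return(NA_real_)
  10 * log10(num / den)
}

#' Score a segmentation against its gold standard
#'
#' Bundles the four label-map metrics into one record. The gold standard
#' is always the same method's segmentation of the noise-free image under
#' identical settings.
#'
#' @param gold,test integer label matrices of identical shape.
#' @param method,noise_kind,level_index,n_regions,image_id run metadata
#'   carried verbatim into the record.
#' @param k SSIM stabilizing constant.
#' @return one-row data.frame: `image_id`, `method`, `noise_kind`,
#'   `level_index`, `n_regions`, `ssim`, `mse`, `corr`, `snr_db`.
#' @export
evaluate_against_gold <- function(gold, test, method = NA_character_,
                                  noise_kind = NA_character_,
                                  level_index = NA_integer_,
                                  n_regions = NA_integer_,
                                  image_id = NA_character_,
                                  k = 0.02) {
  check_same_shape(gold, test)
  data.frame(
    image_id = image_id, method = method, noise_kind = noise_kind,
    level_index = as.integer(level_index), n_regions = as.integer(n_regions),
    ssim = ssim_global(gold, test, k = k),
    mse = mse(gold, test),
    corr = pearson_corr(gold, test),
    snr_db = snr_db(gold, test),
    stringsAsFactors = FALSE
  )
}

#' Chi-square goodness-of-fit test of normality
#'
#' Equal-probability binning against a normal with the sample mean and
#' standard deviation; the class count is `sqrt(n)` capped so that every
#' expected count is at least 5, and the degrees of freedom are
#' `classes - 3` (two estimated parameters).
#'
#' @param sample numeric vector, `n >= 30`.
#' @return p-value in `[0, 1]`.
#' @export
chi_square_normality <- function(sample) {
  n <- length(sample)
  if (n < 30) stopf("chi-square normality test needs n >= 30")
  n_classes <- max(4L, min(floor(sqrt(n)), floor(n / 5)))
  nortest::pearson.test(sample, n.classes = n_classes, adjust = TRUE)$p.value
}

#' One-sided two-sample Wilcoxon rank-sum test
#'
#' Normal approximation with tie correction. `direction = "greater"`
#' tests whether `x` is stochastically larger than `y` (the alternative
#' used for similarity metrics); `"less"` is used for error metrics.
#'
#' @param x,y numeric samples (nonempty).
#' @param direction `"greater"` or `"less"`.
#' @return p-value.
#' @export
wilcoxon_rank_sum_one_sided <- function(x, y,
                                        direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) == 0 || length(y) == 0) stopf("samples must be nonempty")
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = direction,
                       exact = FALSE, correct = FALSE)$p.value
  )
}
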