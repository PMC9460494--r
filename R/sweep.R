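# The robustness protocol: for every image x method x region count,
# segment the native image (the gold standard), then corrupt it at each
# graded noise level, re-segment with identical settings, and score the
# noisy label map against the gold one. Aggregation and significance
# testing mirror the protocol's averaged tables and Wilcoxon matrices.

#' Run a noise-robustness sweep
#'
#' @param images named list of 8-bit grayscale matrices (names become
#'   image ids; unnamed lists get `img1`, `img2`, ...).
#' @param methods segmentation methods (see [mlseg()]).
#' @param n_regions vector of region counts to test (default 4).
#' @param noise_kinds noise generators to sweep (see
#'   [noise_level_grid()]).
#' @param levels which of the 20 grid levels to run (default all).
#' @param master_seed master seed; every cell derives its own noise and
#'   optimizer seeds from it, so the sweep is deterministic end to end.
#' @param control optimizer settings shared by all stochastic methods
#'   (its seed field is overridden per cell).
#' @param include_native also emit the level-0 record (gold scored
#'   against itself).
#' @return data.frame of metric records (class `sweep_result`), one row
#'   per image x method x region count x noise kind x level; failed
#'   cells carry `NA` metrics and the error message in `note`.
#' @export
run_robustness_sweep <- function(images,
                                 methods = c("otsu", "kmeans", "abc_fuzzy", "pso"),
                                 n_regions = 4L,
                                 noise_kinds = "salt_pepper",
                                 levels = 1:20,
                                 master_seed = 1L,
                                 control = optimizer_control(),
                                 include_native = FALSE) {
  if (length(images) == 0 || length(methods) == 0)
    stopf("need at least one image and one method")
  if (is.matrix(images)) images <- list(images)
  if (is.null(names(images)))
    names(images) <- paste0("img", seq_along(images))
  rows <- list()
  for (img_id in names(images)) {
    img <- images[[img_id]]
    for (L in n_regions) {
      for (method in methods) {
        gold_seed <- derive_seed(master_seed, img_id, method, L, "gold")
        gctl <- control; gctl$seed <- gold_seed
        gold_fit <- tryCatch(mlseg(img, method, L, gctl),
                             error = function(e) e)
        for (kind in noise_kinds) {
          grid <- noise_level_grid(kind, L)
          if (include_native) {
            rec <- if (inherits(gold_fit, "error")) {
              failed_record(img_id, method, kind, 0L, L,
                            conditionMessage(gold_fit))
            } else {
              cbind(evaluate_against_gold(gold_fit$labels, gold_fit$labels,
                                          method, kind, 0L, L, img_id),
                    note = NA_character_)
            }
            rows[[length(rows) + 1L]] <- rec
          }
          for (lev in levels) {
            rec <- tryCatch({
              if (inherits(gold_fit, "error")) stop(gold_fit)
              cell_seed <- derive_seed(master_seed, img_id, method, L,
                                       kind, lev)
              noisy <- apply_noise(img, grid[lev, ], seed = cell_seed)
              cctl <- control; cctl$seed <- cell_seed + 1L
              fit <- mlseg(noisy, method, L, cctl)
              cbind(evaluate_against_gold(gold_fit$labels, fit$labels,
                                          method, kind, lev, L, img_id),
                    note = NA_character_)
            }, error = function(e) {
              failed_record(img_id, method, kind, lev, L,
                            conditionMessage(e))
            })
            rows[[length(rows) + 1L]] <- rec
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

failed_record <- function(image_id, method, kind, lev, L, msg) {
  data.frame(image_id = image_id, method = method, noise_kind = kind,
             level_index = as.integer(lev), n_regions = as.integer(L),
             ssim = NA_real_, mse = NA_real_, corr = NA_real_,
             snr_db = NA_real_, note = msg, stringsAsFactors = FALSE)
}

SWEEP_METRICS <- c("ssim", "mse", "corr", "snr_db")

#' Aggregate a sweep into per-level and grand means
#'
#' Per-level means are taken across images for every method x region
#' count x noise kind x level; grand means average the per-level means
#' over levels (levels first, then the grand mean). `NA`/`Inf` metric
#' entries (undefined flags) are excluded, with their counts reported.
#'
#' @param records a `sweep_result` from [run_robustness_sweep()].
#' @return list with data.frames `per_level`, `grand` and `excluded`
#'   (count of excluded entries per method x kind x metric).
#' @export
aggregate_sweep <- function(records) {
  recs <- records[records$level_index > 0, , drop = FALSE]
  key <- list(method = recs$method, noise_kind = recs$noise_kind,
              n_regions = recs$n_regions, level_index = recs$level_index)
  fin_mean <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  per_level <- stats::aggregate(recs[SWEEP_METRICS], by = key, FUN = fin_mean)
  per_level <- per_level[order(per_level$method, per_level$noise_kind,
                               per_level$n_regions, per_level$level_index), ]
  gkey <- list(method = per_level$method, noise_kind = per_level$noise_kind,
               n_regions = per_level$n_regions)
  grand <- stats::aggregate(per_level[SWEEP_METRICS], by = gkey,
                            FUN = fin_mean)
  exc <- stats::aggregate(
    as.data.frame(lapply(recs[SWEEP_METRICS], function(x) !is.finite(x))),
    by = list(method = recs$method, noise_kind = recs$noise_kind,
              n_regions = recs$n_regions),
    FUN = sum)
  list(per_level = per_level, grand = grand, excluded = exc)
}

#' Wilcoxon significance matrix against the conventional baselines
#'
#' For every optimized method x metric x noise kind, the one-sided
#' Wilcoxon rank-sum p-value of that method's metric records against
#' each baseline's, direction `greater` for the similarity metrics
#' (SSIM, correlation, SNR) and `less` for MSE, plus a chi-square
#' normality p-value of the method's sample as the pre-check.
#'
#' @param records a `sweep_result`.
#' @param baselines methods to test against (must be present).
#' @return data.frame: `method`, `baseline`, `noise_kind`, `n_regions`,
#'   `metric`, `p_value`, `normality_p`.
#' @export
significance_matrix <- function(records, baselines = c("otsu", "kmeans")) {
  recs <- records[records$level_index > 0, , drop = FALSE]
  present <- unique(recs$method)
  missing_b <- setdiff(baselines, present)
  if (length(missing_b) > 0)
    stopf("baseline method(s) not in the sweep: %s",
          paste(missing_b, collapse = ", "))
  methods <- setdiff(present, baselines)
  if (length(methods) == 0) stopf("no optimized method in the sweep")
  out <- list()
  for (m in methods) for (b in baselines)
    for (kind in unique(recs$noise_kind))
      for (L in unique(recs$n_regions))
        for (metric in SWEEP_METRICS) {
          sel <- recs$noise_kind == kind & recs$n_regions == L
          x <- recs[sel & recs$method == m, metric]
          y <- recs[sel & recs$method == b, metric]
          x <- x[is.finite(x)]; y <- y[is.finite(y)]
          dirn <- if (metric == "mse") "less" else "greater"
          p <- if (length(x) == 0 || length(y) == 0) NA_real_
               else wilcoxon_rank_sum_one_sided(x, y, dirn)
          normp <- if (length(x) >= 30) chi_square_normality(x) else NA_real_
          out[[length(out) + 1L]] <- data.frame(
            method = m, baseline = b, noise_kind = kind,
            n_regions = L, metric = metric,
            p_value = p, normality_p = normp, stringsAsFactors = FALSE)
        }
  do.call(rbind, out)
}
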