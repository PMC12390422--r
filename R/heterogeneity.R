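#' Heterogeneity scoring parameters
#'
#' The heterogeneity score is the variance of the in-mask voxel PDFF
#' values after discarding values above the `trim_percentile`-th
#' percentile. Trimming is one-sided (upper) only: low PDFF is the disease
#' signal and is never removed. Percentiles use linear interpolation
#' between order statistics.
#'
#' @param trim_percentile percent, in (0, 100]; 100 disables trimming.
#' @param variance_convention `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return An object of class `heterogeneity_params`.
#' @export
heterogeneity_params <- function(trim_percentile = 90,
                                 variance_convention = c("sample", "population")) {
  if (!(trim_percentile > 0 && trim_percentile <= 100))
    stop("trim_percentile must lie in (0, 100]")
  structure(list(trim_percentile = trim_percentile,
                 variance_convention = match.arg(variance_convention),
                 percentile_convention = "linear"),
            class = "heterogeneity_params")
}

#' Extract in-mask voxel values
#'
#' One value per member voxel in deterministic array (column-major raster)
#' order. Any non-finite value inside the mask is a validation error; the
#' sentinel for "no measurement" belongs outside the mask.
#'
#' @param volume a [pdff_volume()].
#' @param mask a non-empty [roi_mask()] of matching shape.
#' @return numeric vector with attribute `n_total` (mask voxel count).
#' @export
roi_values <- function(volume, mask) {
  stopifnot(inherits(volume, "pdff_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$values), dim(mask$membership)))
    stop("volume and mask shapes differ")
  if (!any(mask$membership)) stop("mask is empty")
  vals <- volume$values[mask$membership]
  n_bad <- sum(!is.finite(vals))
  if (n_bad > 0)
    stop(sprintf("%d non-finite in-mask value(s); mask and volume are inconsistent",
                 n_bad))
  attr(vals, "n_total") <- length(vals)
  vals
}

#' Percentile-trimmed voxel variance
#'
#' Threshold at the `trim_percentile`-th percentile of the values (linear
#' interpolation between order statistics), keep values at or below the
#' threshold, and return their variance. Invariant to input ordering.
#'
#' @param values numeric vector of PDFF values (percent).
#' @param params a [heterogeneity_params()].
#' @return score in percent^2, with attributes `n_total`, `n_retained`
#'   and `threshold`. Fewer than 2 retained values raises a condition of
#'   class `degenerate_roi` carrying the counts.
#' @export
trimmed_variance <- function(values, params = heterogeneity_params()) {
  stopifnot(inherits(params, "heterogeneity_params"))
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  n_total <- length(values)
  threshold <- stats::quantile(values, params$trim_percentile / 100,
                               type = 7, names = FALSE)
  retained <- values[values <= threshold]
  n_ret <- length(retained)
  if (n_ret < 2)
    stop(errorCondition(
      sprintf("degenerate ROI: %d value(s) retained of %d after trimming at the %g-th percentile",
              n_ret, n_total, params$trim_percentile),
      class = "degenerate_roi", n_total = n_total, n_retained = n_ret))
  score <- if (params$variance_convention == "sample") stats::var(retained)
           else mean((retained - mean(retained))^2)
  structure(score, n_total = n_total, n_retained = n_ret, threshold = threshold)
}

#' Score every image of a study dataset
#'
#' For each manifest row: read the volume and mask, locate the distal
#' region from the axial mean trajectory (unless labelled masks or
#' explicit boundaries are supplied), and compute the trimmed-variance
#' heterogeneity score of the distal ROI. Rows that fail are reported as
#' absent records with a warning, never as silent zeros.
#'
#' @param dataset a `study_dataset` from [simulate_study()], or any list
#'   with a `manifest` data frame referencing volume/mask files.
#' @param params a [heterogeneity_params()].
#' @param bounds optional list of [detect_regions()] results keyed by
#'   manifest row index; `NULL` (default) detects boundaries per image.
#' @param use_labels if `TRUE` (default) masks carrying region labels are
#'   used directly for the distal extraction; set `FALSE` to force
#'   trajectory-based detection.
#' @param ... passed to [detect_regions()].
#' @return A `cohort_table` data frame with one record per successful row:
#'   `group`, `mouse_id`, `day`, `score`, `mean_pdff` (untrimmed distal
#'   mean), `n_voxels_total`, `n_voxels_retained`, `trim_percentile`.
#' @export
score_dataset <- function(dataset, params = heterogeneity_params(),
                          bounds = NULL, use_labels = TRUE, ...) {
  manifest <- dataset$manifest
  stopifnot(is.data.frame(manifest))
  recs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- tryCatch({
      vol <- read_volume(row$volume_path, validate = FALSE)
      msk <- read_mask(row$mask_path)
      validate_volume(vol, msk)
      distal <- if (use_labels && !is.null(msk$region)) {
        m <- msk$region == .region_codes[["distal"]]
        roi_mask(m, bone_axis = msk$bone_axis)
      } else {
        b <- if (!is.null(bounds)) bounds[[i]]
             else detect_regions(axial_mean_trajectory(vol, msk), ...)
        extract_region_mask(msk, b, "distal")
      }
      vals <- roi_values(vol, distal)
      sc <- trimmed_variance(vals, params)
      data.frame(group = row$group, mouse_id = row$mouse_id, day = row$day,
                 score = as.numeric(sc), mean_pdff = mean(vals),
                 n_voxels_total = attr(sc, "n_total"),
                 n_voxels_retained = attr(sc, "n_retained"),
                 trim_percentile = params$trim_percentile,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("row %d (%s, day %s) dropped: %s",
                      i, row$mouse_id, as.character(row$day), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    recs[[i]] <- rec
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs))
    return(as_cohort_table(data.frame(group = character(0), mouse_id = character(0),
                                      day = integer(0), score = numeric(0))))
  as_cohort_table(do.call(rbind, recs))
}

#' Extract a heatmap slice
#'
#' One bone-axis slice of in-mask PDFF values for pseudo-colour display.
#' In-mask pixels carry the raw voxel values (identity mapping); pixels
#' outside the mask are `NA` (transparent), never 0, since 0 percent is a
#' valid PDFF. The display scale is fixed at [0, 100] regardless of the
#' data range.
#'
#' @param volume a [pdff_volume()].
#' @param mask an [roi_mask()].
#' @param slice_index 0-based slice index along the bone axis; must
#'   intersect the mask.
#' @return numeric matrix with attributes `scale = c(0, 100)` and
#'   `slice_index`.
#' @export
heatmap_slice <- function(volume, mask, slice_index) {
  stopifnot(inherits(volume, "pdff_volume"), inherits(mask, "roi_mask"))
  ax <- volume$bone_axis
  n_ax <- dim(volume$values)[ax]
  s <- as.integer(slice_index) + 1L
  if (s < 1L || s > n_ax) stop(sprintf("slice %d outside the volume", slice_index))
  take <- function(a) switch(ax, a[s, , ], a[, s, ], a[, , s])
  m <- take(mask$membership)
  if (!any(m)) stop(sprintf("slice %d contains no mask voxels", slice_index))
  v <- take(volume$values)
  v[!m] <- NA_real_
  structure(v, scale = c(0, 100), slice_index = as.integer(slice_index))
}
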