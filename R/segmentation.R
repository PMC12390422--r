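#' Axial mean PDFF trajectory along the bone
#'
#' For every bone-axis slice intersecting the mask, the arithmetic mean of
#' the in-mask PDFF values and the contributing voxel count. Slices with no
#' mask voxels are omitted (never zero-filled) so plateau estimates are not
#' biased. Slice indices are 0-based and ascend proximal to distal.
#'
#' @param volume a [pdff_volume()].
#' @param mask an [roi_mask()] of the same shape.
#' @return data frame (class `axial_trajectory`) with columns
#'   `slice_index`, `mean_pdff`, `n_voxels`.
#' @export
axial_mean_trajectory <- function(volume, mask) {
  stopifnot(inherits(volume, "pdff_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$values), dim(mask$membership)))
    stop("volume and mask shapes differ")
  if (!any(mask$membership)) stop("mask is empty")
  ax <- volume$bone_axis
  n_ax <- dim(volume$values)[ax]
  sums <- apply(ifelse(mask$membership, volume$values, 0), ax, sum)
  counts <- apply(mask$membership, ax, sum)
  keep <- counts >= 1L
  out <- data.frame(slice_index = which(keep) - 1L,
                    mean_pdff = sums[keep] / counts[keep],
                    n_voxels = counts[keep])
  if (any(!is.finite(out$mean_pdff)))
    stop("non-finite in-mask PDFF values encountered in trajectory")
  class(out) <- c("axial_trajectory", "data.frame")
  out
}

#' Detect proximal / transition / distal region boundaries
#'
#' The trajectory is smoothed by an edge-truncated centred moving average
#' of width `smooth_window`. Plateau levels are estimated as the mean of
#' the first (`Lp`, proximal) and last (`Ld`, distal) `smooth_window`
#' smoothed values. The transition band lies between the fractional cuts
#' `Lp + f_low (Ld - Lp)` and `Lp + f_high (Ld - Lp)`: `p_end` is the
#' first slice whose smoothed value crosses the low cut toward the distal
#' level, `d_start` the first slice at/after `p_end` crossing the high
#' cut. Regions are half-open on 0-based slice indices:
#' proximal `[mask start, p_end)`, transition `[p_end, d_start)`, distal
#' `[d_start, mask end]`. Boundaries are clamped so ordering holds and the
#' distal region is never empty.
#'
#' @param traj an [axial_mean_trajectory()] spanning >= 3 slices.
#' @param smooth_window moving-average width in slices (default 3).
#' @param f_low,f_high transition cut fractions, `0 < f_low < f_high < 1`.
#' @param flat_tol absolute plateau difference (percent) below which the
#'   trajectory is declared flat: no transition is detectable and the whole
#'   mask is reported as distal with `flat = TRUE`.
#' @return An object of class `region_boundaries`: list with `p_end`,
#'   `d_start`, `mask_start`, `mask_end`, `level_proximal`,
#'   `level_distal`, `flat`.
#' @export
detect_regions <- function(traj, smooth_window = 3L, f_low = 0.25,
                           f_high = 0.75, flat_tol = 1e-3) {
  stopifnot(inherits(traj, "data.frame"))
  if (nrow(traj) < 3) stop("trajectory must span at least 3 slices")
  if (!(f_low > 0 && f_low < f_high && f_high < 1))
    stop("need 0 < f_low < f_high < 1")
  smooth_window <- max(1L, as.integer(smooth_window))
  y <- traj$mean_pdff
  n <- length(y)
  half <- (smooth_window - 1L) %/% 2L
  s <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(y[lo:hi])
  }, 0)
  k <- min(smooth_window, n)
  Lp <- mean(s[seq_len(k)])
  Ld <- mean(s[seq(n - k + 1L, n)])
  idx <- traj$slice_index
  mk_bounds <- function(p_end, d_start, flat) {
    structure(list(p_end = p_end, d_start = d_start,
                   mask_start = idx[1], mask_end = idx[n],
                   level_proximal = Lp, level_distal = Ld, flat = flat),
              class = "region_boundaries")
  }
  if (abs(Ld - Lp) < flat_tol) {
    # no transition detectable: caller may treat the whole mask as one region
    return(mk_bounds(idx[1], idx[1], flat = TRUE))
  }
  low_cut <- Lp + f_low * (Ld - Lp)
  high_cut <- Lp + f_high * (Ld - Lp)
  crossed <- function(v, cut) if (Ld > Lp) v > cut else v < cut
  ip <- which(crossed(s, low_cut))
  ip <- if (length(ip)) ip[1] else n
  id <- which(crossed(s, high_cut) & seq_len(n) >= ip)
  id <- if (length(id)) id[1] else n
  # monotone repair: ordering invariant and non-empty distal region
  ip <- min(ip, id)
  mk_bounds(idx[ip], idx[id], flat = FALSE)
}

#' Extract one region of the marrow mask
#'
#' Keeps exactly the member voxels whose bone-axis slice (0-based) falls in
#' the requested half-open region. Over the three regions the voxel counts
#' partition the original mask.
#'
#' @param mask an [roi_mask()].
#' @param bounds a [detect_regions()] result valid for this mask.
#' @param region `"proximal"`, `"transition"` or `"distal"`.
#' @return An [roi_mask()] restricted to the region.
#' @export
extract_region_mask <- function(mask, bounds,
                                region = c("distal", "proximal", "transition")) {
  stopifnot(inherits(mask, "roi_mask"), inherits(bounds, "region_boundaries"))
  region <- match.arg(region)
  ax <- mask$bone_axis
  n_ax <- dim(mask$membership)[ax]
  slice0 <- seq_len(n_ax) - 1L  # 0-based slice indices
  keep_slice <- switch(region,
    proximal   = slice0 >= bounds$mask_start & slice0 < bounds$p_end,
    transition = slice0 >= bounds$p_end & slice0 < bounds$d_start,
    distal     = slice0 >= bounds$d_start & slice0 <= bounds$mask_end)
  sel <- array(FALSE, dim = dim(mask$membership))
  take <- which(keep_slice)
  if (ax == 3L) sel[, , take] <- TRUE
  else if (ax == 2L) sel[, take, ] <- TRUE
  else sel[take, , ] <- TRUE
  membership <- mask$membership & sel
  if (!any(membership))
    stop(sprintf("requested region '%s' contains no mask voxels", region))
  reg <- if (is.null(mask$region)) NULL else {
    r <- mask$region; r[!membership] <- 0L; r
  }
  roi_mask(membership, region = reg, bone_axis = ax)
}
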