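#' Scaled-Beta voxel law: moment parameterisation
#'
#' PDFF voxel values are drawn from a Beta distribution rescaled to
#' [0, 100] and parameterised by its mean (percent) and variance
#' (percent^2). The Beta family respects the physical range without
#' truncation bias, so clipping never triggers in practice.
#'
#' @param mean_pdff mean in percent, strictly inside (0, 100).
#' @param variance variance in percent^2; must satisfy
#'   `variance < mean_pdff * (100 - mean_pdff)` (feasibility on a bounded
#'   support).
#' @return list with Beta shape parameters `alpha`, `beta`.
#' @keywords internal
beta_shape <- function(mean_pdff, variance) {
  if (mean_pdff < 0 || mean_pdff > 100)
    stop(sprintf("mean PDFF %g outside [0, 100]", mean_pdff))
  mu <- mean_pdff / 100
  s2 <- variance / 1e4
  if (s2 >= mu * (1 - mu))
    stop(sprintf(
      "variance %g percent^2 infeasible for a [0,100]-supported law at mean %g (bound %g)",
      variance, mean_pdff, mean_pdff * (100 - mean_pdff)))
  nu <- mu * (1 - mu) / s2 - 1
  list(alpha = mu * nu, beta = (1 - mu) * nu)
}

#' Trim-adjusted variance of the generating voxel law
#'
#' Population variance of a scaled-Beta voxel distribution after discarding
#' values above its `trim` percentile -- the large-sample value of the
#' trimmed-variance heterogeneity score on a phantom generated at
#' (`mean_pdff`, `variance`). Uses closed-form truncated Beta moments via
#' incomplete-beta ratios.
#'
#' @param mean_pdff generating mean, percent.
#' @param variance generating (untrimmed) variance, percent^2.
#' @param trim trim percentile (default 90).
#' @return trimmed population variance in percent^2.
#' @export
trim_adjusted_variance <- function(mean_pdff, variance, trim = 90) {
  if (variance == 0) return(0)
  sh <- beta_shape(mean_pdff, variance)
  a <- sh$alpha; b <- sh$beta
  q <- stats::qbeta(trim / 100, a, b)
  p0 <- stats::pbeta(q, a, b)
  m1 <- (a / (a + b)) * stats::pbeta(q, a + 1, b) / p0
  m2 <- (a * (a + 1) / ((a + b) * (a + b + 1))) * stats::pbeta(q, a + 2, b) / p0
  (m2 - m1^2) * 1e4
}

#' Invert the trim adjustment: generating variance for a target score
#'
#' One-sided trimming removes the upper tail and so deflates the variance;
#' a phantom calibrated to reproduce a target *trimmed* score must be
#' generated at a larger raw variance. This solves
#' `trim_adjusted_variance(mean, v) = target_score` for `v`.
#'
#' @param target_score desired trimmed-variance score, percent^2.
#' @param mean_pdff generating mean, percent.
#' @param trim trim percentile.
#' @return generating variance in percent^2.
#' @export
calibrate_generating_variance <- function(target_score, mean_pdff, trim = 90) {
  if (target_score <= 0) stop("target score must be positive")
  upper <- 0.98 * mean_pdff * (100 - mean_pdff)
  f <- function(v) trim_adjusted_variance(mean_pdff, v, trim) - target_score
  if (f(upper) < 0)
    stop("target score unreachable at this mean under the scaled-Beta law")
  stats::uniroot(f, c(target_score, upper), tol = 1e-10)$root
}

#' Disease-course specification
#'
#' Deterministic per-day targets for the distal marrow mean PDFF and voxel
#' variance of one simulated cohort. Nonresponder courses decay
#' exponentially from baseline toward a floor (marrow fat replaced by
#' hypercellular tissue); responder courses mirror the form, recovering
#' from a depressed post-irradiation state toward the healthy asymptote;
#' healthy courses are constant. Day 0 is the post-irradiation baseline,
#' modelled for disease courses as a multiplicative variance inflation
#' around the course's own day-0 value.
#'
#' @param group_kind `"healthy"`, `"nonresponder"` or `"responder"`.
#' @param days strictly increasing integer study days starting at 0.
#' @param mu0 baseline (healthy/nonresponder) or asymptotic (responder)
#'   distal mean PDFF, percent.
#' @param mu_floor asymptotic (nonresponder) or day-0 (responder) mean,
#'   percent; `0 <= mu_floor <= mu0 <= 100`.
#' @param decay_rate per-day exponential rate for the mean course, >= 0.
#' @param v0 baseline/asymptotic distal voxel variance, percent^2, > 0.
#' @param v_floor variance floor (nonresponder) or day-0 variance level
#'   (responder), percent^2, >= 0.
#' @param v_decay_rate per-day rate for the variance course, >= 0.
#' @param day0_inflation multiplicative variance inflation at day 0
#'   (irradiated marrow), >= 1 sensible; ignored for healthy courses.
#' @param dropout_prob per-(mouse, post-baseline day) probability of a
#'   missing scan, in [0, 1).
#' @param label cohort label used in manifests (defaults to `group_kind`).
#' @return An object of class `disease_course`.
#' @export
disease_course <- function(group_kind = c("healthy", "nonresponder", "responder"),
                           days, mu0, mu_floor, decay_rate,
                           v0, v_floor, v_decay_rate,
                           day0_inflation = 1, dropout_prob = 0,
                           label = NULL) {
  group_kind <- match.arg(group_kind)
  days <- as.integer(days)
  if (length(days) < 1 || days[1] != 0L || any(diff(days) <= 0))
    stop("`days` must be strictly increasing integers with days[1] = 0")
  if (!(mu_floor >= 0 && mu_floor <= mu0 && mu0 <= 100))
    stop("need 0 <= mu_floor <= mu0 <= 100")
  if (v0 <= 0) stop("v0 must be > 0")
  if (v_floor < 0) stop("v_floor must be >= 0")
  if (decay_rate < 0 || v_decay_rate < 0) stop("decay rates must be >= 0")
  if (day0_inflation <= 0) stop("day0_inflation must be > 0")
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must lie in [0, 1)")
  structure(list(group_kind = group_kind, days = days,
                 mu0 = mu0, mu_floor = mu_floor, decay_rate = decay_rate,
                 v0 = v0, v_floor = v_floor, v_decay_rate = v_decay_rate,
                 day0_inflation = day0_inflation, dropout_prob = dropout_prob,
                 label = if (is.null(label)) group_kind else as.character(label)),
            class = "disease_course")
}

#' Default calibrated cohorts
#'
#' Defaults encode the study conditions the analysis assumes. Healthy
#' distal marrow: mean PDFF 50 percent with the generating variance
#' calibrated so the 90th-percentile-trimmed score has expectation 49.0
#' percent^2 (the published healthy reference). Nonresponders: day-0
#' irradiated marrow with raw variance ~120 percent^2 (v0 = 60 inflated
#' x2), collapsing toward a floor of 3 percent^2 as hematopoietic cells
#' replace fat; mean PDFF decays from an intermediate 30 percent toward
#' ~2 percent. Responders mirror the recovery toward the healthy baseline.
#' Disease cohorts default to 8 percent per-scan dropout, matching the
#' missingness rate of the published table.
#'
#' @param days study days (defaults: healthy day 0 only; disease cohorts
#'   use the two published schedules).
#' @param dropout_prob per-scan dropout probability.
#' @param label cohort label.
#' @return A `disease_course`.
#' @export
healthy_course <- function(days = 0L, label = "healthy") {
  v0 <- calibrate_generating_variance(49, 50, trim = 90)
  disease_course("healthy", days = days, mu0 = 50, mu_floor = 50,
                 decay_rate = 0, v0 = v0, v_floor = v0, v_decay_rate = 0,
                 day0_inflation = 1, dropout_prob = 0, label = label)
}

#' @rdname healthy_course
#' @export
nonresponder_course <- function(days = c(0L, 64L, 69L, 74L),
                                dropout_prob = 0.08, label = "nonresponder") {
  disease_course("nonresponder", days = days,
                 mu0 = 30, mu_floor = 2, decay_rate = 0.06,
                 v0 = 60, v_floor = 3, v_decay_rate = 0.08,
                 day0_inflation = 2, dropout_prob = dropout_prob, label = label)
}

#' @rdname healthy_course
#' @export
responder_course <- function(days = c(0L, 64L, 69L, 74L),
                             dropout_prob = 0.08, label = "responder") {
  v_healthy <- calibrate_generating_variance(49, 50, trim = 90)
  disease_course("responder", days = days,
                 mu0 = 50, mu_floor = 15, decay_rate = 0.03,
                 v0 = v_healthy, v_floor = 20, v_decay_rate = 0.03,
                 day0_inflation = 2, dropout_prob = dropout_prob, label = label)
}

#' Evaluate a disease course at one study day
#'
#' Deterministic closed-form targets. Nonresponder:
#' `mu(d) = mu_floor + (mu0 - mu_floor) exp(-decay_rate d)` and the
#' analogous variance course, except the day-0 variance is inflated by
#' `day0_inflation`. Responder: the mirrored form rising toward
#' (`mu0`, `v0`). Healthy: constants.
#'
#' @param spec a [disease_course()].
#' @param day one of `spec$days`.
#' @return list with `mean_pdff` (percent) and `target_variance`
#'   (percent^2).
#' @export
simulate_course <- function(spec, day) {
  stopifnot(inherits(spec, "disease_course"))
  if (length(day) != 1 || !day %in% spec$days)
    stop(sprintf("day %s is not a scheduled study day (%s)",
                 as.character(day), paste(spec$days, collapse = ", ")))
  d <- as.numeric(day)
  out <- switch(spec$group_kind,
    healthy = list(mean_pdff = spec$mu0, target_variance = spec$v0),
    nonresponder = {
      mu <- spec$mu_floor + (spec$mu0 - spec$mu_floor) * exp(-spec$decay_rate * d)
      v  <- spec$v_floor + (spec$v0 - spec$v_floor) * exp(-spec$v_decay_rate * d)
      if (d == 0) v <- spec$v0 * spec$day0_inflation
      list(mean_pdff = mu, target_variance = v)
    },
    responder = {
      mu <- spec$mu0 - (spec$mu0 - spec$mu_floor) * exp(-spec$decay_rate * d)
      v  <- spec$v0 - (spec$v0 - spec$v_floor) * exp(-spec$v_decay_rate * d)
      if (d == 0) v <- spec$v_floor * spec$day0_inflation
      list(mean_pdff = mu, target_variance = v)
    })
  out
}

#' Phantom tibia geometry
#'
#' A digital stand-in for the imaged tibia: a straight marrow tube of
#' `marrow_radius_voxels` along `bone_axis`, split into proximal
#' (hematopoietic, low PDFF), transition, and distal (fat-rich) slice
#' blocks whose counts sum to the grid extent along the bone.
#'
#' @param grid_shape integer length-3 grid dimensions (voxels).
#' @param voxel_size voxel edge lengths in mm.
#' @param bone_axis axis carrying the proximal-to-distal direction.
#' @param n_slices_proximal,n_slices_transition,n_slices_distal slice
#'   counts per region; must sum to the bone-axis extent.
#' @param marrow_radius_voxels tube radius in voxels.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid_shape = c(24L, 24L, 48L),
                             voxel_size = c(0.1, 0.1, 0.1),
                             bone_axis = 3L,
                             n_slices_proximal = 16L,
                             n_slices_transition = 6L,
                             n_slices_distal = 26L,
                             marrow_radius_voxels = 5L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be three integers >= 1")
  bone_axis <- as.integer(bone_axis)
  if (!bone_axis %in% 1:3) stop("`bone_axis` must be 1, 2 or 3")
  ns <- as.integer(c(n_slices_proximal, n_slices_transition, n_slices_distal))
  if (any(ns < 0L)) stop("region slice counts must be >= 0")
  if (sum(ns) != grid_shape[bone_axis])
    stop(sprintf("region slice counts (%d) must sum to the bone-axis extent (%d)",
                 sum(ns), grid_shape[bone_axis]))
  if (marrow_radius_voxels < 1L) stop("marrow radius must be >= 1 voxel")
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 bone_axis = bone_axis,
                 n_slices_proximal = ns[1], n_slices_transition = ns[2],
                 n_slices_distal = ns[3],
                 marrow_radius_voxels = as.integer(marrow_radius_voxels)),
            class = "phantom_geometry")
}

# Run code under a local RNG state so generators are seeded and
# side-effect free with respect to the caller's stream.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Deterministic substream seeds below 2^31, exact in double arithmetic.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- seed %% 1000003
  for (k in idx) h <- (h * 10007 + (k %% 1000003) + 1) %% 2147483629
  as.integer(h)
}

#' Generate one phantom tibia volume and mask
#'
#' Marrow voxels lie inside a tube of the geometry's radius along the bone
#' axis. Distal-zone voxels are i.i.d. scaled-Beta with the requested mean
#' and variance; the proximal zone is drawn around a fixed low mean
#' (hematopoietic marrow); transition-zone slice means (and variances)
#' interpolate linearly between the zone levels slice by slice. Voxels
#' outside the mask are `NA`. Identical seeds give identical volumes.
#'
#' @param geom a [phantom_geometry()].
#' @param mean_pdff distal-zone mean PDFF, percent.
#' @param target_variance distal-zone voxel variance, percent^2
#'   (0 gives an exactly constant zone).
#' @param seed integer seed.
#' @param proximal_mean,proximal_variance law of the proximal zone.
#' @return list with elements `volume` ([pdff_volume()]) and `mask`
#'   ([roi_mask()] with region labels).
#' @export
generate_volume <- function(geom, mean_pdff, target_variance, seed,
                            proximal_mean = 5, proximal_variance = 9) {
  stopifnot(inherits(geom, "phantom_geometry"))
  if (mean_pdff < 0 || mean_pdff > 100)
    stop(sprintf("requested mean %g outside [0, 100]", mean_pdff))
  if (target_variance < 0) stop("target_variance must be >= 0")
  if (target_variance > 0) beta_shape(mean_pdff, target_variance)  # feasibility
  dims <- geom$grid_shape
  ax <- geom$bone_axis
  perp <- setdiff(1:3, ax)
  centre <- (dims[perp] + 1) / 2
  # tube cross-section
  idx <- expand.grid(i = seq_len(dims[perp[1]]), j = seq_len(dims[perp[2]]))
  inside <- (idx$i - centre[1])^2 + (idx$j - centre[2])^2 <= geom$marrow_radius_voxels^2
  cross <- matrix(inside, nrow = dims[perp[1]], ncol = dims[perp[2]])

  n_ax <- dims[ax]
  zone <- rep(c(1L, 2L, 3L),
              times = c(geom$n_slices_proximal, geom$n_slices_transition,
                        geom$n_slices_distal))
  # per-slice target moments
  n_t <- geom$n_slices_transition
  w <- if (n_t > 0) seq_len(n_t) / (n_t + 1) else numeric(0)
  slice_mean <- numeric(n_ax); slice_var <- numeric(n_ax)
  slice_mean[zone == 1L] <- proximal_mean
  slice_var[zone == 1L] <- proximal_variance
  slice_mean[zone == 2L] <- proximal_mean + w * (mean_pdff - proximal_mean)
  slice_var[zone == 2L] <- proximal_variance + w * (target_variance - proximal_variance)
  slice_mean[zone == 3L] <- mean_pdff
  slice_var[zone == 3L] <- target_variance

  membership <- array(FALSE, dim = dims)
  region <- array(0L, dim = dims)
  vals <- array(NA_real_, dim = dims)
  n_in <- sum(cross)
  with_local_seed(seed, {
    for (s in seq_len(n_ax)) {
      draw <- if (slice_var[s] == 0) rep(slice_mean[s], n_in)
              else {
                sh <- beta_shape(slice_mean[s], slice_var[s])
                100 * stats::rbeta(n_in, sh$alpha, sh$beta)
              }
      draw <- pmin(pmax(draw, 0), 100)  # guard; never triggers for Beta draws
      sl_m <- cross
      sl_v <- matrix(NA_real_, dims[perp[1]], dims[perp[2]])
      sl_v[cross] <- draw
      if (ax == 3L) {
        membership[, , s] <- sl_m; vals[, , s] <- sl_v; region[, , s][cross] <- zone[s]
      } else if (ax == 2L) {
        membership[, s, ] <- sl_m; vals[, s, ] <- sl_v
        r <- region[, s, ]; r[cross] <- zone[s]; region[, s, ] <- r
      } else {
        membership[s, , ] <- sl_m; vals[s, , ] <- sl_v
        r <- region[s, , ]; r[cross] <- zone[s]; region[s, , ] <- r
      }
    }
  })
  list(volume = pdff_volume(vals, voxel_size = geom$voxel_size, bone_axis = ax),
       mask = roi_mask(membership, region = region, bone_axis = ax))
}

#' Simulate a longitudinal phantom study
#'
#' Builds a cohort manifest by drawing, for each mouse and surviving study
#' day, one phantom volume/mask pair at the course's per-day targets.
#' Per-mouse substreams are derived deterministically from
#' (`seed`, cohort index, mouse index), so cohorts reproduce row for row.
#' Dropout is missing-completely-at-random per post-baseline day. Spleen
#' volumes are scalar lognormal trajectories consistent with the course
#' kind: non-decreasing for nonresponders, a guaranteed >= 50 percent drop
#' from baseline by the final surviving day for responders, and flat for
#' healthy mice.
#'
#' @param course_specs list of cohorts, each a `list(spec = disease_course,
#'   n_mice = integer)`.
#' @param geom a [phantom_geometry()].
#' @param seed integer master seed.
#' @param dir directory for NIfTI volumes/masks (created if needed).
#' @param write_volumes set `FALSE` to skip image generation and produce a
#'   manifest of course targets only (no paths).
#' @return An object of class `study_dataset`: list with `manifest`
#'   (data frame: mouse_id, group, day, volume_path, mask_path,
#'   spleen_volume, mean_pdff_target, variance_target), `dir`, `seed`.
#' @export
simulate_study <- function(course_specs, geom = phantom_geometry(), seed = 1L,
                           dir = tempfile("phantom_study_"), write_volumes = TRUE) {
  stopifnot(inherits(geom, "phantom_geometry"))
  if (length(course_specs) == 0 ||
      all(vapply(course_specs, function(cs) as.integer(cs$n_mice), 0L) == 0)) {
    manifest <- data.frame(mouse_id = character(0), group = character(0),
                           day = integer(0), volume_path = character(0),
                           mask_path = character(0), spleen_volume = numeric(0),
                           mean_pdff_target = numeric(0), variance_target = numeric(0),
                           stringsAsFactors = FALSE)
    return(structure(list(manifest = manifest, dir = dir, seed = seed),
                     class = "study_dataset"))
  }
  if (write_volumes) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ci in seq_along(course_specs)) {
    cs <- course_specs[[ci]]
    spec <- cs$spec
    stopifnot(inherits(spec, "disease_course"))
    n_mice <- as.integer(cs$n_mice)
    if (n_mice < 0) stop("n_mice must be >= 0")
    for (mi in seq_len(n_mice)) {
      mouse_id <- sprintf("%s_m%02d", spec$label, mi)
      mseed <- derive_seed(seed, ci, mi)
      days <- spec$days
      keep <- with_local_seed(mseed, {
        k <- rep(TRUE, length(days))
        if (length(days) > 1 && spec$dropout_prob > 0)
          k[-1] <- stats::runif(length(days) - 1) >= spec$dropout_prob
        k
      })
      surv_days <- days[keep]
      spleen <- simulate_spleen(spec, surv_days, derive_seed(mseed, 7L))
      for (di in seq_along(surv_days)) {
        day <- surv_days[di]
        tgt <- simulate_course(spec, day)
        vpath <- mpath <- NA_character_
        if (write_volumes) {
          ph <- generate_volume(geom, tgt$mean_pdff, tgt$target_variance,
                                seed = derive_seed(mseed, 11L, which(days == day)))
          vpath <- file.path(dir, sprintf("%s_d%03d_pdff.nii.gz", mouse_id, day))
          mpath <- file.path(dir, sprintf("%s_d%03d_mask.nii.gz", mouse_id, day))
          write_volume(ph$volume, vpath)
          write_mask(ph$mask, mpath)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          mouse_id = mouse_id, group = spec$label, day = day,
          volume_path = vpath, mask_path = mpath,
          spleen_volume = spleen[di],
          mean_pdff_target = tgt$mean_pdff, variance_target = tgt$target_variance,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, dir = dir, seed = seed),
            class = "study_dataset")
}

# Spleen volume trajectories (mm^3), one value per surviving day.
# Healthy: flat around 100 mm^3. Nonresponder: splenomegaly, strictly
# non-decreasing multiplicative growth. Responder: geometric decline to a
# final value 30-45% of baseline (>= 50% reduction guaranteed).
simulate_spleen <- function(spec, days, seed) {
  n <- length(days)
  if (n == 0) return(numeric(0))
  with_local_seed(seed, {
    switch(spec$group_kind,
      healthy = stats::rlnorm(1, log(100), 0.10) * exp(stats::rnorm(n, 0, 0.03)),
      nonresponder = {
        base <- stats::rlnorm(1, log(300), 0.15)
        out <- numeric(n); out[1] <- base
        if (n > 1) for (k in 2:n) {
          dd <- days[k] - days[k - 1]
          out[k] <- out[k - 1] * exp(0.004 * dd + abs(stats::rnorm(1, 0, 0.03)))
        }
        out
      },
      responder = {
        base <- stats::rlnorm(1, log(300), 0.15)
        ratio <- stats::runif(1, 0.30, 0.45)
        if (n == 1) base
        else {
          frac <- (days - days[1]) / (days[n] - days[1])
          traj <- base * ratio^frac
          if (n > 2) {
            mid <- 2:(n - 1)
            traj[mid] <- traj[mid] * exp(stats::rnorm(length(mid), 0, 0.04))
            traj[mid] <- pmin(traj[mid], base)  # keep the decline plausible
          }
          traj
        }
      })
  })
}
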