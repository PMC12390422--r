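#' Two-group permutation test on the difference in means
#'
#' Nonparametric test with statistic `mean(a) - mean(b)`. Group labels are
#' permuted over the pooled values preserving group sizes. When the number
#' of distinct labelings is at most `exhaustive_limit`, all labelings are
#' enumerated and the p-value is the exact proportion as-or-more extreme
#' (the observed labeling counts itself); otherwise `n_perm` Monte-Carlo
#' draws are used with the add-one convention `p = (1 + b) / (1 + B)`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param sides `"two_sided"`, `"one_sided_greater"` (alternative
#'   `mean(a) > mean(b)`) or `"one_sided_less"`.
#' @param n_perm Monte-Carlo replicates (default 10000).
#' @param seed integer seed for the Monte-Carlo path.
#' @param exhaustive_limit enumerate exactly when `choose(n, |a|)` does not
#'   exceed this (default 200000); set 0 to force Monte Carlo.
#' @return An object of class `permutation_result`: `statistic_obs`,
#'   `p_value`, `n_perm` (replicates actually used), `sides`, `seed`,
#'   `exhaustive`, `n_a`, `n_b`, `degenerate`.
#' @export
permutation_test <- function(a, b,
                             sides = c("two_sided", "one_sided_greater", "one_sided_less"),
                             n_perm = 10000L, seed = 1L,
                             exhaustive_limit = 200000) {
  sides <- match.arg(sides)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("both groups need at least 2 values")
  if (any(!is.finite(c(a, b)))) stop("values must be finite")
  if (n_perm < 1) stop("n_perm must be >= 1")
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  obs <- mean(a) - mean(b)
  mk <- function(p, used, exhaustive, degenerate = FALSE) {
    structure(list(statistic_obs = obs, p_value = p, n_perm = used,
                   sides = sides, seed = as.integer(seed),
                   exhaustive = exhaustive, n_a = na, n_b = length(b),
                   degenerate = degenerate),
              class = "permutation_result")
  }
  if (isTRUE(all(pooled == pooled[1]))) {
    warning("all pooled values identical; permutation distribution is degenerate")
    return(mk(1, 0L, exhaustive = TRUE, degenerate = TRUE))
  }
  total <- sum(pooled)
  # numerical tie tolerance for as-or-more-extreme comparisons
  eps <- 1e-9 * max(1, abs(obs))
  extreme <- function(st) switch(sides,
    two_sided = abs(st) >= abs(obs) - eps,
    one_sided_greater = st >= obs - eps,
    one_sided_less = st <= obs + eps)
  stat_from_sum <- function(sa) sa / na - (total - sa) / (n - na)
  n_label <- choose(n, na)
  if (exhaustive_limit > 0 && n_label <= exhaustive_limit) {
    sums <- utils::combn(n, na, FUN = function(ix) sum(pooled[ix]))
    st <- stat_from_sum(sums)
    p <- sum(extreme(st)) / n_label
    return(mk(p, as.integer(n_label), exhaustive = TRUE))
  }
  st <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
    stat_from_sum(sum(pooled[sample.int(n, na)]))
  }, 0))
  p <- (1 + sum(extreme(st))) / (1 + n_perm)
  mk(p, as.integer(n_perm), exhaustive = FALSE)
}

#' Principal component embedding of heterogeneity features
#'
#' Column-mean centred PCA (no rescaling: the features share percent^2
#' units) via singular value decomposition. Rows with missing entries are
#' excluded with a logged count -- there is no imputation. Component signs
#' are fixed so the largest-magnitude loading entry of each component is
#' positive.
#'
#' @param features numeric matrix, subjects x features; rownames identify
#'   subjects.
#' @param n_components number of components to retain,
#'   `<= min(dim(features))`.
#' @return An object of class `pca_result`: `scores` (complete subjects x
#'   components), `loadings`, `explained_variance` (fractions of total),
#'   `n_components`, `n_dropped`, `center`.
#' @export
pca_embed <- function(features, n_components = 2L) {
  features <- as.matrix(features)
  if (is.null(rownames(features))) rownames(features) <- seq_len(nrow(features))
  complete <- stats::complete.cases(features)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("pca_embed: excluding %d row(s) with missing entries", n_dropped))
  x <- features[complete, , drop = FALSE]
  if (nrow(x) < 2) stop("fewer than 2 complete rows; PCA is undefined")
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > min(dim(x)))
    stop("n_components must lie in 1..min(dim(features))")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  # sign convention: largest-|entry| of each loading vector positive
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  v <- sweep(sv$v, 2, flip, `*`)
  u <- sweep(sv$u, 2, flip, `*`)
  lam <- sv$d^2 / max(1, nrow(x) - 1)
  total <- sum(lam)
  keep <- seq_len(n_components)
  scores <- u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", keep)
  loadings <- v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", keep)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = if (total > 0) lam[keep] / total else rep(0, n_components),
                 n_components = n_components, n_dropped = n_dropped, center = ctr),
            class = "pca_result")
}

#' Permutation p-value for class separation in PC space
#'
#' The embedding is fixed from all complete rows; the statistic is the
#' Euclidean distance between class centroids in the retained component
#' space. Class labels are permuted and
#' `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`.
#'
#' @param features subjects x features matrix.
#' @param labels vector with exactly two classes over the complete rows,
#'   each of size >= 2.
#' @param n_components retained components.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `p_value`, `statistic_obs`, `n_perm`, `seed`,
#'   `n_components`, `classes`, `method`.
#' @export
pca_separation_pvalue <- function(features, labels, n_components = 2L,
                                  n_perm = 10000L, seed = 1L) {
  features <- as.matrix(features)
  if (length(labels) != nrow(features)) stop("labels must match feature rows")
  complete <- stats::complete.cases(features)
  labels <- as.character(labels[complete])
  cls <- unique(labels)
  if (length(cls) != 2) stop("exactly two label classes are required")
  if (min(table(labels)) < 2) stop("each class needs >= 2 complete rows")
  emb <- pca_embed(features, n_components = n_components)
  sc <- emb$scores
  centroid_dist <- function(lab) {
    d <- colMeans(sc[lab == cls[1], , drop = FALSE]) -
         colMeans(sc[lab == cls[2], , drop = FALSE])
    sqrt(sum(d^2))
  }
  obs <- centroid_dist(labels)
  st <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
    centroid_dist(sample(labels))
  }, 0))
  p <- (1 + sum(st >= obs - 1e-12 * max(1, obs))) / (1 + n_perm)
  list(p_value = p, statistic_obs = obs, n_perm = as.integer(n_perm),
       seed = as.integer(seed), n_components = as.integer(n_components),
       classes = cls, method = "centroid distance, label permutation")
}

#' Per-mouse longitudinal course
#'
#' @param mouse_id identifier.
#' @param days strictly increasing study days, >= 1 entry.
#' @param mean_pdff per-day distal mean PDFF (percent), or `NULL`.
#' @param score per-day heterogeneity score (percent^2), or `NULL`.
#' @param spleen_volume per-day spleen volume (mm^3), or `NULL`.
#' @return An object of class `mouse_course`.
#' @export
mouse_course <- function(mouse_id, days, mean_pdff = NULL, score = NULL,
                         spleen_volume = NULL) {
  days <- as.numeric(days)
  if (length(days) < 1 || any(diff(days) <= 0))
    stop("days must be strictly increasing with at least one entry")
  for (v in list(mean_pdff, score, spleen_volume))
    if (!is.null(v) && length(v) != length(days))
      stop("per-day vectors must match `days` in length")
  structure(list(mouse_id = as.character(mouse_id), days = days,
                 mean_pdff = mean_pdff, score = score,
                 spleen_volume = spleen_volume),
            class = "mouse_course")
}

#' Ordinary least squares fit of a mouse's score over time
#'
#' Line of best fit of the heterogeneity score on study day,
#' per mouse, by exact least squares.
#'
#' @param course a [mouse_course()] with >= 2 (day, score) points.
#' @return An object of class `regression_fit`: `mouse_id`, `slope`
#'   (percent^2/day), `intercept` (percent^2), `n_points`.
#' @export
fit_mouse_regression <- function(course) {
  stopifnot(inherits(course, "mouse_course"))
  if (is.null(course$score)) stop("course carries no scores")
  d <- course$days; y <- course$score
  ok <- is.finite(d) & is.finite(y)
  d <- d[ok]; y <- y[ok]
  if (length(d) < 2)
    stop(sprintf("mouse %s has fewer than 2 points", course$mouse_id))
  if (length(unique(d)) < 2) stop("all days equal; slope undefined")
  fit <- stats::lm(y ~ d)
  structure(list(mouse_id = course$mouse_id,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = length(d)),
            class = "regression_fit")
}

#' Combine per-mouse regressions into a group line
#'
#' The group line of best fit is the unweighted arithmetic mean of the
#' contributing per-mouse slopes and intercepts.
#'
#' @param fits non-empty list of [fit_mouse_regression()] results.
#' @param group group label to attach.
#' @return An object of class `group_line`: `group`, `slope`, `intercept`,
#'   `n_fits`, `mouse_ids`.
#' @export
combine_group_line <- function(fits, group = "group") {
  if (length(fits) == 0) stop("no fits to combine")
  stopifnot(all(vapply(fits, inherits, TRUE, "regression_fit")))
  structure(list(group = group,
                 slope = mean(vapply(fits, `[[`, 0, "slope")),
                 intercept = mean(vapply(fits, `[[`, 0, "intercept")),
                 n_fits = length(fits),
                 mouse_ids = vapply(fits, `[[`, "", "mouse_id")),
            class = "group_line")
}

#' Quartile summaries per group and scan day
#'
#' The violin-plot summaries: first quartile, median and third quartile of
#' the heterogeneity scores in every (group, day) cell with at least one
#' record, by linear interpolation between order statistics.
#'
#' @param table a `cohort_table`.
#' @return data frame with columns `group`, `day`, `q1`, `median`, `q3`,
#'   `n`, ordered by (group, day).
#' @export
summarize_violin <- function(table) {
  table <- as_cohort_table(as.data.frame(table))
  cells <- split(table$score, list(table$group, table$day), drop = TRUE)
  out <- do.call(rbind, lapply(names(cells), function(nm) {
    v <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = parts[1], day = as.integer(parts[2]),
               q1 = q[1], median = q[2], q3 = q[3], n = length(v),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$group, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a mouse's disease course
#'
#' Responder: final spleen volume at most 50 percent of baseline.
#' Diseased: spleen volume increased from baseline AND the least-squares
#' slope of distal mean PDFF over days is negative. The responder check
#' precedes the diseased check. With no spleen data only the PDFF
#' criterion applies, so the outcome is restricted to
#' diseased/indeterminate. A single time point is indeterminate.
#'
#' @param course a [mouse_course()] with per-day distal mean PDFF.
#' @return list with `status` (`"responder"`, `"diseased"` or
#'   `"indeterminate"`) and `reason`.
#' @export
classify_mouse <- function(course) {
  stopifnot(inherits(course, "mouse_course"))
  if (length(course$days) < 2)
    return(list(status = "indeterminate", reason = "single time point"))
  if (is.null(course$mean_pdff)) stop("course carries no distal mean PDFF")
  sp <- course$spleen_volume
  if (!is.null(sp) && length(sp) >= 2 && is.finite(sp[1]) && is.finite(sp[length(sp)])) {
    if (sp[length(sp)] <= 0.5 * sp[1])
      return(list(status = "responder",
                  reason = sprintf("spleen volume fell to %.0f%% of baseline",
                                   100 * sp[length(sp)] / sp[1])))
    spleen_up <- sp[length(sp)] > sp[1]
  } else {
    sp <- NULL
    spleen_up <- NA
  }
  slope <- unname(stats::coef(stats::lm(course$mean_pdff ~ course$days))[2])
  pdff_down <- is.finite(slope) && slope < 0
  if (is.null(sp)) {
    if (pdff_down)
      return(list(status = "diseased", reason = "declining distal PDFF (no spleen data)"))
    return(list(status = "indeterminate", reason = "no spleen data and non-declining PDFF"))
  }
  if (isTRUE(spleen_up) && pdff_down)
    return(list(status = "diseased", reason = "spleen growth with declining distal PDFF"))
  list(status = "indeterminate", reason = "criteria not met")
}
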