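#' Group-level inference on a cohort score table
#'
#' Runs the study's statistical battery on a table of per-(mouse, day)
#' heterogeneity scores: the two permutation tests (baseline disease
#' versus healthy, one-sided disease-greater; disease cohort 1 versus
#' cohort 2 over all cells, two-sided), a 1D baseline PCA of healthy
#' against combined disease with a centroid-distance separation p-value,
#' a trajectory PCA between the disease cohorts, per-mouse least-squares
#' lines with group averages, and quartile summaries.
#'
#' @param table a `cohort_table`.
#' @param n_perm Monte-Carlo permutation replicates.
#' @param seed integer seed for all resampling.
#' @param alpha significance level recorded in results (default 0.05).
#' @param pca_components components for the trajectory PCA (default 2).
#' @param exhaustive_limit passed to [permutation_test()].
#' @param healthy_group label of the healthy cohort (default "healthy").
#' @param baseline_day study day treated as pre-treatment baseline
#'   (default 0).
#' @return list with elements `permutation`, `pca`, `fits`,
#'   `group_lines`, `quartiles`, `params`.
#' @export
analyze_cohort_table <- function(table, n_perm = 10000L, seed = 1L,
                                 alpha = 0.05, pca_components = 2L,
                                 exhaustive_limit = 200000,
                                 healthy_group = "healthy",
                                 baseline_day = 0L) {
  table <- as_cohort_table(as.data.frame(table))
  groups <- unique(table$group)
  disease_groups <- setdiff(groups, healthy_group)
  out <- list(params = list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                            alpha = alpha, pca_components = as.integer(pca_components),
                            exhaustive_limit = exhaustive_limit,
                            healthy_group = healthy_group,
                            baseline_day = as.integer(baseline_day)))
  perm <- list(); pca <- list()

  healthy_scores <- table$score[table$group == healthy_group]
  disease_base <- table$score[table$group %in% disease_groups & table$day == baseline_day]
  if (length(healthy_scores) >= 2 && length(disease_base) >= 2) {
    # irradiated baseline marrow carries inflated variance: disease > healthy
    perm$disease_vs_healthy <- permutation_test(
      disease_base, healthy_scores, sides = "one_sided_greater",
      n_perm = n_perm, seed = derive_seed(seed, 1L),
      exhaustive_limit = exhaustive_limit)
  }
  if (length(disease_groups) >= 2) {
    g1 <- disease_groups[1]; g2 <- disease_groups[2]
    a <- table$score[table$group == g1]
    b <- table$score[table$group == g2]
    if (length(a) >= 2 && length(b) >= 2)
      perm$disease1_vs_disease2 <- permutation_test(
        a, b, sides = "two_sided", n_perm = n_perm,
        seed = derive_seed(seed, 2L), exhaustive_limit = exhaustive_limit)
  }

  # 1D baseline PCA: healthy vs combined disease
  base <- table[table$day == baseline_day, , drop = FALSE]
  if (nrow(base) >= 4 && length(unique(base$group == healthy_group)) == 2) {
    feats <- matrix(base$score, ncol = 1,
                    dimnames = list(paste(base$group, base$mouse_id), "baseline_score"))
    lab <- ifelse(base$group == healthy_group, "healthy", "disease")
    emb <- pca_embed(feats, n_components = 1L)
    pca$baseline_1d <- list(
      explained_variance = emb$explained_variance,
      scores = data.frame(subject = rownames(emb$scores),
                          label = lab, pc1 = emb$scores[, 1]),
      separation = pca_separation_pvalue(feats, lab, n_components = 1L,
                                         n_perm = n_perm,
                                         seed = derive_seed(seed, 3L)))
  }

  # trajectory PCA across the two disease cohorts (scan order as feature)
  if (length(disease_groups) >= 2) {
    tr <- trajectory_features(table, disease_groups[1:2])
    if (!is.null(tr) && nrow(tr$features) >= 4 && min(table(tr$labels)) >= 2) {
      nc <- min(pca_components, dim(tr$features))
      pca$disease_trajectory <- list(
        embedding = pca_embed(tr$features, n_components = nc)[
          c("explained_variance", "n_components", "n_dropped")],
        separation = pca_separation_pvalue(tr$features, tr$labels,
                                           n_components = nc, n_perm = n_perm,
                                           seed = derive_seed(seed, 4L)))
    }
  }

  # per-mouse lines and group averages (disease cohorts); the healthy
  # single-time-point cohort is summarised as a horizontal reference
  fits <- list(); lines <- list()
  for (g in disease_groups) {
    sub <- table[table$group == g, , drop = FALSE]
    gfits <- list()
    for (m in unique(sub$mouse_id)) {
      mm <- sub[sub$mouse_id == m, , drop = FALSE]
      if (nrow(mm) >= 2 && length(unique(mm$day)) >= 2) {
        f <- fit_mouse_regression(mouse_course(m, mm$day, score = mm$score))
        gfits[[m]] <- f
        fits[[length(fits) + 1L]] <- data.frame(
          group = g, mouse_id = m, slope = f$slope, intercept = f$intercept,
          n_points = f$n_points, stringsAsFactors = FALSE)
      }
    }
    if (length(gfits)) {
      gl <- combine_group_line(gfits, group = g)
      lines[[length(lines) + 1L]] <- data.frame(
        group = g, slope = gl$slope, intercept = gl$intercept,
        n_fits = gl$n_fits, stringsAsFactors = FALSE)
    }
  }
  if (length(healthy_scores)) {
    lines[[length(lines) + 1L]] <- data.frame(
      group = healthy_group, slope = 0, intercept = mean(healthy_scores),
      n_fits = length(healthy_scores), stringsAsFactors = FALSE)
  }
  out$permutation <- perm
  out$pca <- pca
  out$fits <- if (length(fits)) do.call(rbind, fits) else NULL
  out$group_lines <- if (length(lines)) do.call(rbind, lines) else NULL
  out$quartiles <- summarize_violin(table)
  out
}

# Per-mouse score trajectories over scan order for the disease cohorts.
# Mice missing any scheduled scan are dropped (no imputation).
trajectory_features <- function(table, groups) {
  rows <- list(); labs <- character(0)
  for (g in groups) {
    sub <- table[table$group == g, , drop = FALSE]
    days <- sort(unique(sub$day))
    for (m in unique(sub$mouse_id)) {
      mm <- sub[sub$mouse_id == m, , drop = FALSE]
      v <- mm$score[match(days, mm$day)]
      if (!anyNA(v)) {
        rows[[paste(g, m)]] <- v
        labs <- c(labs, g)
      }
    }
  }
  if (!length(rows)) return(NULL)
  k <- max(lengths(rows))
  rows <- rows[lengths(rows) == k]
  labs <- labs[seq_along(rows)]
  feats <- do.call(rbind, rows)
  colnames(feats) <- paste0("scan", seq_len(k))
  list(features = feats, labels = labs)
}

#' Read a pipeline run configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON by extension. See [run_pipeline()] for
#' the recognised keys.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop(sprintf("unsupported config format: .%s", ext))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> segment -> score -> infer -> report as one
#' reproducible run. Three modes: `"fixture"` runs the statistical battery
#' directly on the bundled per-mouse variance table (no image data;
#' completes in seconds); `"simulate"` generates a phantom study from
#' cohort specifications, scores every image, and runs the battery;
#' `"analyze"` does the same from an existing manifest of volumes and
#' masks. Identical config and seed give identical score tables.
#'
#' @param config named list or path to a YAML/JSON file. Keys: `mode`
#'   (required), `out_dir` (required), `seed` (required for simulate and
#'   any Monte-Carlo stage; default 1), `n_perm` (default 10000), `alpha`
#'   (0.05), `trim_percentile` (90), `pca_components` (2),
#'   `exhaustive_limit` (200000); simulate mode: `cohorts`, a list of
#'   `list(kind, label, n_mice, days, dropout_prob)` entries with kinds
#'   healthy/nonresponder/responder; analyze mode: `manifest` path.
#' @return Invisibly, a list with the score table, statistics,
#'   classification (simulate/analyze modes) and the files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_run_config(config)
  stopifnot(is.list(config))
  mode <- match.arg(config$mode, c("fixture", "simulate", "analyze"))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- as.integer(config$n_perm %||% 10000L)
  alpha <- config$alpha %||% 0.05
  trim <- config$trim_percentile %||% 90
  pcs <- as.integer(config$pca_components %||% 2L)
  exh <- config$exhaustive_limit %||% 200000
  params <- heterogeneity_params(trim_percentile = trim)

  classification <- NULL
  if (mode == "fixture") {
    table <- load_table1_fixture()
  } else {
    if (mode == "simulate") {
      if (is.null(config$cohorts)) stop("simulate mode needs config$cohorts")
      specs <- lapply(config$cohorts, function(co) {
        kind <- match.arg(co$kind, c("healthy", "nonresponder", "responder"))
        args <- list()
        if (!is.null(co$days)) args$days <- as.integer(unlist(co$days))
        if (!is.null(co$label)) args$label <- co$label
        if (kind != "healthy" && !is.null(co$dropout_prob))
          args$dropout_prob <- co$dropout_prob
        spec <- do.call(switch(kind, healthy = healthy_course,
                               nonresponder = nonresponder_course,
                               responder = responder_course), args)
        list(spec = spec, n_mice = as.integer(co$n_mice))
      })
      dataset <- simulate_study(specs, seed = seed,
                                dir = file.path(config$out_dir, "volumes"))
      write_manifest(dataset$manifest, file.path(config$out_dir, "manifest.csv"))
    } else {
      if (is.null(config$manifest)) stop("analyze mode needs config$manifest")
      dataset <- list(manifest = read_manifest(config$manifest))
    }
    table <- score_dataset(dataset, params = params)
    classification <- classify_dataset(dataset, table)
  }

  stats <- analyze_cohort_table(table, n_perm = n_perm, seed = seed,
                                alpha = alpha, pca_components = pcs,
                                exhaustive_limit = exh)
  results <- list(cohort_table = table,
                  permutation = stats$permutation, pca = stats$pca,
                  fits = stats$fits, group_lines = stats$group_lines,
                  quartiles = stats$quartiles,
                  classification = classification)
  files <- write_results(results, config$out_dir)
  manifest <- list(mode = mode, seed = seed, n_perm = n_perm, alpha = alpha,
                   trim_percentile = trim, pca_components = pcs,
                   exhaustive_limit = exh,
                   package_version = as.character(utils::packageVersion("marrowvar")),
                   config = config)
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(results, list(stats_params = stats$params, files = files)))
}

# Per-mouse classification from a scored dataset (needs distal mean PDFF
# and, when present, spleen volumes from the manifest).
classify_dataset <- function(dataset, table) {
  if (!"mean_pdff" %in% names(table)) return(NULL)
  man <- dataset$manifest
  rows <- list()
  for (m in unique(table$mouse_id)) {
    mm <- table[table$mouse_id == m, , drop = FALSE]
    mm <- mm[order(mm$day), , drop = FALSE]
    sp <- NULL
    if (!is.null(man) && "spleen_volume" %in% names(man)) {
      mr <- man[man$mouse_id == m, , drop = FALSE]
      sp <- mr$spleen_volume[match(mm$day, mr$day)]
      if (all(is.na(sp))) sp <- NULL
    }
    cl <- classify_mouse(mouse_course(m, mm$day, mean_pdff = mm$mean_pdff,
                                      score = mm$score, spleen_volume = sp))
    rows[[m]] <- data.frame(mouse_id = m, group = mm$group[1],
                            status = cl$status, reason = cl$reason,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
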