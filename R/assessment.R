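#' @name assessment
#' @title Multi-ensemble assessment: bootstrap, floor, ceiling, ranking
#' @description
#' Orchestrates the comparison of several ensembles against one reference
#' map: per-ensemble bootstrap volumes quantify model-sampling variance, a
#' shuffled reference sets the performance floor, an independent map sets
#' the experimental ceiling, and per-metric Z-scores across ensembles
#' (clipped at zero and summed) rank the ensembles. One global seed fans
#' out deterministically to per-task seeds.
NULL

# counter-based fan-out of one global seed into per-task seeds (< 2^31)
task_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + counter * 104729) %% 2147483647)
}

score_set_metrics <- function(ss) {
  vapply(.metric_names, function(m) ss[[m]], numeric(1))
}

#' Bootstrap the score of an ensemble by resampling its models
#'
#' Draws `n_reps` resamples of the ensemble's models with replacement (each
#' of the original size), reruns the full density build and scoring for
#' each, and reports the per-metric standard deviation as the sampling
#' variance of the ensemble's score.
#'
#' @param ensemble a standardized, trimmed `solvent_ensemble` (>= 2 models;
#'   a single-model ensemble yields `sd` of NA with a flag).
#' @param ref_map reference `density_grid`.
#' @param ref a `reference_structure`.
#' @param mask a `shell_mask` on the reference map lattice.
#' @param config a [cryoshell_config()] list.
#' @param n_reps replicates (default 5).
#' @param seed global seed; replicate index draws are functions of it only.
#' @return list with `replicates` (per replicate: `indices`, `scores`), and
#'   `sd` (named per-metric standard deviation).
#' @export
bootstrap_scores <- function(ensemble, ref_map, ref, mask,
                             config = cryoshell_config(), n_reps = 5, seed = 1) {
  n <- length(ensemble$models)
  idx <- lapply(seq_len(n_reps), function(r)
    with_seed(task_seed(seed, r), sample.int(n, n, replace = TRUE)))
  nbh <- build_neighborhoods(ref, config$neighborhood_radius, config$atom_selection)
  reps <- lapply(seq_len(n_reps), function(r) {
    boot <- new_solvent_ensemble(ensemble$models[idx[[r]]],
                                 paste0(ensemble$source_label, "#boot", r))
    map <- ensemble_to_map(boot, ref, config, lattice = ref_map, neighborhoods = nbh)
    list(indices = idx[[r]],
         scores = score_pair(map$total, ref_map, mask, config, mi_seed = seed))
  })
  mat <- t(vapply(reps, function(r) score_set_metrics(r$scores), numeric(4)))
  sds <- apply(mat, 2, function(col) if (all(is.na(col))) NA_real_ else sd(col, na.rm = TRUE))
  names(sds) <- .metric_names
  if (n < 2L) sds[] <- NA_real_
  list(replicates = reps, sd = sds, single_model = n < 2L)
}

#' Shuffle floor: score of a randomly permuted reference against itself
#'
#' Permutes the masked reference values with a seeded shuffle and scores
#' the shuffled vector (as the prediction) against the ordered one — the
#' performance floor any real prediction should exceed.
#'
#' @param ref_values numeric vector of masked reference values (from
#'   [mask_values()]).
#' @param seed seed for the permutation(s).
#' @param n_shuffles number of independent shuffles.
#' @param config a [cryoshell_config()] list.
#' @return a `score_set` (one shuffle) or a list of them.
#' @export
shuffle_floor <- function(ref_values, seed = 1, n_shuffles = 1,
                          config = cryoshell_config()) {
  ref_values <- as.numeric(ref_values)
  out <- lapply(seq_len(n_shuffles), function(s) {
    shuffled <- with_seed(task_seed(seed, s),
                          ref_values[sample.int(length(ref_values))])
    score_pair(shuffled, ref_values, config = config, mi_seed = task_seed(seed, s))
  })
  if (n_shuffles == 1L) out[[1]] else out
}

#' Experimental ceiling from an independent map
#'
#' Resamples the independent map onto the reference lattice by trilinear
#' interpolation and scores it against the reference on the mask — the
#' agreement attainable given experimental uncertainty alone.
#'
#' @param ref_map reference `density_grid`.
#' @param indep_map independent `density_grid` (any lattice).
#' @param mask a `shell_mask` on the reference lattice.
#' @param config a [cryoshell_config()] list.
#' @param mi_seed seed for the MI jitter.
#' @return a `score_set`.
#' @export
ceiling_from_independent_map <- function(ref_map, indep_map, mask,
                                         config = cryoshell_config(), mi_seed = 0) {
  res <- resample_onto(indep_map, ref_map)
  score_pair(res, ref_map, mask, config, mi_seed = mi_seed)
}

#' Rank ensembles by summed positive Z-scores over the four metrics
#'
#' For each metric the scores are standardized across ensembles (population
#' standard deviation); negative Z-scores are clipped to zero so
#' below-average performance on one metric is not penalized, and the
#' clipped Z-scores are summed. Ensembles missing a metric are excluded
#' from that metric's mean/sd and contribute zero for it.
#'
#' @param scores named list of `score_set`s (>= 3 ensembles).
#' @return a `ranking_table` data frame: per-metric Z, `total`, sorted
#'   decreasing; attribute `missing` flags excluded metrics.
#' @export
rank_ensembles <- function(scores) {
  if (length(scores) < 3L) stop("ranking needs at least 3 ensembles")
  mat <- t(vapply(scores, score_set_metrics, numeric(4)))
  z <- mat
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    ok <- !is.na(v)
    mu <- mean(v[ok])
    sdev <- sqrt(mean((v[ok] - mu)^2))  # population sd
    z[, j] <- if (sum(ok) < 2L || sdev == 0) 0 else (v - mu) / sdev
    z[!ok, j] <- NA
  }
  zc <- pmax(z, 0)
  total <- rowSums(zc, na.rm = TRUE)
  out <- data.frame(ensemble = names(scores), z, total = total,
                    row.names = NULL, check.names = FALSE)
  names(out)[2:5] <- paste0("z_", .metric_names)
  out <- out[order(-out$total), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- is.na(z)
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' @export
print.ranking_table <- function(x, ...) {
  cat("<ranking_table> summed positive Z-scores over",
      paste(.metric_names, collapse = ", "), "\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Per-residue assessment and Z-score matrices
#'
#' Scores every (ensemble, residue region) pair on the per-residue
#' partition of the solvent shell, then standardizes each metric across
#' ensembles within each residue column.
#'
#' @param maps named list of predicted total `density_grid`s, one per
#'   ensemble, on the reference lattice (build with [ensemble_to_map()]).
#' @param ref_map reference `density_grid`.
#' @param ref a `reference_structure`.
#' @param config a [cryoshell_config()] list.
#' @param mask optionally the full-shell mask (default: the config band).
#' @return list with `scores` (ensemble x residue list of `score_set`), `z`
#'   (per-metric matrices, ensembles x residues), and `order` (ensembles
#'   sorted by summed positive Z of the first metric).
#' @export
per_residue_assessment <- function(maps, ref_map, ref,
                                   config = cryoshell_config(), mask = NULL) {
  if (is.null(mask))
    mask <- compute_shell(ref, ref_map, config$shell_band[1], config$shell_band[2])
  regions <- per_residue_regions(mask, config$min_voxels_mi)
  ens <- names(maps)
  scores <- lapply(maps, function(m)
    lapply(regions, function(rg) score_pair(m, ref_map, rg, config)))
  z <- lapply(.metric_names, function(metric) {
    vals <- vapply(scores, function(per_res)
      vapply(per_res, function(ss) ss[[metric]], numeric(1)), numeric(length(regions)))
    vals <- matrix(vals, nrow = length(regions),
                   dimnames = list(names(regions), ens))
    vals <- t(vals)  # ensembles x residues
    apply(vals, 2, function(col) {
      ok <- !is.na(col)
      if (sum(ok) < 2L) return(rep(NA_real_, length(col)))
      mu <- mean(col[ok]); sdev <- sqrt(mean((col[ok] - mu)^2))
      if (sdev == 0) ifelse(ok, 0, NA) else (col - mu) / sdev
    })
  })
  z <- lapply(z, function(m) {
    m <- matrix(m, nrow = length(ens), dimnames = list(ens, names(regions)))
    m
  })
  names(z) <- .metric_names
  totals <- rowSums(pmax(z[[1]], 0), na.rm = TRUE)
  list(scores = scores, z = z, order = names(sort(totals, decreasing = TRUE)))
}

#' Assess a set of ensembles against a reference map
#'
#' The full orchestration: builds each ensemble's map on the reference
#' lattice, scores it on the default shell, adds bootstrap standard
#' deviations, the shuffle floor, the independent-map ceiling when
#' provided, and the Z-score ranking. Deterministic given the seed; the
#' JSON report is byte-identical across reruns with identical inputs.
#'
#' @param ensembles named list of standardized, trimmed `solvent_ensemble`s.
#' @param ref_map reference `density_grid`.
#' @param ref a `reference_structure`.
#' @param config a [cryoshell_config()] list.
#' @param seed global seed.
#' @param indep_map optional independent `density_grid` for the ceiling.
#' @param bootstrap whether to run bootstrap replicates (default TRUE).
#' @param out_dir optional directory for `report.json` and `scores.csv`.
#' @return list with `scores`, `ranking`, `bootstrap_sd`, `floor`,
#'   `ceiling`, `report` (the serializable report structure).
#' @export
assess <- function(ensembles, ref_map, ref, config = cryoshell_config(),
                   seed = 1, indep_map = NULL, bootstrap = TRUE, out_dir = NULL) {
  stopifnot(length(names(ensembles)) == length(ensembles))
  mask <- compute_shell(ref, ref_map, config$shell_band[1], config$shell_band[2])
  nbh <- build_neighborhoods(ref, config$neighborhood_radius, config$atom_selection)
  scores <- list(); boot_sd <- list()
  for (i in seq_along(ensembles)) {
    nm <- names(ensembles)[i]
    map <- ensemble_to_map(ensembles[[i]], ref, config, lattice = ref_map,
                           neighborhoods = nbh)
    scores[[nm]] <- score_pair(map$total, ref_map, mask, config,
                               mi_seed = task_seed(seed, 100 + i))
    if (bootstrap && length(ensembles[[i]]$models) >= 2L) {
      boot_sd[[nm]] <- bootstrap_scores(ensembles[[i]], ref_map, ref, mask,
                                        config, config$n_bootstrap,
                                        seed = task_seed(seed, 200 + i))$sd
    }
  }
  floor_score <- shuffle_floor(mask_values(ref_map, mask),
                               seed = task_seed(seed, 999), config = config)
  ceiling_score <- if (!is.null(indep_map))
    ceiling_from_independent_map(ref_map, indep_map, mask, config,
                                 mi_seed = task_seed(seed, 998))
  ranking <- if (length(scores) >= 3L) rank_ensembles(scores)
  report <- list(
    seed = seed,
    config = config[order(names(config))],
    n_mask_voxels = length(mask$indices),
    scores = lapply(scores, unclass),
    bootstrap_sd = boot_sd,
    floor = unclass(floor_score),
    ceiling = if (!is.null(ceiling_score)) unclass(ceiling_score),
    ranking = if (!is.null(ranking)) as.list(as.data.frame(ranking))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    tab <- do.call(rbind, lapply(names(scores), function(nm)
      cbind(ensemble = nm, as.data.frame(scores[[nm]]))))
    write.csv(tab, file.path(out_dir, "scores.csv"), row.names = FALSE)
  }
  list(scores = scores, ranking = ranking, bootstrap_sd = boot_sd,
       floor = floor_score, ceiling = ceiling_score, report = report)
}
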