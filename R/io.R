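#' Write tap records as TSV
#'
#' One row per iteration: group_id, participant_id, trial_id,
#' iteration_index, period_ms, stimulus_onsets_ms and response_onsets_ms
#' (both comma-joined). The dialect [read_tap_records()] reads back.
#'
#' @param records data frame in the tap-record layout, or a
#'   `rhythm_dataset` (converted with [dataset_to_records()]).
#' @param path output file.
#' @param group_id,participant_id used when converting a dataset.
#' @return the path, invisibly.
#' @export
write_tap_records <- function(records, path, group_id = "G1",
                              participant_id = "P1") {
  if (inherits(records, "rhythm_dataset") || inherits(records[[1]],
                                                      "trial_record")) {
    records <- dataset_to_records(records, group_id, participant_id)
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a simulated dataset to the tap-record table
#'
#' @param trials a `rhythm_dataset` or list of `trial_record`s. The raw
#'   onset streams are not retained in trial records, so this export is
#'   only available for datasets carrying `streams` attributes (as written
#'   by [simulate_dataset_records()]); for analysis-side persistence use
#'   [write_prior()] and the statistics TSVs instead.
#' @keywords internal
dataset_to_records <- function(trials, group_id = "G1",
                               participant_id = "P1") {
  streams <- attr(trials, "streams")
  if (is.null(streams)) {
    stop("dataset does not carry raw onset streams; simulate with ",
         "simulate_dataset_records() to export tap records")
  }
  streams$group_id <- group_id
  streams$participant_id <- participant_id
  streams[, c("group_id", "participant_id", "trial_id", "iteration_index",
              "period_ms", "stimulus_onsets_ms", "response_onsets_ms")]
}

#' Simulate a dataset and keep the raw onset streams
#'
#' Like [simulate_dataset()] but also records every iteration's stimulus
#' and response onsets in the tap-record table layout (attribute
#' `streams`), so the simulation can be written with
#' [write_tap_records()] and replayed with [replay_records()].
#'
#' @inheritParams simulate_dataset
#' @return a `rhythm_dataset` with a `streams` attribute.
#' @export
simulate_dataset_records <- function(params, n_trials, period = 2000,
                                     repetitions = 10, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- attr(params$grid, "f")
  seeds <- sample_seed(n_trials, period = period, min_interval = f * period)
  rows <- list()
  base <- make_responder(params, period, repetitions)
  factory <- function(i) {
    function(stimulus, iteration) {
      st <- base(stimulus, iteration)
      rows[[length(rows) + 1L]] <<- data.frame(
        trial_id = i, iteration_index = iteration, period_ms = period,
        stimulus_onsets_ms = paste(sprintf("%.6f", st$stimulus_onsets),
                                   collapse = ","),
        response_onsets_ms = paste(sprintf("%.6f", st$response_onsets),
                                   collapse = ","))
      st
    }
  }
  ds <- run_group(seeds, factory, period = period,
                  repetitions = repetitions, ...)
  attr(ds, "streams") <- do.call(rbind, rows)
  ds
}

parse_onsets <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

#' Read tap records from TSV
#'
#' Validates the schema (missing columns are a hard error) and each row
#' (the stimulus must have 3 * repetitions + 1 strictly increasing
#' onsets); malformed rows are skipped and collected in the `errors`
#' attribute.
#'
#' @param path TSV file in the tap-record dialect.
#' @param repetitions expected pattern cycles per iteration.
#' @return data frame of valid rows with list columns `stimulus_onsets`
#'   and `response_onsets` (numeric vectors, ms).
#' @export
read_tap_records <- function(path, repetitions = 10) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("group_id", "participant_id", "trial_id",
                "iteration_index", "period_ms", "stimulus_onsets_ms",
                "response_onsets_ms")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  n_onsets <- 3L * repetitions + 1L
  errors <- character(0)
  keep <- logical(nrow(raw))
  stim <- resp <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    s <- suppressWarnings(parse_onsets(raw$stimulus_onsets_ms[i]))
    r <- if (nzchar(raw$response_onsets_ms[i])) {
      suppressWarnings(parse_onsets(raw$response_onsets_ms[i]))
    } else numeric(0)
    it <- suppressWarnings(as.integer(raw$iteration_index[i]))
    per <- suppressWarnings(as.numeric(raw$period_ms[i]))
    reason <- NULL
    if (anyNA(s) || anyNA(r)) reason <- "unparsable onsets"
    else if (length(s) != n_onsets) {
      reason <- sprintf("expected %d stimulus onsets, found %d",
                        n_onsets, length(s))
    } else if (any(diff(s) <= 0)) reason <- "stimulus onsets not increasing"
    else if (is.na(it) || is.na(per) || per <= 0) {
      reason <- "bad iteration index or period"
    }
    if (is.null(reason)) {
      keep[i] <- TRUE
      stim[[i]] <- s
      resp[[i]] <- r
    } else {
      errors <- c(errors, sprintf("row %d: %s", i, reason))
    }
  }
  out <- raw[keep, c("group_id", "participant_id", "trial_id",
                     "iteration_index", "period_ms"), drop = FALSE]
  out$iteration_index <- as.integer(out$iteration_index)
  out$period_ms <- as.numeric(out$period_ms)
  out$stimulus_onsets <- stim[keep]
  out$response_onsets <- resp[keep]
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Replay recorded onset streams through the preprocessing pipeline
#'
#' Rebuilds `trial_record`s from a tap-record table: each row's onsets are
#' matched, averaged and validity-flagged with the standard rules (the
#' recorded stimulus is trusted as the presented stimulus).
#'
#' @param records table from [read_tap_records()].
#' @param repetitions pattern cycles per iteration.
#' @param ... passed to [preprocess_stream()].
#' @return a `rhythm_dataset` (list of `trial_record`s).
#' @export
replay_records <- function(records, repetitions = 10, ...) {
  ids <- unique(records$trial_id)
  trials <- lapply(ids, function(id) {
    rows <- records[records$trial_id == id, ]
    rows <- rows[order(rows$iteration_index), ]
    period <- rows$period_ms[1]
    iterations <- lapply(seq_len(nrow(rows)), function(i) {
      s <- rows$stimulus_onsets[[i]]
      rec <- preprocess_stream(s, rows$response_onsets[[i]],
                               period = period, repetitions = repetitions,
                               ...)
      list(index = rows$iteration_index[i],
           stimulus = diff(s)[1:3], record = rec)
    })
    n_invalid <- sum(!vapply(iterations, function(it) it$record$valid,
                             logical(1)))
    structure(list(seed = diff(rows$stimulus_onsets[[1]])[1:3],
                   iterations = iterations,
                   n_invalid = n_invalid,
                   stopped_early = n_invalid >= 3L &&
                     length(iterations) < 5L,
                   aborted = NA_character_),
              class = "trial_record")
  })
  structure(trials, class = "rhythm_dataset",
            period = records$period_ms[1])
}

#' Analysis configuration with tempo scaling
#'
#' Central bundle of protocol and analysis constants. Time constants that
#' belong to the experiment (seed floor, response floor, match window)
#' scale linearly with the pattern duration; the 80 ms merge gap is a
#' motor limit and does not scale; the inner fraction f is dimensionless
#' and invariant.
#'
#' @param period_ms pattern duration (2000 default; 1000 fast variant).
#' @param n_repetitions pattern cycles per iteration.
#' @param n_iter iterations per trial.
#' @param max_invalid invalid iterations that stop a trial.
#' @param merge_gap_ms onset merge gap.
#' @param gamma_kde_ms KDE covariance regularizer.
#' @param bin grid bin width (triangle units).
#' @param em_tol EM convergence threshold.
#' @param A mixture aspect constant.
#' @param gamma_cat,iso_boost categorization parameters.
#' @param n_boot default bootstrap rounds.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(period_ms = 2000, n_repetitions = 10,
                            n_iter = 5, max_invalid = 3,
                            merge_gap_ms = 80, gamma_kde_ms = 15,
                            bin = 0.006, em_tol = 1e-6, A = 0.2,
                            gamma_cat = 7, iso_boost = 3, n_boot = 1000) {
  scale <- period_ms / 2000
  cfg <- list(period_ms = period_ms,
              min_seed_interval_ms = 300 * scale,
              response_floor_ms = 285 * scale,
              match_window_ms = 150 * scale,
              merge_gap_ms = merge_gap_ms,
              gamma_kde_ms = gamma_kde_ms,
              bin = bin, f = 0.15,
              n_repetitions = n_repetitions, n_iter = n_iter,
              max_invalid = max_invalid, em_tol = em_tol, A = A,
              gamma_cat = gamma_cat, iso_boost = iso_boost,
              n_boot = n_boot)
  stopifnot(cfg$f == cfg$min_seed_interval_ms / cfg$period_ms)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration
#'
#' Flat `key=value` text; unknown keys are an error on read (typo
#' protection); round-trips losslessly.
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  keys <- setdiff(names(config), "f")
  writeLines(sprintf("%s=%.17g", keys,
                     vapply(config[keys], as.numeric, numeric(1))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  known <- names(formals(pipeline_config))
  scaled <- c("min_seed_interval_ms", "response_floor_ms",
              "match_window_ms")
  unknown <- setdiff(keys, c(known, scaled))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  args <- as.list(vals[keys %in% known])
  names(args) <- keys[keys %in% known]
  cfg <- do.call(pipeline_config, args)
  for (k in intersect(keys, scaled)) cfg[[k]] <- vals[keys == k]
  cfg
}

#' Run the full analysis pipeline for one or more groups
#'
#' For each group: fifth-iteration points, the estimated prior, the
#' constrained mixture fit and its class weights, peakiness and overlap
#' statistics. Across groups: the JSD matrix, MDS embedding and grid PCA
#' (when at least two groups are given). All artefacts are written as TSV
#' (plus a JSON manifest recording the configuration and seed), so two
#' runs with the same seed produce byte-identical files.
#'
#' @param datasets named list of `rhythm_dataset`s (or lists of
#'   `trial_record`s).
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param seed RNG seed for the stochastic stages.
#' @param anchors category `ratio_set` for the mixture fits.
#' @return invisible list of per-group results and cross-group objects.
#' @export
run_pipeline <- function(datasets, out_dir, config = pipeline_config(),
                         seed = 1, anchors = omega22()) {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    names(datasets) <- paste0("G", seq_along(datasets))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  grid <- triangle_grid(bin = config$bin, f = config$f)
  groups <- list()
  stats_rows <- list()
  for (g in names(datasets)) {
    pts <- dataset_points(datasets[[g]], iteration = config$n_iter,
                          period = config$period_ms)
    prior <- estimate_prior(pts, grid = grid,
                            gamma_ms = config$gamma_kde_ms,
                            period = config$period_ms)
    km_means <- kernel_matrix(pts, grid, gamma_ms = config$gamma_kde_ms,
                              period = config$period_ms)$means
    gmm <- fit_constrained_gmm(km_means, anchors = anchors, A = config$A,
                               tol = config$em_tol)
    cw <- category_weights(gmm)
    pk <- peakiness(pts, grid, n_null = config$n_boot,
                    gamma_ms = config$gamma_kde_ms,
                    period = config$period_ms)
    ov <- integer_overlap(km_means, anchors, variant = "uniform",
                          n_null = config$n_boot, grid = grid,
                          gamma_ms = config$gamma_kde_ms,
                          period = config$period_ms)
    tm <- tapping_metrics(datasets[[g]])
    write_prior(prior, file.path(out_dir, paste0(g, "_prior.tsv")))
    gm_df <- data.frame(ratio = anchors$ratio, class = anchors$class,
                        mean_x = gmm$means[, 1], mean_y = gmm$means[, 2],
                        cov_xx = gmm$covs[1, 1, ], cov_xy = gmm$covs[1, 2, ],
                        cov_yy = gmm$covs[2, 2, ], weight = gmm$weights)
    utils::write.table(gm_df, file.path(out_dir, paste0(g, "_gmm.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stats_rows[[g]] <- data.frame(
      group = g, n_trials = prior$n_trials,
      top_mass = pk$top_mass$statistic, top_mass_p = pk$top_mass$p_value,
      peak_ratio = pk$peak_ratio$statistic,
      peak_ratio_p = pk$peak_ratio$p_value,
      overlap_dist = ov$statistic, overlap_p = ov$p_value,
      explained_var = explained_variance(gmm, prior),
      mean_asynchrony_ms = tm$mean_ms, sd_asynchrony_ms = tm$sd_ms)
    groups[[g]] <- list(points = pts, prior = prior, gmm = gmm,
                        class_weights = cw)
  }
  stats_df <- do.call(rbind, stats_rows)
  utils::write.table(stats_df, file.path(out_dir, "group_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wt <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g, class = names(groups[[g]]$class_weights),
               weight = as.numeric(groups[[g]]$class_weights))
  }))
  utils::write.table(wt, file.path(out_dir, "category_weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cross <- NULL
  if (length(groups) >= 2L) {
    priors <- lapply(groups, `[[`, "prior")
    n <- length(priors)
    D <- matrix(0, n, n, dimnames = list(names(priors), names(priors)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- jsd(priors[[i]], priors[[j]])
      }
    }
    emb <- mds_embedding(D)
    emb_df <- data.frame(group = names(priors), dim1 = emb$points[, 1],
                         dim2 = emb$points[, 2])
    utils::write.table(emb_df, file.path(out_dir, "mds_embedding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pca <- pca_on_grids(priors)
    proj_df <- data.frame(group = names(priors),
                          pc1 = pca$projections[, 1],
                          pc2 = if (ncol(pca$projections) > 1) {
                            pca$projections[, 2]
                          } else 0)
    utils::write.table(proj_df, file.path(out_dir, "pca_projections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cross <- list(jsd_matrix = D, mds = emb, pca = pca)
  }
  manifest <- list(seed = seed, groups = names(datasets),
                   config = unclass(config)[!vapply(config, is.null,
                                                    logical(1))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(groups = groups, cross = cross, stats = stats_df))
}
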