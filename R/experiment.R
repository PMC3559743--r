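#' Configure an end-to-end authentication experiment
#'
#' Bundles everything one run needs: the dataset (a [dataset_index()], a
#' [phantom_config()] to generate, or a manifest CSV path), optional
#' Gaussian smoothing, the distance form, which protocols to run and the
#' scan selectors for imposter enumeration and the identification
#' gallery/probes.
#'
#' @param dataset A [dataset_index()], [phantom_config()], or path to a
#'   manifest CSV.
#' @param fwhm_mm Gaussian smoothing FWHM in mm applied to every volume on
#'   load; 0 (default) disables. Phantom volumes are generated already
#'   spatially smooth, so smoothing is chiefly for real normalized GM maps.
#' @param metric `"L1"` or `"L2"`, see [gm_distance()].
#' @param protocols Subset of `c("same_visit", "different_visit",
#'   "identification")`, nonempty.
#' @param imposter_selector One-scan-per-subject rule for imposter pairs,
#'   default visit 1 scan 2.
#' @param gallery_selector,probe_selector Enrollment and probe scan rules
#'   for identification; defaults: gallery = visit 1 scan 2, probes =
#'   visit 2 scan 2.
#' @param histogram_bin_width Bin width of exported score histograms.
#' @param out_dir Output directory for reports; `NULL` keeps everything in
#'   memory (phantom volumes then go to a temporary directory).
#' @param seed Optional integer; when `dataset` is a [phantom_config()]
#'   this overrides its `master_seed`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(dataset,
                              fwhm_mm = 0,
                              metric = c("L1", "L2"),
                              protocols = c("same_visit", "different_visit",
                                            "identification"),
                              imposter_selector = c(visit = 1L, scan = 2L),
                              gallery_selector = c(visit = 1L, scan = 2L),
                              probe_selector = c(visit = 2L, scan = 2L),
                              histogram_bin_width = 5,
                              out_dir = NULL,
                              seed = NULL) {
  metric <- match.arg(metric)
  protocols <- match.arg(protocols, several.ok = TRUE)
  stopifnot(fwhm_mm >= 0, histogram_bin_width > 0)
  if (is.character(dataset)) {
    if (!file.exists(dataset)) stop("no such manifest: ", dataset, call. = FALSE)
  } else if (!inherits(dataset, c("dataset_index", "phantom_config"))) {
    stop("dataset must be a dataset_index, phantom_config or manifest path",
         call. = FALSE)
  }
  if (!is.null(seed) && inherits(dataset, "phantom_config")) {
    dataset$master_seed <- as.integer(seed)
  }
  structure(list(dataset = dataset, fwhm_mm = fwhm_mm, metric = metric,
                 protocols = protocols,
                 imposter_selector = imposter_selector,
                 gallery_selector = gallery_selector,
                 probe_selector = probe_selector,
                 histogram_bin_width = histogram_bin_width,
                 out_dir = out_dir, seed = seed),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors [experiment_config()]: a `dataset` block with either
#' `manifest: <path>` or `phantom: {<phantom_config fields>}`, plus any of
#' `fwhm_mm`, `metric`, `protocols`, `imposter_selector`,
#' `gallery_selector`, `probe_selector`, `histogram_bin_width`, `out_dir`,
#' `seed`. Selectors are maps with `visit` and `scan` entries.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$dataset)) stop("config needs a dataset block", call. = FALSE)
  ds <- vals$dataset
  dataset <- if (!is.null(ds$manifest)) {
    ds$manifest
  } else if (!is.null(ds$phantom)) {
    do.call(phantom_config, ds$phantom)
  } else {
    stop("dataset block needs `manifest:` or `phantom:`", call. = FALSE)
  }
  args <- vals[setdiff(names(vals), "dataset")]
  for (sel in c("imposter_selector", "gallery_selector", "probe_selector")) {
    if (!is.null(args[[sel]])) args[[sel]] <- unlist(args[[sel]])
  }
  do.call(experiment_config, c(list(dataset = dataset), args))
}

#' Run a full authentication experiment
#'
#' Drives the whole pipeline: dataset resolution (generating phantoms when
#' configured), optional smoothing, genuine/imposter pair enumeration,
#' voxel-level distances, min-max score normalization over each protocol's
#' pooled comparisons, FAR/FRR threshold sweep, ROC, EER, separation gap,
#' score histograms, and the closed-set identification experiment. When
#' `out_dir` is set, writes per-protocol score and ROC CSVs, histogram
#' CSVs, the identification report, and a `summary.json`; the run is
#' deterministic given the configuration.
#'
#' @param config An [experiment_config()].
#' @param verbose Log pair counts and pool extremes via [message()].
#' @return Invisibly, a list with the `summary` (what `summary.json`
#'   holds), per-protocol `pools` and `curves`, and the identification
#'   `report`.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  index <- config$dataset
  if (is.character(index)) {
    index <- read_manifest(index)
  } else if (inherits(index, "phantom_config")) {
    phantom_dir <- if (is.null(out_dir)) {
      tempfile("phantoms")
    } else {
      file.path(out_dir, "phantoms")
    }
    say("generating %d x %d x %d phantom volumes under %s",
        index$n_subjects, index$visits_per_subject, index$scans_per_visit,
        phantom_dir)
    index <- generate_dataset(index, phantom_dir)
  }
  say("dataset: %d volumes, %d subjects", nrow(index$manifest),
      length(subjects(index)))

  volumes <- volume_matrix(index, fwhm_mm = config$fwhm_mm)
  grid_shape <- attr(volumes, "grid_shape")

  summary <- list(
    n_subjects = length(subjects(index)),
    n_volumes = nrow(index$manifest),
    grid_shape = as.integer(grid_shape),
    metric = config$metric,
    fwhm_mm = config$fwhm_mm,
    threshold_convention = "FRR: score < t; FAR: score > t (strict)"
  )
  pools <- list()
  curves <- list()
  id_result <- NULL

  for (mode in intersect(config$protocols, c("same_visit", "different_visit"))) {
    genuine <- enumerate_genuine_pairs(index, mode)
    imposter <- enumerate_imposter_pairs(index, config$imposter_selector)
    if (nrow(genuine) == 0L) {
      stop("protocol ", mode, ": visit structure admits no genuine pairs",
           call. = FALSE)
    }
    say("%s: %d genuine + %d imposter pairs", mode, nrow(genuine),
        nrow(imposter))
    pool <- pairwise_distances(rbind(genuine, imposter), index,
                               metric = config$metric, volumes = volumes)
    pool <- normalize_scores(pool)
    say("%s: distance pool d_min %.6g, d_max %.6g", mode, pool$d_min,
        pool$d_max)
    g <- pool_scores(pool, "genuine")
    i <- pool_scores(pool, "imposter")
    curve <- roc_curve(g, i)
    e <- eer(curve)
    gap <- separation_gap(g, i)
    summary[[mode]] <- list(
      n_genuine = length(g), n_imposter = length(i),
      d_min = pool$d_min, d_max = pool$d_max,
      eer = e$eer, threshold_at_eer = e$threshold_at_eer,
      exact_crossing = e$exact_crossing,
      max_imposter = gap$max_imposter, min_genuine = gap$min_genuine,
      separable = gap$separable)
    pools[[mode]] <- pool
    curves[[mode]] <- curve
    if (!is.null(out_dir)) {
      write_scores(pool, file.path(out_dir, paste0("scores_", mode, ".csv")))
      write.csv(as.data.frame(curve),
                file.path(out_dir, paste0("roc_", mode, ".csv")),
                row.names = FALSE)
      write.csv(score_histogram(g, config$histogram_bin_width),
                file.path(out_dir, paste0("hist_genuine_", mode, ".csv")),
                row.names = FALSE)
      write.csv(score_histogram(i, config$histogram_bin_width),
                file.path(out_dir, paste0("hist_imposter_", mode, ".csv")),
                row.names = FALSE)
    }
  }

  if ("identification" %in% config$protocols) {
    gal_sel <- select_one_per_subject(index, config$gallery_selector)
    gal_ids <- format_scan_id(gal_sel$subject_id, gal_sel$visit_id,
                              gal_sel$scan_id)
    # reuse the (already smoothed) in-memory volume matrix for enrollment
    gallery <- structure(
      list(subject_ids = gal_sel$subject_id,
           volumes = volumes[, match(gal_ids, colnames(volumes)),
                             drop = FALSE],
           grid_shape = grid_shape,
           voxel_size_mm = attr(volumes, "voxel_size_mm"),
           selector = config$gallery_selector),
      class = "gm_gallery")
    probe_sel <- select_one_per_subject(index, config$probe_selector)
    probes <- lapply(seq_len(nrow(probe_sel)), function(j) {
      id <- format_scan_id(probe_sel$subject_id[j], probe_sel$visit_id[j],
                           probe_sel$scan_id[j])
      gm_volume(array(volumes[, id], dim = grid_shape),
                probe_sel$subject_id[j], probe_sel$visit_id[j],
                probe_sel$scan_id[j],
                voxel_size_mm = attr(volumes, "voxel_size_mm"))
    })
    id_result <- identification_ratio(probes, gallery, metric = config$metric)
    say("identification: %d/%d probes correct (%.2f%%)",
        id_result$n_correct, id_result$n_probes, id_result$ratio)
    summary$identification <- list(
      n_probes = id_result$n_probes,
      n_correct = id_result$n_correct,
      identification_ratio = id_result$ratio)
    if (!is.null(out_dir)) {
      write.csv(id_result$report, file.path(out_dir, "identification.csv"),
                row.names = FALSE)
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(summary = summary, pools = pools, curves = curves,
                 identification = id_result, index = index))
}
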