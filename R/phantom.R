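#' Configuration of the synthetic GM phantom generator
#'
#' The generator emulates the statistical structure of a longitudinal
#' structural-MRI study after preprocessing: every subject has a stable
#' GM pattern (shared brain-like support plus a subject-unique smooth random
#' field), every visit adds a smooth drift field (intra-class variability:
#' scanner electronics and environment differ between sessions), and every
#' scan adds voxelwise acquisition noise.
#'
#' Defaults mirror a 150-subject longitudinal cohort with 2 visits and
#' 3 scans per visit on a 32x32x32 grid of 2 mm voxels. The variation
#' amplitudes (subject 0.2, visit drift 0.05, scan noise 0.02) put the
#' generator in the regime where same-visit genuine and imposter score
#' distributions separate completely while different-visit matching is
#' slightly degraded.
#'
#' @param n_subjects Number of subjects (>= 2 for any matching experiment).
#' @param visits_per_subject Visits (sessions) per subject, >= 1.
#' @param scans_per_visit Scans per visit, >= 1.
#' @param grid_shape Length-3 voxel counts of the volume grid.
#' @param voxel_size_mm Length-3 positive voxel edge lengths in mm.
#' @param subject_amplitude Amplitude of the subject-unique smooth field
#'   (dimensionless, on the GM probability scale).
#' @param visit_drift_sd Standard deviation of the per-visit smooth drift
#'   field, shared by all scans of one visit.
#' @param scan_noise_sd Standard deviation of per-scan white voxel noise.
#' @param smoothness_vox Correlation length (Gaussian sd, in voxels) of the
#'   subject and visit random fields.
#' @param master_seed Integer master seed; every volume is reproducible in
#'   isolation through hierarchical (master, subject, visit, scan) seeding.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 150L,
                           visits_per_subject = 2L,
                           scans_per_visit = 3L,
                           grid_shape = c(32L, 32L, 32L),
                           voxel_size_mm = c(2, 2, 2),
                           subject_amplitude = 0.2,
                           visit_drift_sd = 0.05,
                           scan_noise_sd = 0.02,
                           smoothness_vox = 2,
                           master_seed = 1L) {
  stopifnot(n_subjects >= 2, visits_per_subject >= 1, scans_per_visit >= 1,
            length(grid_shape) == 3, all(grid_shape >= 4),
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            subject_amplitude >= 0, subject_amplitude <= 1,
            visit_drift_sd >= 0, scan_noise_sd >= 0, smoothness_vox >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects),
         visits_per_subject = as.integer(visits_per_subject),
         scans_per_visit = as.integer(scans_per_visit),
         grid_shape = as.integer(grid_shape),
         voxel_size_mm = as.numeric(voxel_size_mm),
         subject_amplitude = subject_amplitude,
         visit_drift_sd = visit_drift_sd,
         scan_noise_sd = scan_noise_sd,
         smoothness_vox = smoothness_vox,
         master_seed = as.integer(master_seed)),
    class = "phantom_config"
  )
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_config> %d subjects x %d visits x %d scans, grid %s\n",
    "  subject_amplitude %.3g, visit_drift_sd %.3g, scan_noise_sd %.3g,",
    " smoothness %.3g vox, master_seed %d\n"),
    x$n_subjects, x$visits_per_subject, x$scans_per_visit,
    paste(x$grid_shape, collapse = "x"),
    x$subject_amplitude, x$visit_drift_sd, x$scan_noise_sd,
    x$smoothness_vox, x$master_seed))
  invisible(x)
}

# Brain-like support shared by all subjects: an ellipsoidal cortical shell
# with GM probability 0.8 between 50% and 90% of the ellipsoid radius
# (semi-axes at 45% of each grid extent), 0 elsewhere.
brain_shell <- function(grid_shape) {
  ax <- 0.45 * grid_shape
  ctr <- (grid_shape + 1) / 2
  g <- lapply(1:3, function(a) ((seq_len(grid_shape[a]) - ctr[a]) / ax[a])^2)
  r2 <- outer(outer(g[[1]], g[[2]], `+`), g[[3]], `+`)
  base <- array(0, dim = grid_shape)
  shell <- r2 >= 0.5^2 & r2 <= 0.9^2
  base[shell] <- 0.8
  attr(base, "shell_mask") <- shell
  base
}

# Zero-mean, unit-sd (over the shell) smooth Gaussian random field: white
# noise smoothed to `smoothness_vox`, then standardized by its shell sample
# moments so amplitudes are on a comparable scale regardless of smoothness.
random_field <- function(grid_shape, smoothness_vox, shell_mask, seed) {
  f <- with_seed(seed, array(rnorm(prod(grid_shape)), dim = grid_shape))
  if (smoothness_vox > 0) {
    f <- smooth_array_gaussian(f, rep(smoothness_vox, 3))
  }
  (f - mean(f[shell_mask])) / sd(f[shell_mask])
}

#' Generate a subject's noise-free GM template
#'
#' The template is the shared ellipsoidal-shell support plus the subject's
#' unique smooth random field scaled by `subject_amplitude`, clipped to
#' \[0, 1\]. It idealizes the subject's stable GM anatomy: what every scan
#' of that subject would look like with no session drift and no noise.
#'
#' @param config A [phantom_config()].
#' @param subject_index 1-based subject index in `1..n_subjects`.
#' @return A list of class `subject_template` with `subject_id`, `template`
#'   (3D array in \[0, 1\]) and the shell mask of the support.
#' @export
make_subject_template <- function(config, subject_index) {
  stopifnot(inherits(config, "phantom_config"))
  if (subject_index < 1 || subject_index > config$n_subjects) {
    stop("subject_index out of range 1..", config$n_subjects, call. = FALSE)
  }
  base <- brain_shell(config$grid_shape)
  shell <- attr(base, "shell_mask")
  fld <- random_field(config$grid_shape, config$smoothness_vox, shell,
                      derive_seed(config$master_seed, subject_index))
  tpl <- clip01(base + config$subject_amplitude * fld)
  structure(
    list(subject_id = sprintf("S%03d", subject_index),
         subject_index = as.integer(subject_index),
         template = tpl,
         shell_mask = shell),
    class = "subject_template"
  )
}

#' Simulate one scan of a subject
#'
#' Adds the two degradation sources the verification experiments probe:
#' a per-visit smooth drift field (identical for all scans acquired in that
#' visit, modelling session-to-session intra-class variability) and
#' per-scan white acquisition noise. The result is clipped to \[0, 1\].
#'
#' @param tpl A [make_subject_template()] result.
#' @param visit_id,scan_id 1-based visit and scan ordinals.
#' @param config The [phantom_config()] used to build `tpl`.
#' @return A [gm_volume()].
#' @export
sample_scan <- function(tpl, visit_id, scan_id, config) {
  stopifnot(inherits(tpl, "subject_template"),
            inherits(config, "phantom_config"))
  if (visit_id < 1 || scan_id < 1) {
    stop("visit_id and scan_id are 1-based ordinals", call. = FALSE)
  }
  x <- tpl$template
  if (config$visit_drift_sd > 0) {
    drift <- random_field(
      config$grid_shape, config$smoothness_vox, tpl$shell_mask,
      derive_seed(config$master_seed, tpl$subject_index, visit_id))
    x <- x + config$visit_drift_sd * drift
  }
  if (config$scan_noise_sd > 0) {
    noise <- with_seed(
      derive_seed(config$master_seed, tpl$subject_index, visit_id, scan_id),
      array(rnorm(prod(config$grid_shape)), dim = config$grid_shape))
    x <- x + config$scan_noise_sd * noise
  }
  gm_volume(clip01(x), tpl$subject_id, visit_id, scan_id,
            voxel_size_mm = config$voxel_size_mm)
}

#' Generate a full synthetic phantom dataset on disk
#'
#' Writes one NIfTI-1 volume per (subject, visit, scan) plus a manifest CSV
#' (`manifest.csv`: path, subject_id, visit_id, scan_id) into `out_dir`, and
#' returns the corresponding [dataset_index()]. Rerunning with the same
#' configuration reproduces the volumes byte-for-byte.
#'
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if needed).
#' @return A [dataset_index()] over the written volumes.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list",
                 config$n_subjects * config$visits_per_subject *
                   config$scans_per_visit)
  r <- 0L
  for (s in seq_len(config$n_subjects)) {
    tpl <- make_subject_template(config, s)
    for (v in seq_len(config$visits_per_subject)) {
      for (k in seq_len(config$scans_per_visit)) {
        vol <- sample_scan(tpl, v, k, config)
        fname <- paste0(format_scan_id(vol$subject_id, v, k), ".nii")
        write_gm_volume(vol, file.path(out_dir, fname))
        r <- r + 1L
        rows[[r]] <- data.frame(path = fname, subject_id = vol$subject_id,
                                visit_id = v, scan_id = k,
                                stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  dataset_index(manifest, dir = out_dir)
}

#' Read a phantom configuration from a YAML file
#'
#' Any subset of the [phantom_config()] fields may be given; the rest take
#' their defaults.
#'
#' @param path YAML file path.
#' @return A [phantom_config()].
#' @export
read_phantom_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(phantom_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown phantom_config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(phantom_config, vals)
}
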