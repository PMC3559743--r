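#' Build an identification gallery
#'
#' Enrolls exactly one GM volume per subject — by default the second scan
#' of the first visit — as the database of a 1-to-N closed-set
#' identification system.
#'
#' @param index A [dataset_index()] with at least two subjects.
#' @param selector Named vector `c(visit = ..., scan = ...)` choosing the
#'   enrolled scan of each subject.
#' @param fwhm_mm Optional Gaussian smoothing (FWHM, mm) applied to each
#'   enrolled volume on load; 0 disables.
#' @return An object of class `gm_gallery` holding the enrolled volumes
#'   and subject ids (sorted).
#' @export
build_gallery <- function(index, selector = c(visit = 1L, scan = 2L),
                          fwhm_mm = 0) {
  stopifnot(inherits(index, "dataset_index"))
  sel <- select_one_per_subject(index, selector)
  if (nrow(sel) < 2L) stop("a gallery needs at least 2 subjects", call. = FALSE)
  rows <- vapply(seq_len(nrow(sel)), function(i) {
    manifest_row(index, sel$subject_id[i], sel$visit_id[i], sel$scan_id[i])
  }, integer(1))
  vols <- volume_matrix(index, rows, fwhm_mm = fwhm_mm)
  structure(list(subject_ids = sel$subject_id,
                 volumes = vols,
                 grid_shape = attr(vols, "grid_shape"),
                 voxel_size_mm = attr(vols, "voxel_size_mm"),
                 selector = selector),
            class = "gm_gallery")
}

#' @export
print.gm_gallery <- function(x, ...) {
  cat(sprintf("<gm_gallery> %d enrolled subjects, grid %s (visit %d, scan %d)\n",
              length(x$subject_ids), paste(x$grid_shape, collapse = "x"),
              x$selector[["visit"]], x$selector[["scan"]]))
  invisible(x)
}

#' Identify a probe volume against a gallery
#'
#' Computes the matching distance between the probe and every enrolled
#' volume, min-max normalizes the distances over that pool to scores on
#' \[0, 100\], and returns the subject with the highest score (equivalently
#' the smallest distance). On exact distance ties the lexicographically
#' smallest subject id is returned and `tie` is set.
#'
#' @param probe A [gm_volume()] on the gallery's grid.
#' @param gallery A [build_gallery()] result.
#' @param metric Distance form, see [gm_distance()].
#' @return List with `subject_id`, `score`, `tie`, and the full per-subject
#'   `scores` vector (named, in gallery order).
#' @export
identify_probe <- function(probe, gallery, metric = c("L1", "L2")) {
  stopifnot(inherits(probe, "gm_volume"), inherits(gallery, "gm_gallery"))
  metric <- match.arg(metric)
  if (!identical(dim(probe$data), gallery$grid_shape) ||
      !isTRUE(all.equal(probe$voxel_size_mm, gallery$voxel_size_mm))) {
    stop("probe grid does not match gallery grid", call. = FALSE)
  }
  diff <- gallery$volumes - as.vector(probe$data)
  d <- if (metric == "L1") colSums(abs(diff)) else colSums(diff^2)
  rng <- max(d) - min(d)
  scores <- if (rng > 0) 100 * (max(d) - d) / rng else rep(100, length(d))
  names(scores) <- gallery$subject_ids
  winners <- which(d == min(d))
  best <- winners[order(gallery$subject_ids[winners])[1]]
  list(subject_id = gallery$subject_ids[best],
       score = scores[[best]],
       tie = length(winners) > 1L,
       scores = scores)
}

#' Closed-set rank-1 identification ratio
#'
#' Runs [identify_probe()] for every probe and reports the percentage whose
#' true subject (the probe's own `subject_id`) is returned at rank 1.
#'
#' @param probes Nonempty list of [gm_volume()] probes; each carries its
#'   true subject id.
#' @param gallery A [build_gallery()] result.
#' @param metric Distance form, see [gm_distance()].
#' @return List with `ratio` (percentage in \[0, 100\]), `n_probes`,
#'   `n_correct`, and a per-probe `report` data frame (`probe_id,
#'   returned_subject, true_subject, score, correct, tie`).
#' @export
identification_ratio <- function(probes, gallery, metric = c("L1", "L2")) {
  if (!length(probes)) stop("empty probe list", call. = FALSE)
  metric <- match.arg(metric)
  rows <- lapply(probes, function(p) {
    res <- identify_probe(p, gallery, metric)
    data.frame(probe_id = format_scan_id(p$subject_id, p$visit_id, p$scan_id),
               returned_subject = res$subject_id,
               true_subject = p$subject_id,
               score = res$score,
               correct = res$subject_id == p$subject_id,
               tie = res$tie,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(ratio = 100 * sum(report$correct) / nrow(report),
       n_probes = nrow(report),
       n_correct = sum(report$correct),
       report = report)
}
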