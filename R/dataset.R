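#' Build a dataset index from a manifest
#'
#' A `dataset_index` describes the membership of one experiment: which
#' (subject, visit, scan) triples exist and where their NIfTI volumes live.
#' It carries the visit structure the pair-counting formulas use: the number
#' of visits V per subject, the scans-per-visit counts m_1..m_V, and n_V,
#' the number of subjects scanned at exactly V visits.
#'
#' @param manifest Data frame with columns `path`, `subject_id`, `visit_id`,
#'   `scan_id`. `path` may be `NA` for index-only (counting/enumeration)
#'   use; loading a volume then fails.
#' @param dir Directory against which relative `path` entries are resolved.
#' @return An object of class `dataset_index`.
#' @export
dataset_index <- function(manifest, dir = ".") {
  req <- c("path", "subject_id", "visit_id", "scan_id")
  if (!is.data.frame(manifest) || !all(req %in% names(manifest))) {
    stop("manifest needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  manifest$subject_id <- as.character(manifest$subject_id)
  manifest$visit_id <- as.integer(manifest$visit_id)
  manifest$scan_id <- as.integer(manifest$scan_id)
  if (any(manifest$visit_id < 1L) || any(manifest$scan_id < 1L)) {
    stop("visit_id and scan_id are 1-based ordinals", call. = FALSE)
  }
  key <- format_scan_id(manifest$subject_id, manifest$visit_id, manifest$scan_id)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, visit, scan) triples in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(manifest$subject_id, manifest$visit_id, manifest$scan_id)
  manifest <- manifest[ord, req]
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, dir = dir), class = "dataset_index")
}

#' Read a dataset manifest CSV
#'
#' The manifest is a CSV with columns `path, subject_id, visit_id, scan_id`;
#' relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A [dataset_index()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  dataset_index(read.csv(path, stringsAsFactors = FALSE),
                dir = dirname(path))
}

#' @export
print.dataset_index <- function(x, ...) {
  nv <- visit_count_table(x)
  cat(sprintf("<dataset_index> %d volumes, %d subjects; n_V: {%s}\n",
              nrow(x$manifest), length(subjects(x)),
              paste(sprintf("%s: %d", names(nv), nv), collapse = ", ")))
  invisible(x)
}

#' Subjects of a dataset index
#' @param index A [dataset_index()].
#' @return Sorted character vector of distinct subject ids.
#' @export
subjects <- function(index) {
  stopifnot(inherits(index, "dataset_index"))
  sort(unique(index$manifest$subject_id))
}

#' Scans-per-visit structure of one subject
#'
#' @param index A [dataset_index()].
#' @param subject_id Subject identifier.
#' @return Integer vector m_1..m_V of scan counts, named by visit id.
#' @export
visit_structure <- function(index, subject_id) {
  stopifnot(inherits(index, "dataset_index"))
  m <- index$manifest[index$manifest$subject_id == subject_id, ]
  if (nrow(m) == 0L) stop("unknown subject: ", subject_id, call. = FALSE)
  tab <- table(m$visit_id)
  setNames(as.integer(tab), names(tab))
}

#' Count subjects by number of visits (n_V)
#'
#' @param index A [dataset_index()].
#' @return Integer vector: entry named "V" is the number of subjects with
#'   exactly V visits. Entries sum to the number of distinct subjects.
#' @export
visit_count_table <- function(index) {
  stopifnot(inherits(index, "dataset_index"))
  per_subject <- tapply(index$manifest$visit_id, index$manifest$subject_id,
                        function(v) length(unique(v)))
  tab <- table(per_subject)
  setNames(as.integer(tab), names(tab))
}

# Resolve the manifest row of one (subject, visit, scan); error if absent.
manifest_row <- function(index, subject_id, visit_id, scan_id) {
  m <- index$manifest
  i <- which(m$subject_id == subject_id & m$visit_id == visit_id &
               m$scan_id == scan_id)
  if (length(i) != 1L) {
    stop("no volume indexed for ",
         format_scan_id(subject_id, visit_id, scan_id), call. = FALSE)
  }
  i
}

resolve_path <- function(index, i) {
  p <- index$manifest$path[i]
  if (is.na(p)) {
    stop("index carries no volume path for ",
         format_scan_id(index$manifest$subject_id[i],
                        index$manifest$visit_id[i],
                        index$manifest$scan_id[i]), call. = FALSE)
  }
  if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(index$dir, p)
  p
}

#' Load one volume referenced by a dataset index
#'
#' @param index A [dataset_index()].
#' @param subject_id,visit_id,scan_id Identity triple to load.
#' @return A [gm_volume()].
#' @export
load_volume <- function(index, subject_id, visit_id, scan_id) {
  i <- manifest_row(index, subject_id, visit_id, scan_id)
  read_gm_volume(resolve_path(index, i), subject_id, visit_id, scan_id)
}

# Load a set of manifest rows as a voxels x n matrix with one column per
# scan (column names are canonical scan ids). All volumes must share grid
# shape and voxel size: the matcher assumes one common normalized space.
# Optionally smooths each volume on load.
volume_matrix <- function(index, rows = seq_len(nrow(index$manifest)),
                          fwhm_mm = 0) {
  m <- index$manifest[rows, ]
  ref <- NULL
  out <- NULL
  for (j in seq_len(nrow(m))) {
    vol <- read_gm_volume(resolve_path(index, rows[j]),
                          m$subject_id[j], m$visit_id[j], m$scan_id[j])
    if (fwhm_mm > 0) vol <- smooth_volume(vol, fwhm_mm)
    if (is.null(ref)) {
      ref <- vol
      out <- matrix(0, length(vol$data), nrow(m))
    } else {
      check_same_grid(ref, vol)
    }
    out[, j] <- as.vector(vol$data)
  }
  colnames(out) <- format_scan_id(m$subject_id, m$visit_id, m$scan_id)
  attr(out, "grid_shape") <- dim(ref$data)
  attr(out, "voxel_size_mm") <- ref$voxel_size_mm
  out
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm))) {
    stop("volumes are not in a common grid (shape/voxel size mismatch); ",
         "all volumes of one experiment must share the normalized space",
         call. = FALSE)
  }
  invisible(TRUE)
}
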