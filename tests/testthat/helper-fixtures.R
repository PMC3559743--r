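# Shared fixtures and independent oracles, built in code at test time.

# A random GM volume on a small grid.
rand_gm_volume <- function(shape = c(6, 6, 6), seed = 1,
                           subject = "A", visit = 1, scan = 1,
                           voxel = c(2, 2, 2)) {
  set.seed(seed)
  gm_volume(array(runif(prod(shape)), dim = shape), subject, visit, scan,
            voxel_size_mm = voxel)
}

# Write a list of gm_volumes to a fresh temp dir and index them.
index_from_volumes <- function(vols) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  rows <- lapply(vols, function(v) {
    fname <- paste0(gmauth:::format_scan_id(v$subject_id, v$visit_id,
                                            v$scan_id), ".nii")
    write_gm_volume(v, file.path(dir, fname))
    data.frame(path = fname, subject_id = v$subject_id,
               visit_id = v$visit_id, scan_id = v$scan_id,
               stringsAsFactors = FALSE)
  })
  dataset_index(do.call(rbind, rows), dir = dir)
}

# Index with no volume files, for pair counting/enumeration: `structure` is
# a named list subject_id -> integer vector of scans per visit.
index_from_structure <- function(structure) {
  rows <- list()
  for (subj in names(structure)) {
    m <- structure[[subj]]
    for (v in seq_along(m)) {
      for (s in seq_len(m[v])) {
        rows[[length(rows) + 1L]] <- data.frame(
          path = NA_character_, subject_id = subj, visit_id = v, scan_id = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  dataset_index(do.call(rbind, rows))
}

# Independent brute-force genuine-pair count for one subject: explicit
# double loop over the scan list, no combinatorial formula.
brute_genuine_count <- function(scans_per_visit, mode) {
  scans <- do.call(rbind, lapply(seq_along(scans_per_visit), function(v) {
    data.frame(visit = v, scan = seq_len(scans_per_visit[v]))
  }))
  n <- 0L
  for (i in seq_len(nrow(scans))) {
    for (j in seq_len(nrow(scans))) {
      if (j <= i) next
      same <- scans$visit[i] == scans$visit[j]
      if ((mode == "same_visit" && same) ||
          (mode == "different_visit" && !same)) {
        n <- n + 1L
      }
    }
  }
  n
}

# Independent EER estimate: exhaustive fine-grid threshold search,
# reporting (FAR + FRR) / 2 where |FAR - FRR| is smallest.
grid_eer <- function(genuine, imposter, n_grid = 20001) {
  thr <- seq(min(c(genuine, imposter)) - 1, max(c(genuine, imposter)) + 1,
             length.out = n_grid)
  far <- vapply(thr, function(t) 100 * mean(imposter > t), numeric(1))
  frr <- vapply(thr, function(t) 100 * mean(genuine < t), numeric(1))
  i <- which.min(abs(far - frr))
  (far[i] + frr[i]) / 2
}
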