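tiny_cfg <- function(...) {
  args <- modifyList(
    list(n_subjects = 3, visits_per_subject = 2, scans_per_visit = 2,
         grid_shape = c(12, 12, 12), master_seed = 11),
    list(...))
  do.call(phantom_config, args)
}

test_that("subject templates are seeded, distinct, and degenerate at zero amplitude", {
  cfg <- tiny_cfg()
  expect_error(make_subject_template(cfg, 0), "out of range")
  expect_error(make_subject_template(cfg, 4), "out of range")

  # same (master_seed, subject) twice -> identical template
  t1 <- make_subject_template(cfg, 1)
  t1b <- make_subject_template(cfg, 1)
  expect_identical(t1$template, t1b$template)

  # zero amplitude -> all subjects share the base support
  cfg0 <- tiny_cfg(subject_amplitude = 0)
  expect_identical(make_subject_template(cfg0, 1)$template,
                   make_subject_template(cfg0, 2)$template)

  # default amplitude: two subjects differ over a substantial shell fraction
  cfg2 <- phantom_config(n_subjects = 2, grid_shape = c(16, 16, 16),
                         subject_amplitude = 0.2, master_seed = 5)
  a <- make_subject_template(cfg2, 1)
  b <- make_subject_template(cfg2, 2)
  shell <- a$shell_mask
  frac <- mean(abs(a$template[shell] - b$template[shell]) > 0.01)
  expect_gt(frac, 0.10)
  expect_true(all(a$template >= 0 & a$template <= 1))
})

test_that("sampled scans decompose into template + visit drift + scan noise", {
  # noise-free: scan equals template voxelwise
  cfg0 <- tiny_cfg(visit_drift_sd = 0, scan_noise_sd = 0)
  tpl <- make_subject_template(cfg0, 1)
  expect_identical(sample_scan(tpl, 1, 1, cfg0)$data, tpl$template)

  # all outputs clipped to [0, 1]
  cfgN <- tiny_cfg(visit_drift_sd = 0.3, scan_noise_sd = 0.3)
  tplN <- make_subject_template(cfgN, 2)
  s <- sample_scan(tplN, 2, 1, cfgN)
  expect_true(all(s$data >= 0 & s$data <= 1))
  expect_error(sample_scan(tplN, 0, 1, cfgN), "1-based")

  # two scans of one visit differ only by the white-noise term: on
  # unclipped shell voxels the difference sd is scan_noise_sd * sqrt(2)
  cfg <- phantom_config(n_subjects = 2, grid_shape = c(40, 40, 40),
                        subject_amplitude = 0.05, visit_drift_sd = 0,
                        scan_noise_sd = 0.02, master_seed = 21)
  tpl <- make_subject_template(cfg, 1)
  s1 <- sample_scan(tpl, 1, 1, cfg)
  s2 <- sample_scan(tpl, 1, 2, cfg)
  keep <- tpl$shell_mask & tpl$template > 0.1 & tpl$template < 0.9
  expect_gte(sum(keep), 1e4)
  expect_equal(sd((s1$data - s2$data)[keep]), 0.02 * sqrt(2),
               tolerance = 0.05)
})

test_that("generate_dataset writes the full grid of volumes deterministically", {
  cfg <- tiny_cfg(scans_per_visit = 3)  # 3 subjects x 2 visits x 3 scans
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  idx <- generate_dataset(cfg, d1)
  expect_equal(nrow(idx$manifest), 18)
  expect_length(list.files(d1, pattern = "\\.nii$"), 18)
  expect_identical(visit_count_table(idx), setNames(3L, "2"))

  # rerun with same config -> byte-identical volumes
  generate_dataset(cfg, d2)
  for (f in list.files(d1, pattern = "\\.nii$")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }

  # volumes reload through the manifest with intact identity
  v <- load_volume(idx, "S002", 2, 3)
  expect_identical(v$subject_id, "S002")
  expect_true(all(v$data >= 0 & v$data <= 1))
})

test_that("mean genuine distance grows with visit drift and scan noise", {
  mean_genuine_dist <- function(drift, noise, mode) {
    dists <- c()
    for (seed in c(101, 202, 303)) {
      cfg <- phantom_config(n_subjects = 2, grid_shape = c(12, 12, 12),
                            subject_amplitude = 0.2, visit_drift_sd = drift,
                            scan_noise_sd = noise, master_seed = seed)
      tpl <- make_subject_template(cfg, 1)
      pairs <- if (mode == "different_visit") {
        list(list(sample_scan(tpl, 1, 1, cfg), sample_scan(tpl, 2, 1, cfg)))
      } else {
        list(list(sample_scan(tpl, 1, 1, cfg), sample_scan(tpl, 1, 2, cfg)))
      }
      dists <- c(dists, vapply(pairs, function(p) gm_distance(p[[1]], p[[2]]),
                               numeric(1)))
    }
    mean(dists)
  }
  by_drift <- vapply(c(0, 0.05, 0.2),
                     function(d) mean_genuine_dist(d, 0.02, "different_visit"),
                     numeric(1))
  expect_true(all(diff(by_drift) >= 0))
  by_noise <- vapply(c(0, 0.02, 0.1),
                     function(n) mean_genuine_dist(0.05, n, "same_visit"),
                     numeric(1))
  expect_true(all(diff(by_noise) >= 0))
})

test_that("phantom config validates and loads from YAML", {
  expect_error(phantom_config(n_subjects = 1), "n_subjects")
  expect_error(phantom_config(scan_noise_sd = -1), "scan_noise_sd")
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 4", "grid_shape: [8, 8, 8]",
               "scan_noise_sd: 0.01", "master_seed: 9"), p)
  cfg <- read_phantom_config(p)
  expect_equal(cfg$n_subjects, 4L)
  expect_equal(cfg$grid_shape, c(8L, 8L, 8L))
  expect_equal(cfg$subject_amplitude, 0.2)  # default retained
  expect_error(read_phantom_config({
    writeLines("bogus_field: 1", p); p
  }), "unknown")
})
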