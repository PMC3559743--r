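#' Pixel-level distance between two aligned GM volumes
#'
#' The matching distance between two spatially normalized gray-matter maps
#' is the sum over all voxel coordinates x of `|G_a(x) - G_b(x)|` (the L1
#' form, default), or optionally the sum of squared differences (L2 form).
#' Both volumes must already live in the common normalized space: same grid
#' shape and voxel size. A smaller distance means a higher probability that
#' the two images come from the same subject.
#'
#' @param a,b [gm_volume()] objects on the same grid.
#' @param metric `"L1"` (sum of absolute differences, default) or `"L2"`
#'   (sum of squared differences).
#' @return Nonnegative scalar distance; 0 iff the volumes are voxelwise
#'   identical.
#' @export
gm_distance <- function(a, b, metric = c("L1", "L2")) {
  stopifnot(inherits(a, "gm_volume"), inherits(b, "gm_volume"))
  metric <- match.arg(metric)
  check_same_grid(a, b)
  diff <- a$data - b$data
  switch(metric, L1 = sum(abs(diff)), L2 = sum(diff^2))
}

#' Construct a pair list
#'
#' Pairs are represented as a data frame with one row per comparison and
#' columns `subject_a, visit_a, scan_a, subject_b, visit_b, scan_b`.
#'
#' @param subject_a,visit_a,scan_a,subject_b,visit_b,scan_b Vectors of equal
#'   length identifying both members of each pair.
#' @return A pair data frame.
#' @export
pair_list <- function(subject_a, visit_a, scan_a,
                      subject_b, visit_b, scan_b) {
  data.frame(subject_a = as.character(subject_a),
             visit_a = as.integer(visit_a), scan_a = as.integer(scan_a),
             subject_b = as.character(subject_b),
             visit_b = as.integer(visit_b), scan_b = as.integer(scan_b),
             stringsAsFactors = FALSE)
}

#' Compute matching distances for a list of pairs
#'
#' Evaluates [gm_distance()] for every pair, labels each result genuine
#' (same subject) or imposter (different subjects), and records the pool
#' extremes `d_min`/`d_max` over exactly this set of comparisons, ready for
#' [normalize_scores()].
#'
#' @param pairs A pair data frame (see [pair_list()]); every id triple must
#'   resolve in `index`.
#' @param index A [dataset_index()].
#' @param metric Distance form, see [gm_distance()].
#' @param volumes Optional precomputed voxel matrix from the internal
#'   loader; when supplied, volumes are not re-read from disk.
#' @return An object of class `score_pool`: list with `results` (data frame
#'   `subject_a, visit_a, scan_a, subject_b, visit_b, scan_b, label,
#'   distance, score`), `d_min`, `d_max`, `metric`. `score` is `NA` until
#'   normalization.
#' @export
pairwise_distances <- function(pairs, index, metric = c("L1", "L2"),
                               volumes = NULL) {
  metric <- match.arg(metric)
  if (!is.data.frame(pairs) || nrow(pairs) == 0L) {
    stop("empty pair list: nothing to match", call. = FALSE)
  }
  id_a <- format_scan_id(pairs$subject_a, pairs$visit_a, pairs$scan_a)
  id_b <- format_scan_id(pairs$subject_b, pairs$visit_b, pairs$scan_b)
  if (is.null(volumes)) {
    need <- unique(c(id_a, id_b))
    all_ids <- format_scan_id(index$manifest$subject_id,
                              index$manifest$visit_id,
                              index$manifest$scan_id)
    rows <- match(need, all_ids)
    if (anyNA(rows)) {
      stop("pair ids not in index: ",
           paste(need[is.na(rows)], collapse = ", "), call. = FALSE)
    }
    volumes <- volume_matrix(index, rows)
  } else {
    missing <- setdiff(unique(c(id_a, id_b)), colnames(volumes))
    if (length(missing)) {
      stop("pair ids not in supplied volumes: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  ca <- match(id_a, colnames(volumes))
  cb <- match(id_b, colnames(volumes))
  d <- vapply(seq_along(ca), function(i) {
    diff <- volumes[, ca[i]] - volumes[, cb[i]]
    if (metric == "L1") sum(abs(diff)) else sum(diff^2)
  }, numeric(1))
  results <- data.frame(
    pairs[, c("subject_a", "visit_a", "scan_a",
              "subject_b", "visit_b", "scan_b")],
    label = ifelse(pairs$subject_a == pairs$subject_b, "genuine", "imposter"),
    distance = d,
    score = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(results) <- NULL
  structure(list(results = results, d_min = min(d), d_max = max(d),
                 metric = metric),
            class = "score_pool")
}

#' @export
print.score_pool <- function(x, ...) {
  cat(sprintf(
    "<score_pool> %d comparisons (%d genuine, %d imposter), %s distance in [%.4g, %.4g]%s\n",
    nrow(x$results), sum(x$results$label == "genuine"),
    sum(x$results$label == "imposter"), x$metric, x$d_min, x$d_max,
    if (all(is.na(x$results$score))) ", scores not yet normalized" else ""))
  invisible(x)
}

#' Min-max normalize matching distances to scores on \[0, 100\]
#'
#' Each distance d is mapped to the matching score
#' `s = 100 * (d_max - d) / (d_max - d_min)`, where `d_max` and `d_min` are
#' the maximum and minimum over all differences of the pool. The most
#' similar pair (d = d_min) scores 100 and the least similar (d = d_max)
#' scores 0: a smaller distance indicates a higher probability that both
#' images come from the same subject. In the degenerate pool where all
#' distances are equal, every score is 100.
#'
#' @param pool A `score_pool` from [pairwise_distances()].
#' @return The pool with the `score` column filled.
#' @export
normalize_scores <- function(pool) {
  stopifnot(inherits(pool, "score_pool"))
  if (nrow(pool$results) == 0L) stop("empty score pool", call. = FALSE)
  rng <- pool$d_max - pool$d_min
  pool$results$score <- if (rng > 0) {
    100 * (pool$d_max - pool$results$distance) / rng
  } else {
    rep(100, nrow(pool$results))
  }
  pool
}

#' Export a score table to CSV
#'
#' Columns `id_a, id_b, label, distance, score`, rows sorted
#' lexicographically by (id_a, id_b) for deterministic output.
#'
#' @param pool A `score_pool`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(pool, path) {
  stopifnot(inherits(pool, "score_pool"))
  r <- pool$results
  out <- data.frame(
    id_a = format_scan_id(r$subject_a, r$visit_a, r$scan_a),
    id_b = format_scan_id(r$subject_b, r$visit_b, r$scan_b),
    label = r$label, distance = r$distance, score = r$score,
    stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), ]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Scores of one label class, after normalization.
pool_scores <- function(pool, label) {
  s <- pool$results$score[pool$results$label == label]
  if (anyNA(s)) stop("scores not normalized; call normalize_scores() first",
                     call. = FALSE)
  s
}
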