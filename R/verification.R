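#' Enumerate genuine matching pairs under a visit protocol
#'
#' A genuine pair compares two images of the same subject. Two protocols
#' are supported: `"same_visit"` pairs scans acquired in the same session
#' (all unordered within-visit scan pairs, for every subject and visit);
#' `"different_visit"` pairs scans of one subject across distinct sessions
#' (all unordered cross-visit scan pairs). Output order is deterministic
#' (subjects, visits, scans sorted ascending) and duplicate-free.
#'
#' @param index A [dataset_index()].
#' @param mode `"same_visit"` or `"different_visit"`.
#' @return A pair data frame (see [pair_list()]); zero rows when the visit
#'   structure admits no pairs.
#' @export
enumerate_genuine_pairs <- function(index,
                                    mode = c("same_visit", "different_visit")) {
  stopifnot(inherits(index, "dataset_index"))
  mode <- match.arg(mode)
  if (nrow(index$manifest) == 0L) stop("empty index", call. = FALSE)
  out <- list()
  for (subj in subjects(index)) {
    m <- index$manifest[index$manifest$subject_id == subj, ]
    m <- m[order(m$visit_id, m$scan_id), ]
    n <- nrow(m)
    if (n < 2L) next
    ij <- combn_pairs(n)
    same_visit <- m$visit_id[ij[, 1]] == m$visit_id[ij[, 2]]
    keep <- if (mode == "same_visit") same_visit else !same_visit
    if (!any(keep)) next
    ij <- ij[keep, , drop = FALSE]
    out[[subj]] <- pair_list(subj, m$visit_id[ij[, 1]], m$scan_id[ij[, 1]],
                             subj, m$visit_id[ij[, 2]], m$scan_id[ij[, 2]])
  }
  if (!length(out)) return(pair_list(character(), integer(), integer(),
                                     character(), integer(), integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# All unordered index pairs (i < j) of 1..n as an n*(n-1)/2 x 2 matrix,
# ordered by first then second index.
combn_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(), 0, 2))
  t(combn(n, 2))
}

#' Count genuine matching pairs from a visit structure
#'
#' Closed-form counterpart of [enumerate_genuine_pairs()] for one subject
#' scanned at V visits with m_1..m_V scans. For different-visit matching
#' the count is the sum over visit pairs j < k of `m_j * m_k`, which reduces
#' to `choose(V, 2) * m^2` when every visit has m scans; for same-visit
#' matching it is the sum over visits of `choose(m_j, 2)`. The dataset
#' total is the sum of this count over subjects (equivalently, aggregated
#' over the n_V subjects having each visit count V).
#'
#' @param scans_per_visit Integer vector m_1..m_V of scans per visit,
#'   all >= 1.
#' @param mode `"same_visit"` or `"different_visit"`.
#' @return Integer pair count.
#' @export
count_genuine_pairs <- function(scans_per_visit,
                                mode = c("same_visit", "different_visit")) {
  mode <- match.arg(mode)
  m <- as.numeric(scans_per_visit)
  if (length(m) == 0L) stop("empty visit structure", call. = FALSE)
  if (any(m < 1)) stop("every visit has at least one scan", call. = FALSE)
  n <- if (mode == "different_visit") {
    (sum(m)^2 - sum(m^2)) / 2
  } else {
    sum(choose(m, 2))
  }
  as.integer(n)
}

#' Enumerate imposter matching pairs
#'
#' An imposter pair compares images of two different subjects. Following
#' the one-volume-per-subject convention (which makes the imposter count
#' `choose(N_subjects, 2)`), a selector picks exactly one scan per subject
#' — by default the second scan of the first visit — and all unordered
#' cross-subject pairs of the selected volumes are returned.
#'
#' @param index A [dataset_index()] with at least two subjects.
#' @param selector Named vector `c(visit = ..., scan = ...)` choosing the
#'   one volume per subject.
#' @return A pair data frame with `choose(N, 2)` rows, N the number of
#'   subjects.
#' @export
enumerate_imposter_pairs <- function(index, selector = c(visit = 1L, scan = 2L)) {
  stopifnot(inherits(index, "dataset_index"))
  subj <- subjects(index)
  if (length(subj) < 2L) {
    stop("imposter matching needs at least 2 subjects", call. = FALSE)
  }
  sel <- select_one_per_subject(index, selector)
  ij <- combn_pairs(length(subj))
  pair_list(sel$subject_id[ij[, 1]], sel$visit_id[ij[, 1]], sel$scan_id[ij[, 1]],
            sel$subject_id[ij[, 2]], sel$visit_id[ij[, 2]], sel$scan_id[ij[, 2]])
}

# Resolve the (visit, scan) selector for every subject; error if any
# subject lacks the selected scan.
select_one_per_subject <- function(index, selector) {
  if (!all(c("visit", "scan") %in% names(selector))) {
    stop("selector must name visit and scan", call. = FALSE)
  }
  subj <- subjects(index)
  m <- index$manifest
  hit <- m$visit_id == selector[["visit"]] & m$scan_id == selector[["scan"]]
  sel <- m[hit, ]
  missing <- setdiff(subj, sel$subject_id)
  if (length(missing)) {
    stop("selector (visit ", selector[["visit"]], ", scan ",
         selector[["scan"]], ") resolves no volume for subject(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sel[order(sel$subject_id), ]
}

#' FAR and FRR at one decision threshold
#'
#' The false rejection rate is the percentage of genuine pairs with scores
#' strictly below the threshold; the false acceptance rate is the
#' percentage of imposter pairs with scores strictly above it. Scores equal
#' to the threshold therefore count as accepted genuine and correctly
#' rejected imposter comparisons.
#'
#' @param genuine_scores,imposter_scores Nonempty numeric score vectors.
#' @param threshold Decision threshold in score units.
#' @return Named numeric `c(far = , frr = )`, both percentages in
#'   \[0, 100\].
#' @export
far_frr_at_threshold <- function(genuine_scores, imposter_scores, threshold) {
  if (!length(genuine_scores) || !length(imposter_scores)) {
    stop("both score lists must be nonempty", call. = FALSE)
  }
  c(far = 100 * mean(imposter_scores > threshold),
    frr = 100 * mean(genuine_scores < threshold))
}

#' ROC curve of a verification experiment
#'
#' Sweeps the decision threshold over all values where FAR or FRR can
#' change: the observed scores, the midpoints between adjacent distinct
#' scores (FAR and FRR are step functions, constant between observations,
#' and the open intervals between scores carry their own operating points),
#' and one point below the minimum and one above the maximum score. Along
#' the sweep FAR is nonincreasing and FRR nondecreasing; the endpoints are
#' (FAR 100, FRR 0) and (FAR 0, FRR 100).
#'
#' @inheritParams far_frr_at_threshold
#' @return An object of class `roc_curve`: data frame with columns
#'   `threshold`, `far`, `frr`, ordered by threshold.
#' @export
roc_curve <- function(genuine_scores, imposter_scores) {
  if (!length(genuine_scores) || !length(imposter_scores)) {
    stop("both score lists must be nonempty", call. = FALSE)
  }
  s <- sort(unique(c(genuine_scores, imposter_scores)))
  mids <- if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2 else numeric()
  thr <- sort(unique(c(min(s) - 1, s, mids, max(s) + 1)))
  fr <- vapply(thr, function(t) {
    far_frr_at_threshold(genuine_scores, imposter_scores, t)
  }, numeric(2))
  structure(data.frame(threshold = thr, far = fr["far", ], frr = fr["frr", ]),
            class = c("roc_curve", "data.frame"))
}

#' Equal error rate of an ROC curve
#'
#' The EER is the operating point where FAR equals FRR. If some swept
#' threshold attains FAR == FRR exactly, that value is returned (smallest
#' such threshold on ties) and `exact_crossing` is `TRUE`; otherwise FAR(t)
#' and FRR(t) are linearly interpolated between the two adjacent swept
#' thresholds where FAR - FRR changes sign and the crossing value is
#' returned with `exact_crossing = FALSE`.
#'
#' @param curve A [roc_curve()].
#' @return List of class `eer_result` with `eer` (percentage in
#'   \[0, 100\]), `threshold_at_eer` and `exact_crossing`.
#' @export
eer <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"), nrow(curve) > 0)
  d <- curve$far - curve$frr
  hit <- which(d == 0)
  if (length(hit)) {
    i <- hit[1]
    return(structure(list(eer = curve$far[i],
                          threshold_at_eer = curve$threshold[i],
                          exact_crossing = TRUE),
                     class = "eer_result"))
  }
  # d starts at +100 (threshold below all scores) and ends at -100.
  i <- which(d[-length(d)] > 0 & d[-1] < 0)[1]
  alpha <- d[i] / (d[i] - d[i + 1])
  structure(list(
    eer = curve$far[i] + alpha * (curve$far[i + 1] - curve$far[i]),
    threshold_at_eer = curve$threshold[i] +
      alpha * (curve$threshold[i + 1] - curve$threshold[i]),
    exact_crossing = FALSE), class = "eer_result")
}

#' @export
print.eer_result <- function(x, ...) {
  cat(sprintf("EER %.4g%% at threshold %.4g (%s crossing)\n", x$eer,
              x$threshold_at_eer,
              if (x$exact_crossing) "exact" else "interpolated"))
  invisible(x)
}

#' Separation gap between genuine and imposter scores
#'
#' Reports the maximum imposter score and minimum genuine score. The two
#' distributions are separable iff the maximum imposter score is strictly
#' below the minimum genuine score; any threshold strictly between them
#' then yields FAR = FRR = 0, hence an EER of 0.
#'
#' @inheritParams far_frr_at_threshold
#' @return List with `max_imposter`, `min_genuine`, `separable`.
#' @export
separation_gap <- function(genuine_scores, imposter_scores) {
  if (!length(genuine_scores) || !length(imposter_scores)) {
    stop("both score lists must be nonempty", call. = FALSE)
  }
  mx <- max(imposter_scores)
  mn <- min(genuine_scores)
  list(max_imposter = mx, min_genuine = mn, separable = mx < mn)
}

#' Histogram of matching scores as percentages
#'
#' Bins cover \[0, 100\] in widths of `bin_width` (the last bin is padded
#' to reach 100 when the width does not divide it); each score falls into
#' the bin `[left, right)`, with 100 included in the last bin. Percentages
#' sum to 100.
#'
#' @param scores Nonempty numeric scores in \[0, 100\].
#' @param bin_width Positive bin width in score units.
#' @return Data frame with columns `bin_center` and `percentage`.
#' @export
score_histogram <- function(scores, bin_width = 5) {
  if (!length(scores)) stop("empty score list", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive", call. = FALSE)
  }
  breaks <- seq(0, 100, by = bin_width)
  if (tail(breaks, 1) < 100) breaks <- c(breaks, 100)
  nb <- length(breaks) - 1L
  idx <- pmin(pmax(findInterval(scores, breaks), 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin_center = (head(breaks, -1) + tail(breaks, -1)) / 2,
             percentage = 100 * counts / length(scores))
}
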