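test_that("genuine pair enumeration follows the visit protocols", {
  # 1 subject, visits [3, 3]: 9 cross-visit pairs, C(3,2)*2 within-visit
  idx <- index_from_structure(list(A = c(3, 3)))
  dv <- enumerate_genuine_pairs(idx, "different_visit")
  expect_equal(nrow(dv), 9)
  expect_true(all(dv$subject_a == dv$subject_b))
  expect_true(all(dv$visit_a != dv$visit_b))
  sv <- enumerate_genuine_pairs(idx, "same_visit")
  expect_equal(nrow(sv), 6)
  expect_true(all(sv$visit_a == sv$visit_b & sv$scan_a != sv$scan_b))

  # single visit: no different-visit pairs; C(3,2) same-visit pairs
  idx1 <- index_from_structure(list(A = 3))
  expect_equal(nrow(enumerate_genuine_pairs(idx1, "different_visit")), 0)
  expect_equal(nrow(enumerate_genuine_pairs(idx1, "same_visit")), 3)

  # no duplicates, deterministic order
  key <- paste(dv$visit_a, dv$scan_a, dv$visit_b, dv$scan_b)
  expect_false(anyDuplicated(key) > 0)
  expect_identical(dv, enumerate_genuine_pairs(idx, "different_visit"))
})

test_that("closed-form genuine pair counts match brute-force enumeration", {
  expect_equal(count_genuine_pairs(c(3, 3), "different_visit"), 9L)
  expect_equal(count_genuine_pairs(5, "different_visit"), 0L)
  expect_equal(count_genuine_pairs(c(4, 3, 3), "different_visit"), 33L)
  expect_equal(count_genuine_pairs(c(3, 3), "same_visit"), 6L)
  expect_error(count_genuine_pairs(integer(), "same_visit"), "empty")
  expect_error(count_genuine_pairs(c(3, 0), "same_visit"), "at least one")

  # oracle equivalence on random visit structures, both against the
  # brute-force double loop and against enumeration length
  set.seed(1234)
  for (rep in 1:100) {
    m <- sample(1:4, sample(1:4, 1), replace = TRUE)
    for (mode in c("same_visit", "different_visit")) {
      expected <- brute_genuine_count(m, mode)
      expect_equal(count_genuine_pairs(m, mode), expected)
      idx <- index_from_structure(list(X = m))
      expect_equal(nrow(enumerate_genuine_pairs(idx, mode)), expected)
    }
  }
})

test_that("imposter pairs use one volume per subject, all cross-subject", {
  str2 <- function(n) setNames(rep(list(c(3, 3)), n), sprintf("S%03d", 1:n))
  expect_equal(nrow(enumerate_imposter_pairs(index_from_structure(str2(2)))), 1)
  expect_equal(nrow(enumerate_imposter_pairs(index_from_structure(str2(10)))), 45)

  ip <- enumerate_imposter_pairs(index_from_structure(str2(10)))
  expect_true(all(ip$subject_a != ip$subject_b))
  # default selector: second scan of the first visit
  expect_true(all(ip$visit_a == 1 & ip$scan_a == 2))

  # a subject lacking the selected scan is an error
  idx <- index_from_structure(list(A = c(3, 3), B = c(1, 3)))
  expect_error(enumerate_imposter_pairs(idx), "resolves no volume.*B")
  # but a different selector can resolve it
  expect_equal(nrow(enumerate_imposter_pairs(idx, c(visit = 2, scan = 1))), 1)
  expect_error(
    enumerate_imposter_pairs(index_from_structure(list(A = c(3, 3)))),
    "at least 2 subjects")
})

test_that("FAR/FRR use strict inequalities at the threshold", {
  expect_equal(far_frr_at_threshold(c(80, 90), c(60, 85), 85),
               c(far = 0, frr = 50))
  # scores equal to t count as accepted genuine / rejected imposter
  expect_equal(far_frr_at_threshold(c(85), c(85), 85), c(far = 0, frr = 0))
  expect_equal(far_frr_at_threshold(c(80, 90), c(60, 85), 0),
               c(far = 100, frr = 0))
  expect_equal(far_frr_at_threshold(c(80, 90), c(60, 85), 100),
               c(far = 0, frr = 100))
  expect_error(far_frr_at_threshold(numeric(), c(1), 5), "nonempty")
})

test_that("ROC sweep covers the operating range with monotone FAR/FRR", {
  # fully separated scores: some threshold attains FAR = FRR = 0
  curve <- roc_curve(c(90, 95), c(10, 20))
  expect_true(any(curve$far == 0 & curve$frr == 0))

  # interleaved scores contain the 50/50 operating point
  curve <- roc_curve(c(1, 3), c(2, 4))
  expect_true(any(curve$far == 50 & curve$frr == 50))

  # endpoints: (FAR 100, FRR 0) and (FAR 0, FRR 100)
  expect_equal(unlist(curve[1, c("far", "frr")]), c(far = 100, frr = 0))
  expect_equal(unlist(curve[nrow(curve), c("far", "frr")]),
               c(far = 0, frr = 100))

  # monotone in threshold on random score sets
  for (seed in 1:5) {
    set.seed(seed)
    g <- runif(40, 40, 100)
    i <- runif(60, 0, 70)
    curve <- roc_curve(g, i)
    expect_true(all(diff(curve$far) <= 0))
    expect_true(all(diff(curve$frr) >= 0))
    expect_true(all(curve$far >= 0 & curve$far <= 100))
  }
})

test_that("EER matches exhaustive threshold search", {
  expect_equal(eer(roc_curve(c(90, 95), c(10, 20)))$eer, 0)
  e <- eer(roc_curve(c(1, 3), c(2, 4)))
  expect_equal(e$eer, 50)
  expect_true(e$exact_crossing)
  # fully inverted scores: both error rates reach 100 between the groups
  expect_equal(eer(roc_curve(c(10, 20), c(90, 95)))$eer, 100)

  # agreement with an independent fine-grid search on random score sets
  # (sets large enough that the step functions resolve half a point)
  set.seed(77)
  for (rep in 1:20) {
    g <- runif(400, 30, 100)
    i <- runif(400, 0, 80)
    e <- eer(roc_curve(g, i))
    expect_lt(abs(e$eer - grid_eer(g, i)), 0.5)
    expect_gte(e$eer, 0)
    expect_lte(e$eer, 100)
  }
})

test_that("separation gap characterizes the zero-EER condition", {
  gap <- separation_gap(86.03, 83.46)
  expect_equal(gap$max_imposter, 83.46)
  expect_equal(gap$min_genuine, 86.03)
  expect_true(gap$separable)
  expect_false(separation_gap(50, 60)$separable)

  # separable <=> EER 0, property-tested on random score sets
  set.seed(31)
  for (rep in 1:20) {
    g <- runif(25, sample(c(20, 60), 1), 100)
    i <- runif(25, 0, sample(c(50, 90), 1))
    sep <- separation_gap(g, i)$separable
    e <- eer(roc_curve(g, i))$eer
    expect_identical(sep, e == 0)
  }
})

test_that("score histograms are percentage-normalized over [0,100]", {
  h <- score_histogram(95, 5)
  expect_equal(h$percentage[h$bin_center == 97.5], 100)
  expect_equal(sum(h$percentage), 100)

  h <- score_histogram(c(10, 30, 50, 70), 20)
  expect_equal(h$bin_center, c(10, 30, 50, 70, 90))
  expect_equal(h$percentage, c(25, 25, 25, 25, 0))

  # random scores: percentages always sum to 100, bins span [0, 100]
  set.seed(5)
  h <- score_histogram(runif(1000, 0, 100), 7)
  expect_equal(sum(h$percentage), 100)
  expect_equal(min(h$bin_center - 3.5), 0)
  expect_error(score_histogram(numeric(), 5), "empty")
  expect_error(score_histogram(50, 0), "positive")
})
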