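test_that("a brightness step is detected at the discontinuity only", {
  rep_ <- detect_edges(c(1, 1, 1, 1, 5, 5, 5, 5), duration = 500)
  expect_equal(rep_$pair[rep_$edge], 4L)
  expect_equal(rep_$mode[rep_$edge], "NULL")
  expect_true(all(rep_$mode[!rep_$edge] == "AND"))
})

test_that("uniform input produces no edges", {
  rep_ <- detect_edges(rep(3, 6), duration = 500)
  expect_false(any(rep_$edge))
  rep0 <- probe_edges(edge_detector(5))
  expect_false(any(rep0$edge))
})

test_that("detection uses the gates' own summation rule", {
  det <- edge_detector(3, delta = 0.006, window = 0.4)
  # contrast just below the window: no edge
  det_low <- charge(det, c(1, 1, 1), duration = 0)
  det_low$q <- c(0, 0, 66)  # 66 * 0.006 = 0.396 < 0.4
  expect_false(any(probe_edges(det_low)$edge))
  det_hi <- det
  det_hi$q <- c(0, 0, 67)   # 67 * 0.006 = 0.402 > 0.4
  expect_equal(probe_edges(det_hi)$edge, c(FALSE, TRUE))
})

test_that("longer charging increases contrast sensitivity", {
  b <- c(1, 1.2, 1.2)
  short <- detect_edges(b, duration = 100)
  long <- detect_edges(b, duration = 2000)
  expect_false(any(short$edge))
  expect_true(long$edge[1])
})

test_that("probabilistic charging is seeded and probing non-destructive", {
  det <- edge_detector(4)
  a <- charge(det, c(1, 1, 4, 4), 500, mode = "probability", seed = 3)
  b <- charge(det, c(1, 1, 4, 4), 500, mode = "probability", seed = 3)
  expect_identical(a$q, b$q)
  before <- a$q
  invisible(probe_edges(a))
  expect_identical(a$q, before)
})

test_that("reset restores the initial equal delays", {
  det <- charge(edge_detector(4), c(1, 5, 1, 5), 300)
  expect_true(any(probe_edges(det)$edge))
  det <- reset_detector(det)
  expect_false(any(probe_edges(det)$edge))
  expect_true(all(det$q == 0))
})

test_that("charging validates the brightness vector", {
  det <- edge_detector(3)
  expect_error(charge(det, c(1, 2), 100), "length")
  expect_error(charge(det, c(1, -2, 1), 100), "non-negative")
  expect_error(edge_detector(1), "two input")
  # all-zero brightness leaves the detector unchanged
  expect_identical(charge(det, c(0, 0, 0), 100)$q, det$q)
})
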