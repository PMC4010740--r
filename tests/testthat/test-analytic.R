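canonical_gate <- function(delta = 0.006) {
  build_generalized_and(c(1, 2, 5), c(30, 27, 25), delta = delta,
                        window = 0.4)
}

test_that("delay lines reproduce the chain arrangement", {
  L <- build_lines(canonical_gate(), delta = 0.006)
  expect_equal(L$chain_id, c("in1", "in2", "in3"))
  expect_equal(L$intercept, c(30, 27, 25))
  expect_equal(L$slope, c(1, 2, 5) * 0.006)
  expect_equal(L$n, c(1, 2, 5))
  expect_equal(line_delays(L, 0)[, 1], c(30, 27, 25))
  expect_equal(line_delays(L, 100)[, 1], c(30.6, 28.2, 28))
})

test_that("pairwise intersections follow the closed form", {
  L <- build_lines(canonical_gate(), delta = 0.006)
  pi <- pairwise_intersections(L, horizon = 1000)
  expect_equal(nrow(pi), 3)
  got <- setNames(pi$q, paste(pi$chain_i, pi$chain_j))
  expect_equal(got[["in1 in2"]], (30 - 27) / (0.012 - 0.006))
  expect_equal(got[["in1 in3"]], (30 - 25) / (0.030 - 0.006))
  expect_equal(got[["in2 in3"]], (27 - 25) / (0.030 - 0.012))
  # parallel lines produce no intersection
  L2 <- rbind(L[1, ], L[1, ]); L2$chain_id <- c("a", "b")
  expect_equal(nrow(pairwise_intersections(L2, 1000)), 0)
  # intersections beyond the horizon are dropped
  expect_equal(nrow(pairwise_intersections(L, horizon = 100)), 0)
})

test_that("firing regions have half-width w over the slope difference", {
  L <- build_lines(canonical_gate(), delta = 0.006)
  fr <- firing_regions(L, threshold = 1, window = 0.4, horizon = 1000)
  ivs <- lapply(fr$subsets, `[[`, "interval")
  names(ivs) <- vapply(fr$subsets, function(s)
    paste(s$members, collapse = ","), character(1))
  expect_equal(ivs[["in2,in3"]],
               (27 - 25) / 0.018 + c(-1, 1) * 0.4 / 0.018)
  expect_equal(ivs[["in1,in3"]],
               (30 - 25) / 0.024 + c(-1, 1) * 0.4 / 0.024)
  expect_equal(ivs[["in1,in2"]],
               (30 - 27) / 0.006 + c(-1, 1) * 0.4 / 0.006)
  expect_equal(nrow(fr$regions), 3)
  # membership closure agrees with the intervals
  expect_true(fr$fires_at(111))
  expect_false(fr$fires_at(150))
  expect_true(fr$fires_at(500))
})

test_that("weighted strengths remove sub-threshold pairs", {
  circ <- build_generalized_and(c(1, 2, 5), c(30, 27, 25),
                                strengths = c(0.3, 0.75, 0.5),
                                delta = 0.004, window = 0.4)
  fr <- firing_regions(build_lines(circ, delta = 0.004), 1, 0.4, 1000)
  pairs <- vapply(fr$subsets, function(s)
    paste(sort(s$members), collapse = ","), character(1))
  expect_false("in1,in3" %in% pairs)  # 0.3 + 0.5 < 1
  expect_setequal(pairs, c("in1,in2", "in2,in3"))
})

test_that("inhibition regions follow the closed form", {
  e <- delay_line("e", 30, 0.006)
  i <- delay_line("i", 26, 0.012, sign = "inhibitory")
  # exc - inh = 4 - 0.006 q in [1, 7]: q in [-500, 500] -> [0, 500]
  m <- inhibition_regions(e, i, c(1, 7), horizon = 1000)
  expect_equal(unname(m[1, ]), c(0, 500))
  # parallel, offset inside the window: whole horizon
  i2 <- delay_line("i", 26, 0.006, sign = "inhibitory")
  m2 <- inhibition_regions(e, i2, c(1, 7), horizon = 1000)
  expect_equal(unname(m2[1, ]), c(0, 1000))
  # parallel, offset outside: empty
  i3 <- delay_line("i", 10, 0.006, sign = "inhibitory")
  expect_equal(nrow(inhibition_regions(e, i3, c(1, 7), 1000)), 0)
})

test_that("the mode timeline is piecewise constant with exact boundaries", {
  tl <- mode_timeline(canonical_gate(), delta = 0.006, horizon = 1000)
  expect_s3_class(tl, "mode_timeline")
  expect_equal(tl$label,
               c("NULL", "AND(in2,in3)", "NULL", "AND(in1,in3)", "NULL",
                 "AND(in1,in2)", "NULL"))
  expect_equal(tl$q_start[2], 2 / 0.018 - 0.4 / 0.018)
  expect_equal(tl$q_end[6], 3 / 0.006 + 0.4 / 0.006)
  expect_equal(tl$q_start[1], 0)
  expect_equal(tl$q_end[nrow(tl)], 1000)
})

test_that("discretization assigns fractional boundaries to the later integer", {
  tl <- mode_timeline(canonical_gate(), delta = 0.006, horizon = 1000)
  d <- discretize_timeline(tl)
  # first AND interval starts at 88.89: q = 88 NULL, q = 89 AND
  expect_equal(d$label[d$q == 88], "NULL")
  expect_equal(d$label[d$q == 89], "AND(in2,in3)")
  expect_equal(d$label[d$q == 133], "AND(in2,in3)")
  expect_equal(d$label[d$q == 134], "NULL")
})

test_that("region boundaries rescale with the latency increment", {
  circ <- canonical_gate()
  expect_true(rescale_check(circ, 0.004, 0.006, horizon = 1500))
  expect_true(rescale_check(circ, 0.006, 0.006, horizon = 1000))
  f1 <- firing_regions(build_lines(circ, 0.004), 1, 0.4, 1500)
  f2 <- firing_regions(build_lines(circ, 0.006), 1, 0.4, 1000)
  expect_equal(as.matrix(f2$regions), as.matrix(f1$regions) * 2 / 3)
})

test_that("synfire chains with matching differences are equivalent", {
  a <- build_generalized_and(c(1, 2, 5), c(30, 27, 25), delta = 0.006)
  b <- build_generalized_and(c(26, 27, 30), c(156, 153, 151), delta = 0.006)
  expect_true(synfire_equivalent(a, b, 0.006, 600))
  # breaking the length differences breaks the equivalence
  c3 <- build_generalized_and(c(26, 28, 30), c(156, 153, 151), delta = 0.006)
  expect_false(synfire_equivalent(a, c3, 0.006, 600))
})
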