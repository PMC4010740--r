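test_that("every fixture builds a valid configuration", {
  for (nm in dlg_fixture()) {
    fx <- dlg_fixture(nm)
    if (!is.null(fx$circuit)) {
      expect_s3_class(fx$circuit, "circuit_spec")
      expect_silent(validate_circuit(fx$circuit))
      expect_s3_class(fx$protocol, "stimulation_protocol")
    }
    if (!is.null(fx$detector)) expect_s3_class(fx$detector, "edge_detector")
    if (!is.null(fx$population)) {
      expect_s3_class(fx$population, "population_spec")
    }
  }
})

test_that("unknown fixture names list the available ones", {
  expect_error(dlg_fixture("fig99"), "available: fig2_and")
})

test_that("fixture parameterizations match their study conditions", {
  fx <- dlg_fixture("fig6d")
  L <- build_lines(fx$circuit, fx$delta)
  expect_equal(L$n, c(1, 2, 5))
  expect_equal(L$intercept, c(30, 27, 25))
  expect_equal(fx$delta, 0.006)
  pop <- dlg_fixture("fig13_population")$population
  expect_equal(pop$size, 40L)
  expect_equal(pop$connection_probability, 0.1)
  expect_equal(pop$delay_jitter, 0.15)
  expect_equal(pop$delta, 0.04)
  mv <- dlg_fixture("fig10_varying")
  expect_equal(mv$moderation_interval, c(250, 475))
  expect_equal(mv$moderation_probability, 0.1)
  expect_equal(unique(mv$protocol$probability[300, "in2"]), 0.1)
})

test_that("the three-chain fixtures share their intersection structure", {
  a <- dlg_fixture("fig6c"); d <- dlg_fixture("fig6d")
  ia <- pairwise_intersections(build_lines(a$circuit, a$delta), 2000)
  id <- pairwise_intersections(build_lines(d$circuit, d$delta), 2000)
  # delta 0.004 vs 0.006: abscissae scale by 3/2
  expect_equal(sort(ia$q), sort(id$q) * 0.006 / 0.004)
})
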