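test_that("population_spec validates its parameters", {
  expect_error(population_spec(size = 0))
  expect_error(population_spec(connection_probability = 1.5))
  expect_error(population_spec(g_weak = 0))
  expect_error(population_spec(dt = 0))
  s <- population_spec()
  expect_equal(s$size, 40L)
  expect_equal(s$connection_probability, 0.1)
  expect_equal(s$delay_jitter, 0.15)
  expect_equal(s$delta, 0.04)
})

test_that("a strong drive fires every neuron, silence stays at rest", {
  spec <- population_spec()
  ev <- data.frame(time = rep(1, 3), g = spec$g_strong, neuron = 1:3)
  r <- simulate_population(ev, 3, spec)
  expect_true(all(!is.na(r$first_spike)))
  expect_true(all(r$first_spike > 1))
  expect_true(all(r$n_spikes >= 1))
  r0 <- simulate_population(ev[0, ], 3, spec)
  expect_true(all(is.na(r0$first_spike)))
  expect_true(all(r0$n_spikes == 0))
})

test_that("a single weak input is sub-threshold, coincident many fire", {
  spec <- population_spec()
  one <- simulate_population(data.frame(time = 1, g = spec$g_weak,
                                        neuron = 1), 1, spec)
  expect_true(is.na(one$first_spike))
  eight <- simulate_population(data.frame(time = rep(1, 8), g = spec$g_weak,
                                          neuron = rep(1, 8)), 1, spec)
  expect_false(is.na(eight$first_spike))
})

test_that("weak inputs must be near-coincident to fire the target", {
  spec <- population_spec()
  spread <- simulate_population(
    data.frame(time = seq(1, by = 3, length.out = 8), g = spec$g_weak,
               neuron = rep(1, 8)), 1, spec, t_end = 40)
  expect_true(is.na(spread$first_spike))
})

test_that("wiring respects the connection probability and delay center", {
  spec <- population_spec()
  set.seed(1)
  p <- wire_projection(200, 200, center = 5, spec)
  expect_equal(mean(p$mask), 0.1, tolerance = 0.01)
  expect_equal(mean(p$delays, na.rm = TRUE), 5, tolerance = 0.01)
  expect_true(all(p$delays >= 0, na.rm = TRUE))
  expect_true(all(is.na(p$delays[!p$mask])))
})

test_that("projection events apply the per-source latency stretch", {
  proj <- list(mask = matrix(TRUE, 2, 2), delays = matrix(3, 2, 2))
  spikes <- c(10, 20); q <- c(0, 100)
  ev <- dlgsim:::projection_events(spikes, q, proj, g = 1, delta = 0.04)
  # arrivals: spike + q*delta + delay
  expect_setequal(round(ev$time, 6), round(c(13, 13, 27, 27), 6))
  # silent sources generate no events
  ev2 <- dlgsim:::projection_events(c(10, NA), q, proj, 1, 0.04)
  expect_equal(nrow(ev2), 2)
})

test_that("wiring draws are seed-reproducible", {
  spec <- population_spec()
  a <- wire_populations(spec, seed = 5)
  b <- wire_populations(spec, seed = 5)
  c <- wire_populations(spec, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$A$mask, c$A$mask))
})

test_that("the firing-probability curve decreases with the input lag", {
  spec <- population_spec()
  res <- firing_probability_vs_gamma(spec, gamma = c(0, 3), trials = 5,
                                     seed = 2)
  agg <- aggregate(fraction ~ gamma, res, mean)
  expect_true(agg$fraction[agg$gamma == 0] >
                agg$fraction[agg$gamma == 3])
})
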