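test_that("neuron_spec validates its fields", {
  n <- neuron_spec("a", l0 = 1, delta = 0.005)
  expect_s3_class(n, "neuron_spec")
  expect_error(neuron_spec("a", l0 = -1), "l0")
  expect_error(neuron_spec("a", delta = -0.001), "delta")
  expect_error(neuron_spec("a", window = 0), "window")
  expect_error(neuron_spec("a", threshold = 0), "threshold")
  expect_error(neuron_spec(""), "nzchar")
})

test_that("link_spec validates delay, strength and sign", {
  expect_error(link_spec("a", "b", delay = -1), "delay")
  expect_error(link_spec("a", "b", delay = 1, strength = 0), "strength")
  expect_error(link_spec("a", "b", delay = 1, strength = 1.5), "strength")
  expect_error(link_spec("a", "b", delay = 1, sign = "modulatory"))
  l <- link_spec("a", "b", delay = 2, strength = 0.5, sign = "inhibitory")
  expect_identical(l$sign, "inhibitory")
})

test_that("latency stretches linearly with the evoked-spike count", {
  n <- neuron_spec("a", l0 = 1.2, delta = 0.004)
  expect_equal(latency_of(n, 0), 1.2)
  expect_equal(latency_of(n, c(0, 100, 250)), 1.2 + c(0, 100, 250) * 0.004)
  expect_error(latency_of(n, -1), "q")
})

test_that("chain delay grows n times faster than a single latency", {
  ch <- chain_spec(5, tau0 = 25)
  expect_equal(chain_delay(ch, 0.006, 0), 25)
  expect_equal(chain_delay(ch, 0.006, 100), 25 + 5 * 100 * 0.006)
  one <- chain_spec(1, tau0 = 25)
  q <- 0:10
  expect_equal(chain_delay(ch, 0.006, q) - 25,
               5 * (chain_delay(one, 0.006, q) - 25))
})

test_that("circuit validation catches malformed graphs", {
  ns <- lapply(c("a", "b"), neuron_spec)
  expect_error(circuit_spec(ns, list(link_spec("a", "c", 1)),
                            inputs = "a", output = "b"), "unknown neuron")
  expect_error(circuit_spec(ns, list(link_spec("a", "b", 1),
                                     link_spec("b", "a", 1)),
                            inputs = "a", output = "b"), "acyclic")
  expect_error(circuit_spec(c(ns, ns[1]), list(link_spec("a", "b", 1)),
                            inputs = "a", output = "b"), "duplicate")
  expect_error(circuit_spec(ns, list(link_spec("a", "b", 1)),
                            inputs = "a", output = "b",
                            inhibition_window = c(7, 1)), "inhibition_window")
  ns3 <- lapply(c("a", "b", "c"), neuron_spec)
  expect_error(circuit_spec(ns3, list(link_spec("a", "b", 1)),
                            inputs = "a", output = "b"), "unreachable")
})

test_that("temporal summation uses a strict window comparison", {
  # within the window: fires
  arr <- list(time = c(10, 10.39), strength = c(0.5, 0.5))
  expect_true(summation_decision(arr, 1, 0.4)$fires)
  # exactly w apart: does not sum
  arr2 <- list(time = c(10, 10.4), strength = c(0.5, 0.5))
  expect_false(summation_decision(arr2, 1, 0.4)$fires)
  # single strong arrival
  expect_true(summation_decision(list(time = 5, strength = 1), 1, 0.4)$fires)
  # empty
  expect_false(summation_decision(list(time = numeric(0),
                                       strength = numeric(0)), 1, 0.4)$fires)
  # fire time is the triggering (second) arrival
  expect_equal(summation_decision(arr, 1, 0.4)$fire_time, 10.39)
})

test_that("inhibition window is closed on both ends", {
  expect_false(inhibition_covers(10, 10.5))
  expect_true(inhibition_covers(10, 11))    # T + 1 exactly
  expect_true(inhibition_covers(10, 14))
  expect_true(inhibition_covers(10, 17))    # T + 7 exactly
  expect_false(inhibition_covers(10, 17.001))
})

test_that("refractoriness blocks strictly below r", {
  expect_true(refractory_blocks(100, 103.999, 4))
  expect_false(refractory_blocks(100, 104, 4))
  expect_error(refractory_blocks(100, 99), "precede")
})

test_that("resolve_firing consumes summed inputs and honors blackouts", {
  rf <- dlgsim:::resolve_firing
  # two weak pairs far apart: two fires
  exc <- list(time = c(10, 10.1, 30, 30.1), strength = rep(0.5, 4))
  r <- rf(exc, numeric(0), 0.4, 1, 4, c(1, 7))
  expect_equal(r$fires, c(10.1, 30.1))
  # refractoriness: second trigger 2 ms after the first is blocked
  exc2 <- list(time = c(10, 10.1, 12, 12.1), strength = rep(0.5, 4))
  r2 <- rf(exc2, numeric(0), 0.4, 1, 4, c(1, 7))
  expect_equal(r2$fires, 10.1)
  # inhibitory veto removes the covered excitation
  r3 <- rf(list(time = 15, strength = 1), 10, 0.4, 1, 4, c(1, 7))
  expect_length(r3$fires, 0)
  expect_equal(r3$blocked_inhibition, 15)
  # pending blackout matrix behaves like a fresh inhibitory arrival
  r4 <- rf(list(time = 15, strength = 1), numeric(0), 0.4, 1, 4, c(1, 7),
           blackouts = matrix(c(11, 17), 1))
  expect_length(r4$fires, 0)
})
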