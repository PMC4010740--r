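test_that("protocol constructors validate and shape their fields", {
  p <- periodic_protocol(5, 10, c("in1", "in2"))
  expect_equal(p$times, c(0, 100, 200, 300, 400))
  expect_equal(dim(p$probability), c(5, 2))
  expect_error(stimulation_protocol(c(0, 0), "in1"), "diff")
  expect_error(stimulation_protocol(0, "in1", probability = 1.5))
  # per-input probability vector is spread across columns
  p2 <- stimulation_protocol(c(0, 100), c("a", "b"), probability = c(1, 0.5))
  expect_equal(p2$probability[, "a"], c(1, 1))
  expect_equal(p2$probability[, "b"], c(0.5, 0.5))
})

test_that("moderation applies strictly inside the open interval", {
  p <- periodic_protocol(10, 10, c("in1", "in2"))
  p <- moderate_protocol(p, "in2", c(3, 7), 0.1)
  expect_equal(p$probability[, "in2"], c(1, 1, 1, 0.1, 0.1, 0.1, 1, 1, 1, 1))
  expect_equal(p$probability[, "in1"], rep(1, 10))
})

test_that("single-chain arrivals reproduce the latency line", {
  circ <- build_generalized_and(1, 30, delta = 0.006)
  res <- simulate_circuit(circ, periodic_protocol(50, 10, "in1"))
  # arrival at the output = l0 + q*delta + base link delay, q = stim - 1
  expect_equal(res$summary$arrival_in1, 30 + (0:49) * 0.006)
  # a single weak 0.5 stimulation never fires the output
  expect_false(any(res$summary$output_fired))
  expect_equal(unname(res$state$q["in1"]), 50)
  expect_equal(unname(res$state$q["out"]), 0)
})

test_that("runs are bit-reproducible by seed and decoupled by stream", {
  fx <- dlg_fixture("fig10_varying")
  a <- simulate_circuit(fx$circuit, fx$protocol, seed = 42)
  b <- simulate_circuit(fx$circuit, fx$protocol, seed = 42)
  c <- simulate_circuit(fx$circuit, fx$protocol, seed = 43)
  expect_identical(a$summary, b$summary)
  expect_false(identical(a$summary, c$summary))
  # derived child seeds differ between streams, agree per stream
  expect_identical(dlgsim:::derive_seed(1, "delivery"),
                   dlgsim:::derive_seed(1, "delivery"))
  expect_false(dlgsim:::derive_seed(1, "delivery") ==
                 dlgsim:::derive_seed(1, "connectivity"))
})

test_that("zero delivery probability freezes a chain's delay", {
  circ <- build_generalized_and(c(1, 1), c(30, 28), delta = 0.006)
  p <- periodic_protocol(100, 10, circ$inputs, probability = c(1, 0))
  res <- simulate_circuit(circ, p)
  expect_equal(unname(res$state$q["in2"]), 0)
  expect_equal(unname(res$state$q["in1"]), 100)
  expect_true(all(is.na(res$summary$arrival_in2)))
})

test_that("the OR gate emits two spikes outside the refractory period", {
  circ <- build_or()  # initial gap 8 ms > r = 4
  res <- simulate_circuit(circ, periodic_protocol(1, 10, circ$inputs),
                          record = "summary")
  expect_equal(res$summary$output_spikes[1], 2L)
  # inside the refractory period (gap < 4 ms): one spike
  circ2 <- build_or(gap = 2)
  res2 <- simulate_circuit(circ2, periodic_protocol(1, 10, circ2$inputs))
  expect_equal(res2$summary$output_spikes[1], 1L)
})

test_that("full records label blocked arrivals with their cause", {
  circ <- build_generalized_and(c(1, 2), c(30, 27), delta = 0.006)
  res <- simulate_circuit(circ, periodic_protocol(2, 10, circ$inputs),
                          record = "full")
  rec <- res$records
  out_rows <- rec[rec$neuron == "out", ]
  # at q = 0 the arrivals are 3 ms apart: blocked-subthreshold
  expect_true(all(out_rows$cause == "blocked-subthreshold"))
  expect_false(any(out_rows$evoked))
  # relays fire as strong 1:1
  expect_true(all(rec$evoked[rec$neuron == "in1"]))
  expect_true(all(rec$cause[rec$neuron == "in1"] == "strong"))
})

test_that("reset_latencies restores the initial delays", {
  circ <- build_generalized_and(c(1, 2), c(30, 27), delta = 0.006)
  res <- simulate_circuit(circ, periodic_protocol(50, 10, circ$inputs))
  st <- reset_latencies(res$state)
  expect_true(all(st$q == 0))
  expect_true(all(st$last_trigger == -Inf))
  res2 <- simulate_circuit(circ, periodic_protocol(50, 10, circ$inputs),
                           state = st)
  expect_identical(res2$summary, res$summary)
})

test_that("state-implied chain delays track the evoked-spike counts", {
  circ <- build_generalized_and(c(1, 2), c(30, 27), delta = 0.006)
  st <- reset_latencies(circuit = circ)
  expect_equal(unname(state_chain_delays(circ, st)), c(30, 27))
  res <- simulate_circuit(circ, periodic_protocol(100, 10, circ$inputs))
  expect_equal(unname(state_chain_delays(circ, res$state)),
               c(30 + 100 * 0.006, 27 + 100 * 2 * 0.006))
})

test_that("moderation probability 1 leaves a single AND region", {
  fx <- dlg_fixture("fig10_varying")
  vr <- varying_input_run(fx$circuit, n_stim = 700, moderated_input = "in2",
                          interval = c(250, 475), probability = 1, seed = 1)
  expect_equal(vr$n_and_regions, 1L)
})

test_that("the latency increment is recovered from a noise-free series", {
  ser <- data.frame(q = 0:299, latency = 1 + (0:299) * 0.0057)
  est <- estimate_delta(ser)
  expect_equal(as.numeric(est), 0.0057, tolerance = 1e-12)
  expect_true(attr(est, "physiological"))
  est2 <- estimate_delta(data.frame(q = 0:10, latency = 2 + (0:10) * 0.05))
  expect_false(attr(est2, "physiological"))
  expect_error(estimate_delta(data.frame(q = 1, latency = 1)), "two points")
})

test_that("a two-neuron chain reproduces the experimental delay increase", {
  # ~2 ms total increase over 270 stimulations at delta = 0.0074 ms
  ch <- chain_spec(1, tau0 = 10)
  inc <- chain_delay(ch, 0.0074, 270) - chain_delay(ch, 0.0074, 0)
  expect_equal(inc, 270 * 0.0074)
  expect_true(abs(inc - 2) < 0.1)
})
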