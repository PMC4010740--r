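test_that("the default AND gate traverses NULL -> AND -> NULL", {
  tl <- mode_timeline(build_and(), delta = 0.005, horizon = 600)
  expect_equal(tl$label, c("NULL", "AND", "NULL"))
  # gap 1.6 ms > window 0.5 ms at q = 0
  expect_equal(tl$label[1], "NULL")
})

test_that("the default OR gate alternates DOUBLE and OR", {
  tl <- mode_timeline(build_or(), delta = 0.005, horizon = 1000)
  expect_equal(tl$label, c("DOUBLE", "OR", "DOUBLE"))
  # ignoring multiplicity the gate is always an OR
  expect_true(all(tl$boolean_label == "OR"))
})

test_that("the NOT gate relays the outer stimulation outside its window", {
  tl <- mode_timeline(build_not(), delta = 0.005, horizon = 2200)
  expect_equal(tl$label, c("TRUE", "NOT", "TRUE"))
})

test_that("the XOR gate passes through an OR -> XOR -> OR sequence", {
  tl <- mode_timeline(build_xor(), delta = 0.006, horizon = 1000)
  expect_equal(tl$label, c("OR", "XOR", "OR"))
  expect_equal(tl$q_start[2], 250)
  expect_equal(tl$q_end[2], 750)
})

test_that("the five-mode gate validates its mode sequence on build", {
  circ <- build_multimode()
  tl <- mode_timeline(circ, delta = 0.006, horizon = 2000)
  expect_equal(tl$label, c("TRUE", "NOT(in1)", "NOR", "NOT(in2)", "TRUE"))
  # an ordering violating the slope constraints is rejected
  expect_error(build_multimode(lengths = c(2, 5, 3)), "five modes")
})

test_that("generalized AND builder checks its arguments", {
  expect_error(build_generalized_and(c(1, 2), c(30, 27, 25)))
  circ <- build_generalized_and(c(1, 2, 4, 6), c(30, 27.8, 25.2, 22.1))
  expect_equal(circ$inputs, paste0("in", 1:4))
  expect_equal(nrow(build_lines(circ, 0.006)), 4)
})

test_that("chains too short for their neuron count are rejected", {
  expect_error(build_generalized_and(40, 30), "tau0 too short")
})

test_that("classify_table recognizes every canonical mode", {
  for (lab in c("NULL", "TRUE", "AND", "OR", "NOR", "XOR",
                "NOT(in1)", "NOT(in2)", "IDENTITY(in1)", "IDENTITY(in2)")) {
    expect_identical(classify_table(canonical_table(lab, 2)), lab)
  }
  expect_identical(classify_table(canonical_table("NOT", 1)), "NOT")
  # spike multiplicity maps to DOUBLE
  tab <- canonical_table("OR", 2)
  tab$spikes <- c(0L, 2L, 2L, 2L)
  expect_identical(classify_table(tab), "DOUBLE")
  expect_identical(classify_table(tab, multiplicity = FALSE), "OR")
  # unrecognized tables are OTHER, never dropped
  odd <- canonical_table("OR", 2); odd$fired <- c(1L, 0L, 0L, 1L)
  expect_identical(classify_table(odd), "OTHER")
})

test_that("probing a truth table does not perturb the state", {
  circ <- build_generalized_and(c(1, 2, 5), c(30, 27, 25), delta = 0.006)
  st <- reset_latencies(circuit = circ)
  pr <- probe_truth_table(circ, state = st)
  expect_identical(pr$state, st)
  expect_identical(pr$label, "NULL")
})

test_that("the empirical truth table matches the analytic one inside a region", {
  circ <- build_generalized_and(c(1, 2, 5), c(30, 27, 25), delta = 0.006)
  # place the state inside the AND(in2,in3) region (q ~ 111)
  st <- reset_latencies(circuit = circ)
  st$q[] <- 111
  pr <- probe_truth_table(circ, state = st)
  tt <- dlgsim:::truth_table_at(circ, 0.006, 111)
  expect_equal(pr$table$fired, tt$fired)
  expect_identical(pr$label, "AND(in2,in3)")
})
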