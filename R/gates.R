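# Gate library: builders for the canonical dynamic-logic-gate architectures
# and a classifier mapping observed truth tables onto operating-mode labels.

# Helper: neurons and links for a relay chain of `n` neurons starting at an
# existing input neuron `first`, terminating with a link of the given
# strength/sign onto `target`.  The chain's initial input-to-target delay is
# `tau0`; per-neuron initial latencies are `l0` and intra-chain link delays
# `intra`, with the remainder placed on the terminal link.
chain_parts <- function(first, n, tau0, target, strength, sign, delta,
                        l0 = 1, intra = 1, window = 0.4, threshold = 1,
                        refractory = 4) {
  term <- tau0 - n * l0 - (n - 1) * intra
  if (term < 0) stop("tau0 too short for a chain of ", n, " neurons")
  ids <- if (n == 1L) first else c(first, paste0(first, "r", seq_len(n - 1L)))
  neurons <- lapply(ids, neuron_spec, l0 = l0, delta = delta, window = window,
                    threshold = threshold, refractory = refractory)
  links <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      links[[i]] <- link_spec(ids[i], ids[i + 1L], delay = intra)
    }
  }
  links[[length(links) + 1L]] <- link_spec(ids[n], target, delay = term,
                                           strength = strength, sign = sign)
  list(neurons = neurons, links = links, ids = ids)
}

out_neuron <- function(id, delta, window = 0.4, threshold = 1,
                       refractory = 4, l0 = 1) {
  neuron_spec(id, l0 = l0, delta = delta, window = window,
              threshold = threshold, refractory = refractory)
}

#' Build a two-input dynamic AND-gate
#'
#' A chain of `chains[1]` neurons from `in1` and of `chains[2]` neurons from
#' `in2`, both terminating with weak stimulations on the output neuron, so
#' that an output spike requires coincidence within the summation window.
#' The longer chain starts with the shorter delay and stretches faster,
#' producing NULL -> AND -> NULL transitions under repeated simultaneous
#' stimulation.
#'
#' @param chains Chain lengths (number of stretching neurons) for the two
#'   inputs; default `c(3, 1)`.
#' @param tau2 Initial delay of the second (short) chain (ms); default 80.
#' @param gap Initial delay difference `tau2 - tau1` (ms); default 1.6.
#' @param delta Latency increment (ms/spike); default 0.005.
#' @param window Summation window of the output neuron (ms); default 0.5.
#' @param strength Weak terminal strength; default 0.5.
#' @return A [circuit_spec()].
#' @export
build_and <- function(chains = c(3, 1), tau2 = 80, gap = 1.6, delta = 0.005,
                      window = 0.5, strength = 0.5) {
  c1 <- chain_parts("in1", chains[1], tau2 - gap, "out", strength,
                    "excitatory", delta, window = window)
  c2 <- chain_parts("in2", chains[2], tau2, "out", strength,
                    "excitatory", delta, window = window)
  circuit_spec(c(c1$neurons, c2$neurons,
                 list(out_neuron("out", delta, window = window))),
               c(c1$links, c2$links),
               inputs = c("in1", "in2"), output = "out")
}

#' Build a two-input dynamic OR-gate
#'
#' All stimulations are strong: each input alone evokes an output spike.
#' When the two arrival times differ by at least the refractory period the
#' output emits two spikes (two temporally independent relays); inside the
#' refractory period it emits one, acting as an OR.
#'
#' @param chains Chain lengths; default `c(4, 1)` (the four-neuron chain
#'   enlarges the dynamic range of the arrival time-lag).
#' @param tau2 Initial delay of the short chain (ms); default 80.
#' @param gap Initial delay difference `tau2 - tau1` (ms); default 8.
#' @param delta Latency increment (ms/spike); default 0.005.
#' @param refractory Output refractory period (ms); default 4.
#' @return A [circuit_spec()].
#' @export
build_or <- function(chains = c(4, 1), tau2 = 80, gap = 8, delta = 0.005,
                     refractory = 4) {
  c1 <- chain_parts("in1", chains[1], tau2 - gap, "out", 1, "excitatory",
                    delta)
  c2 <- chain_parts("in2", chains[2], tau2, "out", 1, "excitatory", delta)
  circuit_spec(c(c1$neurons, c2$neurons,
                 list(out_neuron("out", delta, refractory = refractory))),
               c(c1$links, c2$links),
               inputs = c("in1", "in2"), output = "out")
}

#' Build a dynamic NOT-gate
#'
#' The logical input `in1` drives an inhibition chain onto the output; an
#' outer excitatory stimulation (applied on every computation, as in
#' electronic circuits, since inhibition is only measurable against an
#' excitation) drives the output through a strong one-neuron chain.  While
#' the inhibitory arrival falls in the window `[1, 7]` ms before the
#' excitatory one, the gate computes NOT(in1); outside it relays the outer
#' stimulation regardless of `in1` (mode sequence 1 -> NOT -> 1).
#'
#' @param inh_chain Number of neurons in the inhibition chain; default 2.
#' @param tau_exc Initial delay of the outer excitatory chain (ms);
#'   default 80.
#' @param tau_inh Initial delay of the inhibition chain (ms); default 70.
#' @param delta Latency increment (ms/spike); default 0.005.
#' @return A [circuit_spec()] with input `in1` and outer neuron `in2`.
#' @export
build_not <- function(inh_chain = 2, tau_exc = 80, tau_inh = 70,
                      delta = 0.005) {
  ci <- chain_parts("in1", inh_chain, tau_inh, "out", 1, "inhibitory", delta)
  ce <- chain_parts("in2", 1, tau_exc, "out", 1, "excitatory", delta)
  circuit_spec(c(ci$neurons, ce$neurons, list(out_neuron("out", delta))),
               c(ci$links, ce$links),
               inputs = "in1", output = "out", outer = "in2")
}

#' Build a dynamic XOR-gate
#'
#' Two strong excitatory chains (2 and 5 neurons) with cross-inhibition:
#' each input also drives an inhibitory stimulation onto a relay neuron of
#' the other input's chain, with identical initial inhibitory delays.  The
#' first input's excitation is permanently vetoed under simultaneous
#' stimulation, while the second is vetoed only while its relative delay
#' lies in the inhibition window -- producing an OR -> XOR -> OR sequence.
#'
#' @param chains Excitatory chain lengths; default `c(2, 5)`.
#' @param taus Initial excitatory delays at the output (ms); default
#'   `c(36, 30)`.
#' @param tau_inh Identical initial delay of both inhibitory stimulations,
#'   referenced at their targets (ms); default 32 for the chain-2 side
#'   (measured at the inhibited relay the effective offsets are chosen so
#'   the long chain is vetoed over a finite stimulation interval and the
#'   short chain permanently).
#' @param inh_chain Number of neurons in the inhibitory path from `in1`;
#'   default 2.
#' @param delta Latency increment (ms/spike); default 0.006.
#' @return A [circuit_spec()].
#' @export
build_xor <- function(chains = c(2, 5), taus = c(36, 30), tau_inh = 32,
                      inh_chain = 2, delta = 0.006) {
  # green chain (in1) and purple chain (in2), both strong
  cg <- chain_parts("in1", chains[1], taus[1], "out", 1, "excitatory", delta,
                    intra = 17)
  cp <- chain_parts("in2", chains[2], taus[2], "out", 1, "excitatory", delta,
                    intra = 5)
  g_last <- cg$ids[length(cg$ids)]
  p_last <- cp$ids[length(cp$ids)]
  # cross-inhibition onto the terminal relay of the opposite chain.  The
  # path from in1 runs through `inh_chain` stretching neurons (in1 plus
  # relays) and arrives at the purple terminal relay tau_inh - 6 ms after
  # in1's stimulation once referenced at the output (the relay's own
  # latency and terminal link are shared with the excitatory path); the
  # delays below realize an at-relay arrival of tau_inh - 6 with the
  # default geometry.
  extra <- if (inh_chain > 1L) paste0("inh", seq_len(inh_chain - 1L)) else
    character()
  inh_neurons <- lapply(extra, neuron_spec, l0 = 1, delta = delta)
  inh_links <- list()
  at_relay <- tau_inh - 6  # arrival time at the inhibited relay
  if (length(extra)) {
    span <- at_relay - inh_chain  # total base delay over inh_chain links
    step <- span / inh_chain
    prev <- "in1"
    for (nm in extra) {
      inh_links[[length(inh_links) + 1L]] <- link_spec(prev, nm, delay = step)
      prev <- nm
    }
    inh_links[[length(inh_links) + 1L]] <-
      link_spec(prev, p_last, delay = step, sign = "inhibitory")
  } else {
    inh_links[[1L]] <- link_spec("in1", p_last, delay = at_relay - 1,
                                 sign = "inhibitory")
  }
  # inhibition of the short chain: a single stretching neuron (in2),
  # parallel to the green excitation at its relay, offset 4 ms inside the
  # window, so the first input is permanently vetoed when in2 is active
  inh_links[[length(inh_links) + 1L]] <-
    link_spec("in2", g_last, delay = 13, sign = "inhibitory")
  circuit_spec(c(cg$neurons, cp$neurons, inh_neurons,
                 list(out_neuron("out", delta))),
               c(cg$links, cp$links, inh_links),
               inputs = c("in1", "in2"), output = "out")
}

#' Build a generalized AND-gate with k weak input chains
#'
#' @param lengths Chain lengths (stretching neurons per input chain).
#' @param taus Initial input-to-output delays (ms), one per chain.
#' @param strengths Weak terminal strengths; default 0.5 each.
#' @param delta Latency increment (ms/spike); default 0.006.
#' @param window Output summation window (ms); default 0.4.
#' @param threshold Output firing threshold; default 1.
#' @return A [circuit_spec()] with inputs `in1 ... ink`.
#' @export
build_generalized_and <- function(lengths, taus, strengths = NULL,
                                  delta = 0.006, window = 0.4,
                                  threshold = 1) {
  k <- length(lengths)
  stopifnot(length(taus) == k)
  if (is.null(strengths)) strengths <- rep(0.5, k)
  neurons <- list(); links <- list()
  for (i in seq_len(k)) {
    ci <- chain_parts(paste0("in", i), lengths[i], taus[i], "out",
                      strengths[i], "excitatory", delta, window = window)
    neurons <- c(neurons, ci$neurons)
    links <- c(links, ci$links)
  }
  circuit_spec(c(neurons, list(out_neuron("out", delta, window = window,
                                          threshold = threshold))),
               links, inputs = paste0("in", seq_len(k)), output = "out")
}

#' Build the five-mode gate (two inhibition chains and an outer excitation)
#'
#' Two logical inputs drive inhibition chains with initial delays 30 and
#' 42 ms; an outer stimulation drives the output through an excitatory
#' chain with total delay 40 ms whose first relay sits at 10 ms.  Chain
#' lengths are chosen so the first inhibition chain stretches faster than
#' the outer chain, which stretches faster than the second inhibition
#' chain; the builder verifies that the gate traverses the five modes
#' TRUE -> NOT(in1) -> NOR -> NOT(in2) -> TRUE before returning.
#'
#' @param delays Named or positional delays (ms): first inhibition chain,
#'   second inhibition chain, outer excitatory chain (at the output), first
#'   relay of the outer chain.  Default `c(30, 42, 40, 10)`.
#' @param lengths Chain lengths for (first inhibition, second inhibition,
#'   outer excitation); default `c(5, 2, 3)`.
#' @param delta Latency increment (ms/spike); default 0.006.
#' @param horizon Validation horizon in stimulations; default 2000.
#' @param validate Check the five-mode sequence (default `TRUE`).
#' @return A [circuit_spec()] with inputs `in1`, `in2` and outer `ext`.
#' @export
build_multimode <- function(delays = c(30, 42, 40, 10),
                            lengths = c(5, 2, 3), delta = 0.006,
                            horizon = 2000, validate = TRUE) {
  ci1 <- chain_parts("in1", lengths[1], delays[1], "out", 1, "inhibitory",
                     delta)
  ci2 <- chain_parts("in2", lengths[2], delays[2], "out", 1, "inhibitory",
                     delta)
  # outer chain: first relay arrives at delays[4], output at delays[3]
  n_out <- lengths[3]
  stopifnot(n_out >= 2)
  ids <- c("ext", paste0("extr", seq_len(n_out - 1L)))
  neurons <- lapply(ids, neuron_spec, l0 = 1, delta = delta)
  links <- list(link_spec(ids[1], ids[2], delay = delays[4] - 1))
  if (n_out > 2L) {
    for (i in seq.int(2L, n_out - 1L)) {
      links[[i]] <- link_spec(ids[i], ids[i + 1L], delay = 1)
    }
  }
  rem <- delays[3] - delays[4] - (n_out - 1L) - (n_out - 2L)
  links[[n_out]] <- link_spec(ids[n_out], "out", delay = rem)
  circ <- circuit_spec(c(ci1$neurons, ci2$neurons, neurons,
                         list(out_neuron("out", delta))),
                       c(ci1$links, ci2$links, links),
                       inputs = c("in1", "in2"), output = "out",
                       outer = "ext")
  if (validate) {
    tl <- mode_timeline(circ, delta, horizon)
    want <- c("TRUE", "NOT(in1)", "NOR", "NOT(in2)", "TRUE")
    if (!identical(tl$label, want))
      stop("multimode gate does not traverse the five modes; got: ",
           paste(tl$label, collapse = " -> "))
  }
  circ
}

canonical_match <- function(inputs_mat, fired) {
  k <- ncol(inputs_mat)
  f <- as.integer(fired)
  sums <- rowSums(inputs_mat)
  if (all(f == 0L)) return("NULL")
  if (all(f == 1L)) return("TRUE")
  if (all(f == as.integer(sums == k))) return("AND")
  if (all(f == as.integer(sums >= 1L))) return("OR")
  if (all(f == as.integer(sums == 0L))) return(if (k == 1L) "NOT" else "NOR")
  if (k == 2L && all(f == as.integer(sums == 1L))) return("XOR")
  for (i in seq_len(k)) {
    nm <- colnames(inputs_mat)[i]
    if (all(f == as.integer(inputs_mat[, i] == 1L)))
      return(paste0("IDENTITY(", nm, ")"))
    if (all(f == as.integer(inputs_mat[, i] == 0L)))
      return(if (k == 1L) "NOT" else paste0("NOT(", nm, ")"))
  }
  # partial (pairwise) AND over a subset of inputs
  if (k > 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (all(f == as.integer(inputs_mat[, i] & inputs_mat[, j])))
          return(paste0("AND(", colnames(inputs_mat)[i], ",",
                        colnames(inputs_mat)[j], ")"))
      }
    }
  }
  "OTHER"
}

#' Classify a truth table into an operating-mode label
#'
#' Exact match against the canonical tables NULL, AND, OR, XOR, NOT,
#' NOR, TRUE and IDENTITY (and, for more than two inputs, pairwise
#' AND(i,j)).  When `multiplicity = TRUE` (default) a table in which any
#' input combination yields two or more output spikes is labeled DOUBLE
#' (two temporally independent relays rather than one logic operation).
#' Unrecognized patterns are labeled OTHER, never dropped.
#'
#' @param table Data frame with one column per input (0/1), plus `fired`
#'   (0/1 or logical) and optionally `spikes` (integer multiplicities).
#' @param multiplicity Consider spike multiplicities (default `TRUE`).
#' @return A character label.
#' @export
classify_table <- function(table, multiplicity = TRUE) {
  aux <- intersect(c("fired", "spikes"), names(table))
  ins <- setdiff(names(table), aux)
  if (multiplicity && "spikes" %in% names(table) && any(table$spikes >= 2L))
    return("DOUBLE")
  canonical_match(as.matrix(table[ins]), as.logical(table$fired))
}

#' Canonical truth table for a mode label
#'
#' Inverse of [classify_table()] for the named modes; useful for
#' constructing reference tables in tests and documentation.
#'
#' @param label One of `"NULL"`, `"AND"`, `"OR"`, `"XOR"`, `"NOR"`,
#'   `"TRUE"`, `"NOT(in1)"`, `"NOT(in2)"`, `"IDENTITY(in1)"`,
#'   `"IDENTITY(in2)"` (two-input), or `"NOT"`, `"TRUE"`, `"NULL"`,
#'   `"IDENTITY"` (one-input).
#' @param k Arity (1 or 2); default 2.
#' @return A data frame with input columns and `fired`.
#' @export
canonical_table <- function(label, k = 2) {
  combos <- expand.grid(rep(list(c(0L, 1L)), k))
  names(combos) <- paste0("in", seq_len(k))
  s <- rowSums(combos)
  f <- switch(label,
    "NULL" = rep(0L, nrow(combos)),
    "TRUE" = rep(1L, nrow(combos)),
    "AND" = as.integer(s == k),
    "OR" = as.integer(s >= 1),
    "NOR" = as.integer(s == 0),
    "XOR" = as.integer(s == 1),
    "NOT" = as.integer(combos$in1 == 0L),
    "IDENTITY" = combos$in1,
    "NOT(in1)" = as.integer(combos$in1 == 0L),
    "NOT(in2)" = as.integer(combos$in2 == 0L),
    "IDENTITY(in1)" = combos$in1,
    "IDENTITY(in2)" = combos$in2,
    stop("unknown label: ", label))
  cbind(combos, fired = f)
}

#' Probe a gate's empirical truth table with the event engine
#'
#' Runs one probe stimulation per input combination on a clone of the
#' given state, so the probes never perturb the simulation (set
#' `perturb = TRUE` to let each probe count as a real stimulation, as it
#' would in an experiment).
#'
#' @param circuit A [circuit_spec()].
#' @param state Simulation state (default fresh).
#' @param perturb Logical; default `FALSE` (non-perturbing probes).
#' @param seed Seed for any stochastic components.
#' @return List with `table` (data frame: input columns, `fired`,
#'   `spikes`), `label`, and the (possibly updated) `state`.
#' @export
probe_truth_table <- function(circuit, state = NULL, perturb = FALSE,
                              seed = 1L) {
  if (is.null(state)) state <- new_state(circuit)
  ins <- circuit$inputs
  k <- length(ins)
  combos <- expand.grid(rep(list(c(0L, 1L)), k))
  names(combos) <- ins
  fired <- integer(nrow(combos)); spikes <- integer(nrow(combos))
  cur <- state
  for (i in seq_len(nrow(combos))) {
    st <- if (perturb) cur else state
    active <- ins[combos[i, ] == 1L]
    # probe at a fresh time, far from any pending refractory bookkeeping
    proto <- stimulation_protocol(1e6 + i * 1000, ins,
                                  probability = as.numeric(combos[i, ]))
    # force delivery deterministically
    proto$probability[] <- as.numeric(combos[i, ])
    res <- simulate_circuit(circuit, proto, seed = seed, state = st,
                            record = "summary")
    fired[i] <- as.integer(res$summary$output_fired[1])
    spikes[i] <- res$summary$output_spikes[1]
    if (perturb) cur <- res$state
  }
  tab <- cbind(combos, fired = fired, spikes = spikes)
  list(table = tab, label = classify_table(tab),
       state = if (perturb) cur else state)
}
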