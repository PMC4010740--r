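# Core model: elastic response latency, circuit data model and the local
# firing rules (temporal summation, refractoriness, inhibition windows).
#
# A neuron's response latency grows linearly with the number of spikes it has
# emitted: l(q) = l0 + q * delta, with delta a few microseconds per spike for
# cortical neurons.  A chain of n such neurons accumulates the stretching of
# every relay, so its input-to-output delay grows as tau(q) = tau0 + n*q*delta.

#' Neuron specification
#'
#' Describes a single model neuron: its initial response latency, the
#' per-evoked-spike latency increment, and the local firing-rule parameters.
#'
#' @param id Character label, unique within a circuit.
#' @param l0 Initial response latency (ms), `>= 0`.
#' @param delta Latency increment per evoked spike (ms/spike), `>= 0`.
#'   Physiological values are a few microseconds (0.002--0.007 ms).
#' @param window Temporal-summation (coincidence) window `w` in ms: weak
#'   inputs arriving within less than `w` of each other sum toward the firing
#'   threshold.  Default 0.4 ms.
#' @param threshold Firing threshold for summed input strengths
#'   (dimensionless). Default 1.
#' @param refractory Refractory period in ms: two evoked spikes must be
#'   separated by at least this much. Default 4 ms.
#' @return An object of class `neuron_spec` (named list).
#' @export
neuron_spec <- function(id, l0 = 1, delta = 0.006, window = 0.4,
                        threshold = 1, refractory = 4) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (l0 < 0) stop("initial latency l0 must be >= 0")
  if (delta < 0) stop("latency increment delta must be >= 0")
  if (window <= 0) stop("summation window must be > 0")
  if (threshold <= 0) stop("firing threshold must be > 0")
  if (refractory < 0) stop("refractory period must be >= 0")
  structure(list(id = id, l0 = l0, delta = delta, window = window,
                 threshold = threshold, refractory = refractory),
            class = "neuron_spec")
}

#' Link specification
#'
#' A directed connection between two neurons. Intermediate links of a relay
#' chain are strong (`strength = 1`); terminal links onto a gate's output
#' neuron may be weak (e.g. 0.5) so that coincident arrivals are required.
#'
#' @param source,target Neuron labels.
#' @param delay Axonal/synaptic base delay in ms, `>= 0` (excludes the
#'   source's response latency, which is added at spike time).
#' @param strength Stimulation strength in (0, 1].
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @return An object of class `link_spec` (named list).
#' @export
link_spec <- function(source, target, delay, strength = 1,
                      sign = c("excitatory", "inhibitory")) {
  sign <- match.arg(sign)
  if (delay < 0) stop("link base delay must be >= 0")
  if (strength <= 0 || strength > 1) stop("link strength must lie in (0, 1]")
  structure(list(source = source, target = target, delay = delay,
                 strength = strength, sign = sign),
            class = "link_spec")
}

#' Chain specification for closed-form delay work
#'
#' @param n Number of neurons in the chain whose latencies stretch: the
#'   stimulated input neuron plus all relays, excluding the target neuron the
#'   chain projects to.
#' @param tau0 Initial total delay of the chain (ms), from input stimulation
#'   to the arrival of its stimulation at the target.
#' @param strength Terminal stimulation strength in (0, 1].
#' @param sign Terminal sign.
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(n, tau0, strength = 1,
                       sign = c("excitatory", "inhibitory")) {
  sign <- match.arg(sign)
  if (n < 1 || n != round(n)) stop("chain neuron count n must be a positive integer")
  if (tau0 <= 0) stop("initial chain delay tau0 must be > 0")
  structure(list(n = as.integer(n), tau0 = tau0, strength = strength,
                 sign = sign),
            class = "chain_spec")
}

#' Circuit specification
#'
#' A feedforward (acyclic) directed graph of neurons and links with
#' designated input neurons and a single output neuron.  Optional `outer`
#' neurons are stimulated on every computation regardless of the logical
#' inputs (used by NOT-style gates, where inhibition is only measurable
#' against a reference excitation).
#'
#' @param neurons List of [neuron_spec()] objects.
#' @param links List of [link_spec()] objects.
#' @param inputs Character vector of input neuron ids (the logical inputs).
#' @param output Output neuron id.
#' @param outer Character vector of always-stimulated neuron ids (default
#'   none).
#' @param inhibition_window Length-2 numeric `(a, b)`: an inhibitory arrival
#'   at time `T` vetoes excitatory arrivals at its target during
#'   `[T + a, T + b]`. Default `c(1, 7)` ms.
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(neurons, links, inputs, output, outer = character(),
                         inhibition_window = c(1, 7)) {
  nd <- do.call(rbind, lapply(neurons, function(n) {
    data.frame(id = n$id, l0 = n$l0, delta = n$delta, window = n$window,
               threshold = n$threshold, refractory = n$refractory,
               stringsAsFactors = FALSE)
  }))
  if (length(links)) {
    ld <- do.call(rbind, lapply(links, function(l) {
      data.frame(source = l$source, target = l$target, delay = l$delay,
                 strength = l$strength, sign = l$sign,
                 stringsAsFactors = FALSE)
    }))
  } else {
    ld <- data.frame(source = character(), target = character(),
                     delay = numeric(), strength = numeric(),
                     sign = character(), stringsAsFactors = FALSE)
  }
  circ <- structure(list(neurons = nd, links = ld,
                         inputs = as.character(inputs),
                         output = as.character(output),
                         outer = as.character(outer),
                         inhibition_window = as.numeric(inhibition_window)),
                    class = "circuit_spec")
  validate_circuit(circ)
  circ
}

#' Validate a circuit specification
#'
#' Checks label uniqueness, link endpoints, acyclicity, reachability of
#' non-input neurons, and the inhibition window ordering.  Called by
#' [circuit_spec()] and after deserialization.
#'
#' @param circuit A `circuit_spec`.
#' @return The circuit, invisibly; errors describe the offending field.
#' @export
validate_circuit <- function(circuit) {
  nd <- circuit$neurons; ld <- circuit$links
  if (anyDuplicated(nd$id)) stop("duplicate neuron ids: ",
                                 paste(nd$id[duplicated(nd$id)], collapse = ", "))
  for (col in c("source", "target")) {
    bad <- setdiff(ld[[col]], nd$id)
    if (length(bad)) stop("link ", col, " refers to unknown neuron id: ",
                          paste(bad, collapse = ", "))
  }
  miss <- setdiff(c(circuit$inputs, circuit$output, circuit$outer), nd$id)
  if (length(miss)) stop("input/output label not in neuron set: ",
                         paste(miss, collapse = ", "))
  if (length(circuit$output) != 1L) stop("exactly one output neuron required")
  g <- circuit_graph(circuit)
  if (nrow(ld) && !igraph::is_dag(g))
    stop("circuit graph must be acyclic (feedforward)")
  drivers <- c(circuit$inputs, circuit$outer)
  if (length(drivers)) {
    reach <- unique(unlist(lapply(drivers, function(i) {
      names(igraph::subcomponent(g, i, mode = "out"))
    })))
    unreach <- setdiff(nd$id, reach)
    if (length(unreach)) stop("neurons unreachable from any input: ",
                              paste(unreach, collapse = ", "))
  }
  iw <- circuit$inhibition_window
  if (length(iw) != 2L || iw[1] >= iw[2])
    stop("inhibition_window must be (a, b) with a < b")
  invisible(circuit)
}

circuit_graph <- function(circuit) {
  igraph::graph_from_data_frame(circuit$links[, c("source", "target")],
                                vertices = circuit$neurons$id)
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("<circuit_spec> ", nrow(x$neurons), " neurons, ", nrow(x$links),
      " links\n", sep = "")
  cat("  inputs: ", paste(x$inputs, collapse = ", "),
      if (length(x$outer)) paste0("  outer: ", paste(x$outer, collapse = ", ")),
      "  output: ", x$output, "\n", sep = "")
  cat("  inhibition window: [", x$inhibition_window[1], ", ",
      x$inhibition_window[2], "] ms\n", sep = "")
  invisible(x)
}

#' Response latency after q evoked spikes
#'
#' `l(q) = l0 + q * delta`: the latency of a neuron grows linearly with the
#' number of spikes it has emitted.
#'
#' @param spec A [neuron_spec()] (or any list with `l0` and `delta`).
#' @param q Non-negative integer(s): evoked-spike count.
#' @return Latency in ms (vectorized over `q`).
#' @export
latency_of <- function(spec, q) {
  if (any(q < 0)) stop("evoked-spike count q must be >= 0")
  spec$l0 + q * spec$delta
}

#' Chain delay after q evoked spikes per neuron
#'
#' `tau(q) = tau0 + n * q * delta`: under 1:1 response every neuron in a
#' chain of `n` stretching neurons has fired `q` times, so the chain delay
#' grows `n` times faster than a single latency.
#'
#' @param chain A [chain_spec()].
#' @param delta Latency increment per evoked spike (ms/spike).
#' @param q Non-negative stimulation count(s).
#' @return Chain delay in ms (vectorized over `q`).
#' @export
chain_delay <- function(chain, delta, q) {
  if (chain$n < 1) stop("chain must contain at least one neuron")
  if (any(q < 0)) stop("stimulation count q must be >= 0")
  chain$tau0 + chain$n * q * delta
}

#' Temporal/spatial summation decision
#'
#' A neuron fires iff at some arrival time `t` the summed strengths of
#' arrivals inside the half-open window `(t - w, t]` reach the threshold.
#' The comparison on the lag is strict: arrivals exactly `w` apart do not
#' sum.
#'
#' @param arrivals Data frame or list with components `time` (ms) and
#'   `strength`; need not be sorted.
#' @param threshold Firing threshold.
#' @param window Summation window `w` (ms).
#' @return List with `fires` (logical) and `fire_time` (time of the
#'   triggering arrival, or `NA` if no fire).
#' @export
summation_decision <- function(arrivals, threshold = 1, window = 0.4) {
  times <- arrivals$time; strengths <- arrivals$strength
  if (length(times) == 0L) return(list(fires = FALSE, fire_time = NA_real_))
  o <- order(times)
  times <- times[o]; strengths <- strengths[o]
  for (i in seq_along(times)) {
    in_win <- times > times[i] - window & times <= times[i]
    if (sum(strengths[in_win]) >= threshold)
      return(list(fires = TRUE, fire_time = times[i]))
  }
  list(fires = FALSE, fire_time = NA_real_)
}

#' Does an inhibitory arrival veto an excitatory one?
#'
#' An inhibitory stimulation at time `T` silences its target during the
#' closed interval `[T + a, T + b]` (default `[T + 1, T + 7]` ms).
#'
#' @param inhibition_time Arrival time `T` of the inhibitory stimulation (ms).
#' @param excitation_time Arrival time of the excitatory stimulation (ms).
#' @param window Length-2 numeric `(a, b)`, `a < b`.
#' @return Logical (vectorized over `excitation_time`).
#' @export
inhibition_covers <- function(inhibition_time, excitation_time,
                              window = c(1, 7)) {
  stopifnot(window[1] < window[2])
  excitation_time >= inhibition_time + window[1] &
    excitation_time <= inhibition_time + window[2]
}

#' Does the refractory period block a candidate spike?
#'
#' Blocks strictly: a gap exactly equal to `r` permits the second spike.
#'
#' @param last_spike Time of the previous evoked spike (ms).
#' @param candidate Candidate spike time (ms), `>= last_spike`.
#' @param refractory Refractory period `r` (ms).
#' @return Logical.
#' @export
refractory_blocks <- function(last_spike, candidate, refractory = 4) {
  if (any(candidate < last_spike)) stop("candidate must not precede last_spike")
  (candidate - last_spike) < refractory
}

# Shared local firing rule: given excitatory/inhibitory arrivals at one
# neuron, return the evoked trigger times.  Used verbatim by the event
# engine and (on line-valued arrivals) by the analytic truth-table
# evaluation, so the two engines cannot drift apart on boundary
# conventions.  Refractoriness compares stimulation trigger times; after a
# fire the running summation is reset (the summed inputs are consumed).
#
# exc: data.frame(time, strength); inh_times: numeric; window/threshold/
# refractory: neuron parameters; iw: circuit inhibition window (a, b);
# last_trigger: trigger time of the most recent evoked spike before these
# arrivals (-Inf if none); blackouts: optional 2-column matrix of earlier
# inhibition intervals still pending.
resolve_firing <- function(exc, inh_times, window, threshold, refractory,
                           iw, last_trigger = -Inf, blackouts = NULL) {
  lo <- c(blackouts[, 1], inh_times + iw[1])
  hi <- c(blackouts[, 2], inh_times + iw[2])
  times <- exc$time; strengths <- exc$strength
  blocked_inh <- logical(length(times))
  if (length(lo) && length(times)) {
    for (i in seq_along(times)) {
      blocked_inh[i] <- any(times[i] >= lo & times[i] <= hi)
    }
  }
  keep <- !blocked_inh
  t_ok <- times[keep]; s_ok <- strengths[keep]
  o <- order(t_ok); t_ok <- t_ok[o]; s_ok <- s_ok[o]
  fires <- numeric(0)
  win_start <- 1L
  acc <- 0
  i <- 1L
  while (i <= length(t_ok)) {
    acc <- acc + s_ok[i]
    while (t_ok[win_start] <= t_ok[i] - window) {
      acc <- acc - s_ok[win_start]
      win_start <- win_start + 1L
    }
    if (acc >= threshold && (t_ok[i] - last_trigger) >= refractory) {
      fires <- c(fires, t_ok[i])
      last_trigger <- t_ok[i]
      acc <- 0
      win_start <- i + 1L
    }
    i <- i + 1L
  }
  list(fires = fires, blocked_inhibition = times[blocked_inh],
       last_trigger = last_trigger)
}
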