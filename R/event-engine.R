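# Event-driven engine: spike-by-spike simulation of a circuit_spec under a
# stimulation protocol.  Neurons are processed in topological order within
# each stimulation (the graph is feedforward and link delays are
# non-negative, so a neuron's arrivals are fully determined by its
# upstream); latencies stretch by delta per evoked spike only.

#' Stimulation protocol
#'
#' @param times Strictly increasing stimulation times (ms), one per
#'   stimulation of the simultaneity group.
#' @param inputs Input labels stimulated on each stimulation (simultaneity
#'   group); outer neurons of a circuit are always stimulated in addition.
#' @param probability Delivery probability: scalar, per-input vector, or a
#'   `length(times) x length(inputs)` matrix (Bernoulli per input
#'   stimulation; a skipped input generates no downstream events).
#' @return Object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(times, inputs, probability = 1) {
  stopifnot(all(diff(times) > 0), all(probability >= 0), all(probability <= 1))
  k <- length(inputs)
  p <- matrix(probability, nrow = length(times), ncol = k,
              byrow = is.vector(probability) && length(probability) == k)
  colnames(p) <- inputs
  structure(list(times = times, inputs = inputs, probability = p),
            class = "stimulation_protocol")
}

#' Periodic stimulation protocol
#'
#' @param n Number of stimulations `Q`.
#' @param rate_hz Stimulation rate (default 10 Hz, i.e. 100 ms spacing).
#' @param inputs Input labels.
#' @param probability As in [stimulation_protocol()].
#' @param start Time of the first stimulation (ms).
#' @return A [stimulation_protocol()].
#' @export
periodic_protocol <- function(n, rate_hz = 10, inputs, probability = 1,
                              start = 0) {
  stimulation_protocol(start + (seq_len(n) - 1) * 1000 / rate_hz,
                       inputs, probability)
}

#' Moderate the delivery probability of one input over a stimulation period
#'
#' Stimulation indices strictly inside `(interval[1], interval[2])` have
#' their delivery probability replaced.
#'
#' @param protocol A [stimulation_protocol()].
#' @param input Input label to moderate.
#' @param interval Open interval of stimulation indices.
#' @param probability Replacement delivery probability.
#' @return The modified protocol.
#' @export
moderate_protocol <- function(protocol, input, interval, probability) {
  s <- seq_along(protocol$times)
  sel <- s > interval[1] & s < interval[2]
  protocol$probability[sel, input] <- probability
  protocol
}

# 32-bit FNV-1a step helpers in double arithmetic (kept exact by splitting
# the multiply into 16-bit halves; R doubles hold < 2^41 products exactly)
fnv1a32 <- function(bytes, h = 2166136261) {
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

derive_seed <- function(seed, stream) {
  # FNV-1a over the stream name, folded with the root seed; keeps child
  # streams decoupled so toggling one stochastic feature does not shift
  # the draws of another.
  h <- fnv1a32(utf8ToInt(stream))
  as.integer((h + as.numeric(seed)) %% 2^31)
}

new_state <- function(circuit) {
  ids <- circuit$neurons$id
  list(q = setNames(numeric(length(ids)), ids),
       last_trigger = setNames(rep(-Inf, length(ids)), ids),
       blackouts = setNames(vector("list", length(ids)), ids))
}

#' Reset all latencies of a simulation state
#'
#' Latency stretching is fully reversible; this models recovery as an
#' explicit reset: all evoked-spike counters return to zero, pending
#' refractory and inhibition bookkeeping is cleared.
#'
#' @param state A state as returned by [simulate_circuit()] (component
#'   `state`), or `NULL`.
#' @param circuit The circuit the state belongs to (used when `state` is
#'   `NULL`).
#' @return A fresh state with all `q = 0`.
#' @export
reset_latencies <- function(state = NULL, circuit = NULL) {
  if (is.null(state)) return(new_state(circuit))
  state$q[] <- 0
  state$last_trigger[] <- -Inf
  state$blackouts <- setNames(vector("list", length(state$q)), names(state$q))
  state
}

#' Chain delays implied by the current simulation state
#'
#' For each input, the input-to-output delay that its (unique-path) chain
#' would realize given the current per-neuron evoked-spike counts:
#' the sum of `l0 + q*delta` over the path neurons plus the base link
#' delays.  Defined for every stimulation, delivered or not.
#'
#' @param circuit A [circuit_spec()].
#' @param state A simulation state.
#' @param delta Optional override of every neuron's latency increment.
#' @return Named numeric vector, one delay per input (first path each).
#' @export
state_chain_delays <- function(circuit, state, delta = NULL) {
  nd <- circuit$neurons
  vapply(circuit$inputs, function(src) {
    p <- paths_to_node(circuit, src, circuit$output)
    if (!length(p)) return(NA_real_)
    pp <- p[[1]]
    idx <- match(pp, nd$id)
    dd <- if (is.null(delta)) nd$delta[idx] else rep(delta, length(idx))
    base <- 0
    ld <- circuit$links
    nodes <- c(pp, circuit$output)
    for (i in seq_len(length(nodes) - 1L)) {
      j <- which(ld$source == nodes[i] & ld$target == nodes[i + 1L])[1]
      base <- base + ld$delay[j]
    }
    sum(nd$l0[idx] + state$q[pp] * dd) + base
  }, numeric(1))
}

graded_veto_prob <- function(gap) {
  # experimental inhibition profile: near-absolute up to 5 ms before the
  # excitation, deteriorating linearly and vanishing around 10 ms
  ifelse(gap >= 1 & gap <= 5, 1,
         ifelse(gap > 5 & gap <= 10, (10 - gap) / 5, 0))
}

#' Simulate a circuit under a stimulation protocol
#'
#' Processes each stimulation through the feedforward graph: external
#' stimulations (strength 1) arrive at the delivered inputs and all outer
#' neurons; every neuron applies inhibition blackouts, temporal summation
#' and refractoriness to its arrivals; each evoked spike increments that
#' neuron's spike count `q`, stretching all its future latencies by its
#' `delta`.  Inhibitory arrivals are applied before excitatory ones at
#' identical times.
#'
#' @param circuit A [circuit_spec()].
#' @param protocol A [stimulation_protocol()] over (a subset of) the
#'   circuit's inputs.
#' @param seed Integer root seed; child streams are derived for delivery
#'   and graded inhibition, so runs are bit-reproducible.
#' @param state Optional state to resume from (default fresh).
#' @param freeze_output If `TRUE` the output neuron's own latency does not
#'   stretch (recovers the pure delay-line picture; by default it does,
#'   which reproduces the experimentally observed asymmetry between region
#'   entry and exit in the output spike times).
#' @param record `"summary"` (default), `"full"` (adds per-arrival spike
#'   records), or `"none"`.
#' @param graded_inhibition If `TRUE`, inhibitory vetoes use the graded
#'   experimental profile (absolute within 5 ms, vanishing at 10 ms)
#'   instead of the sharp window.
#' @return List with `summary` (per-stimulation data frame: delivery flags,
#'   state-implied chain delay and output-arrival time per input, output
#'   spike count), `records` (per-arrival data frame when `record="full"`),
#'   and the final `state`.
#' @export
simulate_circuit <- function(circuit, protocol, seed = 1L, state = NULL,
                             freeze_output = FALSE,
                             record = c("summary", "full", "none"),
                             graded_inhibition = FALSE) {
  record <- match.arg(record)
  if (is.null(state)) state <- new_state(circuit)
  nd <- circuit$neurons
  ld <- circuit$links
  iw <- circuit$inhibition_window
  ids <- nd$id
  topo <- names(igraph::topo_sort(circuit_graph(circuit)))
  out_links <- split(seq_len(nrow(ld)), ld$source)
  nq <- state$q; ltr <- state$last_trigger; blk <- state$blackouts
  l0 <- setNames(nd$l0, ids); dl <- setNames(nd$delta, ids)
  wn <- setNames(nd$window, ids); th <- setNames(nd$threshold, ids)
  rf <- setNames(nd$refractory, ids)
  Q <- length(protocol$times)
  k <- length(protocol$inputs)
  set.seed(derive_seed(seed, "delivery"))
  delivered <- matrix(runif(Q * k), Q, k) < protocol$probability
  colnames(delivered) <- protocol$inputs
  set.seed(derive_seed(seed, "inhibition"))

  arr_mat <- matrix(NA_real_, Q, length(circuit$inputs),
                    dimnames = list(NULL, circuit$inputs))
  spk_vec <- integer(Q)
  rec <- if (record == "full") new.env() else NULL
  if (!is.null(rec)) {
    rec$stim <- integer(0); rec$neuron <- character(0)
    rec$arrival <- numeric(0); rec$strength <- numeric(0)
    rec$evoked <- logical(0); rec$evoked_time <- numeric(0)
    rec$cause <- character(0)
  }
  push_rec <- function(s, nid, t, str, ev, evt, cause) {
    rec$stim <- c(rec$stim, s); rec$neuron <- c(rec$neuron, nid)
    rec$arrival <- c(rec$arrival, t); rec$strength <- c(rec$strength, str)
    rec$evoked <- c(rec$evoked, ev); rec$evoked_time <- c(rec$evoked_time, evt)
    rec$cause <- c(rec$cause, cause)
  }

  for (s in seq_len(Q)) {
    T0 <- protocol$times[s]
    arr_t <- setNames(vector("list", length(ids)), ids)
    arr_s <- arr_t; arr_sign <- arr_t; arr_o <- arr_t
    ext <- c(protocol$inputs[delivered[s, ]], circuit$outer)
    for (nid in ext) {
      arr_t[[nid]] <- T0; arr_s[[nid]] <- 1
      arr_sign[[nid]] <- "excitatory"; arr_o[[nid]] <- nid
    }
    if (!is.null(rec)) {
      for (nid in protocol$inputs[!delivered[s, ]])
        push_rec(s, nid, NA_real_, NA_real_, FALSE, NA_real_, "skipped-input")
    }
    out_arr_t <- numeric(0); out_arr_o <- character(0)
    out_spikes <- 0L
    for (nid in topo) {
      ts <- arr_t[[nid]]
      if (is.null(ts)) next
      ss <- arr_s[[nid]]; sg <- arr_sign[[nid]]; oo <- arr_o[[nid]]
      if (nid == circuit$output) {
        exm <- sg == "excitatory"
        out_arr_t <- ts[exm]; out_arr_o <- oo[exm]
      }
      inh_t <- ts[sg == "inhibitory"]
      excm <- sg == "excitatory"
      exc <- list(time = ts[excm], strength = ss[excm])
      exc_o <- oo[excm]
      b <- blk[[nid]]
      if (!is.null(b) && nrow(b)) {
        b <- b[b[, 2] >= T0, , drop = FALSE]
      }
      if (graded_inhibition && length(inh_t) && length(exc$time)) {
        # probabilistic veto by gap; vetoed arrivals removed up front
        veto <- vapply(seq_along(exc$time), function(i) {
          p <- graded_veto_prob(exc$time[i] - inh_t)
          any(runif(length(p)) < p)
        }, logical(1))
        if (!is.null(rec) && any(veto)) {
          for (i in which(veto))
            push_rec(s, nid, exc$time[i], exc$strength[i], FALSE, NA_real_,
                     "blocked-inhibition")
        }
        exc$time <- exc$time[!veto]; exc$strength <- exc$strength[!veto]
        exc_o <- exc_o[!veto]
        inh_t <- numeric(0)
      }
      res <- resolve_firing(exc, inh_t, wn[nid], th[nid], rf[nid], iw,
                            last_trigger = ltr[nid], blackouts = b)
      if (length(inh_t)) {
        b <- rbind(b, cbind(inh_t + iw[1], inh_t + iw[2]))
      }
      blk[[nid]] <- b
      ltr[nid] <- res$last_trigger
      for (t in res$fires) {
        frozen <- freeze_output && nid == circuit$output
        spike_time <- t + l0[nid] + nq[nid] * dl[nid]
        if (!frozen) nq[nid] <- nq[nid] + 1
        if (nid == circuit$output) out_spikes <- out_spikes + 1L
        orig <- exc_o[match(t, exc$time)]
        for (j in out_links[[nid]]) {
          tgt <- ld$target[j]
          arr_t[[tgt]] <- c(arr_t[[tgt]], spike_time + ld$delay[j])
          arr_s[[tgt]] <- c(arr_s[[tgt]], ld$strength[j])
          arr_sign[[tgt]] <- c(arr_sign[[tgt]], ld$sign[j])
          arr_o[[tgt]] <- c(arr_o[[tgt]], orig)
        }
        if (!is.null(rec)) {
          str <- exc$strength[match(t, exc$time)]
          push_rec(s, nid, t, str, TRUE, spike_time,
                   if (!is.na(str) && str >= th[nid]) "strong" else "summation")
        }
      }
      if (!is.null(rec)) {
        for (t in res$blocked_inhibition)
          push_rec(s, nid, t, exc$strength[match(t, exc$time)], FALSE,
                   NA_real_, "blocked-inhibition")
        others <- setdiff(exc$time, c(res$fires, res$blocked_inhibition))
        for (t in others) {
          i <- match(t, exc$time)
          in_win <- exc$time > t - wn[nid] & exc$time <= t
          cause <- if (sum(exc$strength[in_win]) >= th[nid])
            "blocked-refractory" else "blocked-subthreshold"
          push_rec(s, nid, t, exc$strength[i], FALSE, NA_real_, cause)
        }
        for (t in inh_t)
          push_rec(s, nid, t, NA_real_, FALSE, NA_real_, "inhibitory-arrival")
      }
    }
    if (record != "none") {
      for (inp in circuit$inputs) {
        a <- out_arr_t[out_arr_o == inp]
        if (length(a)) arr_mat[s, inp] <- min(a) - T0
      }
      spk_vec[s] <- out_spikes
    }
  }
  state$q <- nq; state$last_trigger <- ltr; state$blackouts <- blk
  out <- list(state = state)
  if (record != "none") {
    sm <- data.frame(stim = seq_len(Q), time = protocol$times)
    for (inp in circuit$inputs) {
      sm[[paste0("arrival_", inp)]] <- arr_mat[, inp]
      sm[[paste0("delivered_", inp)]] <-
        if (inp %in% colnames(delivered)) delivered[, inp] else TRUE
    }
    sm$output_spikes <- spk_vec
    sm$output_fired <- spk_vec > 0L
    out$summary <- sm
  }
  if (!is.null(rec)) {
    out$records <- data.frame(stim = rec$stim, neuron = rec$neuron,
                              arrival = rec$arrival, strength = rec$strength,
                              evoked = rec$evoked,
                              evoked_time = rec$evoked_time,
                              cause = rec$cause, stringsAsFactors = FALSE)
  }
  out
}

#' Run an AND-gate with a moderated input and report its empirical timeline
#'
#' Reproduces the varying-input phenomenon: temporarily reducing the
#' delivery probability of one input slows that chain's latency stretching,
#' so the two delay lines cross, and re-cross once the full rate resumes --
#' yielding a re-entry to additional AND regions.
#'
#' @param circuit A two-input AND-style circuit.
#' @param n_stim Number of stimulations.
#' @param moderated_input Label of the input whose delivery is moderated.
#' @param interval Open interval of stimulation indices for the moderation.
#' @param probability Delivery probability inside the interval.
#' @param rate_hz Stimulation rate.
#' @param seed Root seed.
#' @param min_length Minimum number of consecutive stimulations for a run
#'   of the AND indicator to count as a region (default 2).  Bernoulli
#'   delivery makes the moderated chain's delay a random walk, so the
#'   indicator can flicker for a single stimulation where the delay
#'   difference grazes the summation-window boundary; such flickers are
#'   not operating regions.  The unfiltered runs are returned as
#'   `regions_raw`.
#' @return List with `summary` (adds state-implied chain delays `delay_<in>`
#'   and the AND indicator), `n_and_regions`, `regions` (run bounds of at
#'   least `min_length` stimulations), and `regions_raw` (all runs).
#' @export
varying_input_run <- function(circuit, n_stim = 700, moderated_input,
                              interval = c(250, 475), probability = 0.1,
                              rate_hz = 10, seed = 1L, min_length = 2L) {
  stopifnot(length(circuit$inputs) == 2L)
  proto <- periodic_protocol(n_stim, rate_hz, circuit$inputs)
  proto <- moderate_protocol(proto, moderated_input, interval, probability)
  state <- new_state(circuit)
  wn <- circuit$neurons$window[circuit$neurons$id == circuit$output]
  delays <- matrix(NA_real_, n_stim, 2,
                   dimnames = list(NULL, circuit$inputs))
  # step one stimulation at a time so the state-implied delays are recorded
  # *before* each stimulation's own spikes
  res_sum <- vector("list", n_stim)
  full <- simulate_circuit(circuit, proto, seed = seed, state = state,
                           record = "summary")
  # reconstruct pre-stimulation delays: q of each chain neuron before stim s
  # equals its number of evoked spikes in stims < s; recompute by replay of
  # per-input delivery since chain relays fire 1:1 when delivered
  q_chain <- setNames(numeric(2), circuit$inputs)
  set.seed(derive_seed(seed, "delivery"))
  delivered <- matrix(runif(n_stim * 2), n_stim, 2) < proto$probability
  for (s in seq_len(n_stim)) {
    for (i in 1:2) {
      inp <- circuit$inputs[i]
      fake <- state; fake$q[] <- 0
      p <- paths_to_node(circuit, inp, circuit$output)[[1]]
      fake$q[p] <- q_chain[inp]
      delays[s, i] <- state_chain_delays(circuit, fake)[inp]
    }
    q_chain <- q_chain + delivered[s, ]
  }
  sm <- full$summary
  sm$delay_in1 <- delays[, 1]; sm$delay_in2 <- delays[, 2]
  sm$and_state <- abs(delays[, 1] - delays[, 2]) < wn
  r <- rle(sm$and_state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  regions_raw <- data.frame(start = starts[r$values], end = ends[r$values])
  regions <- regions_raw[regions_raw$end - regions_raw$start + 1L >=
                           min_length, , drop = FALSE]
  rownames(regions) <- NULL
  list(summary = sm, n_and_regions = nrow(regions), regions = regions,
       regions_raw = regions_raw, state = full$state)
}

#' Estimate the latency increment from a latency series
#'
#' Least-squares slope of latency against evoked-spike count; on noise-free
#' simulated data this recovers the configured increment exactly.
#'
#' @param series Data frame (or list) with components `q` and `latency`.
#' @return The slope estimate (ms/spike), with attributes `stderr` and
#'   `physiological` (`TRUE` when the estimate lies in the 0.002--0.007
#'   ms/spike range observed for cortical neurons).
#' @export
estimate_delta <- function(series) {
  q <- series$q; lat <- series$latency
  if (length(q) < 2L) stop("need at least two points")
  if (length(unique(q)) < 2L) stop("all q equal; slope undefined")
  fit <- lm(lat ~ q)
  est <- unname(coef(fit)[2])
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, 2]),
                 error = function(e) NA_real_)
  structure(est, stderr = se,
            physiological = est >= 0.002 && est <= 0.007)
}
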