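# Hodgkin-Huxley population engine: each "neuron" of a gate is replaced by a
# population of conductance-based HH neurons with diluted weak projections,
# which makes the gate's operation robust to single-neuron response
# failures while preserving its time-dependent logic.

#' Population specification
#'
#' @param size Neurons per population (default 40).
#' @param connection_probability Probability that a given neuron of a source
#'   population projects to a given neuron of the target population
#'   (default 0.1, i.e. on average 8 inputs per output neuron when two
#'   40-neuron populations project in).
#' @param delay_jitter Standard deviation of the Gaussian inter-population
#'   delay distribution (ms, default 0.15; delays truncated at 0).
#' @param g_weak Maximal synaptic conductance of a weak (sub-threshold)
#'   projection (mS/cm^2).  The default is a nominal 0.0662 mS/cm^2 scaled
#'   down by 4.5: under the classic squid-axon parameters used here, a
#'   single unscaled input is already supra-threshold, while the scaled
#'   value restores the intended semantics (drive from one input
#'   population alone stays sub-threshold; near-coincident drive from both
#'   populations fires the target).  See the calibration section of the
#'   vignette.
#' @param g_strong Maximal synaptic conductance of a strong projection
#'   (mS/cm^2, default 1.6).
#' @param E_syn Synaptic reversal potential (mV, default 0).
#' @param delta Latency increment per evoked spike applied to each neuron's
#'   outgoing delay (ms/spike, default 0.04).
#' @param tau_syn Alpha-function synaptic time constant (ms, default 0.5;
#'   calibrated so the output population discriminates sub-millisecond
#'   input time-lags, see the vignette).
#' @param dt Integration time step (ms, default 0.01; fixed-step RK4).
#' @param hh Named list of HH membrane parameters (classic squid-axon
#'   values by default).
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(size = 40, connection_probability = 0.1,
                            delay_jitter = 0.15, g_weak = 0.0662 / 4.5,
                            g_strong = 1.6, E_syn = 0, delta = 0.04,
                            tau_syn = 0.5, dt = 0.01,
                            hh = list(C = 1, gNa = 120, gK = 36, gL = 0.3,
                                      ENa = 50, EK = -77, EL = -54.4)) {
  stopifnot(size >= 1, connection_probability >= 0,
            connection_probability <= 1, delay_jitter >= 0,
            g_weak > 0, g_strong > 0, dt > 0)
  structure(list(size = as.integer(size),
                 connection_probability = connection_probability,
                 delay_jitter = delay_jitter, g_weak = g_weak,
                 g_strong = g_strong, E_syn = E_syn, delta = delta,
                 tau_syn = tau_syn, dt = dt, hh = hh),
            class = "population_spec")
}

hh_param_vector <- function(spec) {
  c(C = spec$hh$C, gNa = spec$hh$gNa, gK = spec$hh$gK, gL = spec$hh$gL,
    ENa = spec$hh$ENa, EK = spec$hh$EK, EL = spec$hh$EL,
    Esyn = spec$E_syn, tau_syn = spec$tau_syn)
}

#' Simulate one population for one stimulation window
#'
#' @param events Data frame with columns `time` (ms), `g` (maximal
#'   conductance of the alpha-function input, mS/cm^2) and `neuron`
#'   (1-based index of the receiving neuron).
#' @param n Number of neurons.
#' @param spec A [population_spec()].
#' @param t_end Window length (ms); default covers the last event plus
#'   15 ms.
#' @param dt Optional override of the integration step.
#' @return List with `first_spike` (NA when the neuron does not fire) and
#'   `n_spikes`.
#' @export
simulate_population <- function(events, n, spec, t_end = NULL, dt = NULL) {
  if (is.null(t_end)) t_end <- max(events$time, 0) + 15
  if (is.null(dt)) dt <- spec$dt
  if (!nrow(events)) {
    return(list(first_spike = rep(NA_real_, n), n_spikes = integer(n)))
  }
  .hh_pop_sim(events$time, events$g, as.integer(events$neuron) - 1L,
              as.integer(n), t_end, dt, hh_param_vector(spec))
}

#' Wire one population onto another
#'
#' Each target neuron connects to each source neuron independently with the
#' spec's connection probability; connection delays are Gaussian around
#' `center` with the spec's jitter, truncated at 0.
#'
#' @param n_from,n_to Population sizes.
#' @param center Mean delay (ms).
#' @param spec A [population_spec()].
#' @return List with `mask` (`n_to x n_from` logical) and `delays`
#'   (matrix, `NA` where unconnected).
#' @export
wire_projection <- function(n_from, n_to, center, spec) {
  mask <- matrix(runif(n_to * n_from) < spec$connection_probability,
                 n_to, n_from)
  delays <- matrix(pmax(rnorm(n_to * n_from, center, spec$delay_jitter), 0),
                   n_to, n_from)
  delays[!mask] <- NA_real_
  list(mask = mask, delays = delays)
}

#' Wire the population AND-gate (two input populations onto one output)
#'
#' @param spec A [population_spec()].
#' @param tau_AC Mean delay from population A to C (ms); default 5.
#' @param gamma Time-lag added to the B-to-C delay (ms); default 0
#'   (`tau_BC = tau_AC + gamma`).
#' @param seed Integer seed.
#' @return List with projections `A` and `B` (each as from
#'   [wire_projection()]) and the per-C-neuron input counts `in_degree`.
#' @export
wire_populations <- function(spec, tau_AC = 5, gamma = 0, seed = 1L) {
  set.seed(derive_seed(seed, "connectivity"))
  A <- wire_projection(spec$size, spec$size, tau_AC, spec)
  B <- wire_projection(spec$size, spec$size, tau_AC + gamma, spec)
  list(A = A, B = B, in_degree = rowSums(A$mask) + rowSums(B$mask))
}

# arrivals at a target population given source spike times, per-source
# latency stretch, and a projection
projection_events <- function(spikes, q, proj, g, delta) {
  idx <- which(proj$mask & !is.na(spikes)[col(proj$mask)], arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(time = numeric(0), g = numeric(0), neuron = integer(0)))
  }
  src <- idx[, 2]; tgt <- idx[, 1]
  data.frame(time = spikes[src] + q[src] * delta +
               proj$delays[idx],
             g = g, neuron = tgt)
}

drive_events <- function(n, spec, t = 0) {
  data.frame(time = rep(t, n), g = spec$g_strong, neuron = seq_len(n))
}

#' Output-population firing probability versus input time-lag
#'
#' All neurons of the input populations A and B receive a common strong
#' drive; C receives their spikes through diluted weak projections with
#' mean delays `tau_AC` and `tau_AC + gamma`.  The fraction of C neurons
#' that fire is reported per trial (fresh wiring and jitter per trial).
#'
#' @param spec A [population_spec()].
#' @param gamma Numeric vector of time-lags (ms).
#' @param trials Trials per lag.
#' @param tau_AC Mean A-to-C delay (ms); default 5.
#' @param seed Integer root seed.
#' @return Data frame with columns `gamma`, `trial`, `fraction`.
#' @export
firing_probability_vs_gamma <- function(spec, gamma, trials = 20,
                                        tau_AC = 5, seed = 1L) {
  out <- list()
  N <- spec$size
  q0 <- numeric(N)
  for (g in gamma) {
    for (tr in seq_len(trials)) {
      set.seed(derive_seed(seed, sprintf("gamma%.4f_trial%d", g, tr)))
      A <- wire_projection(N, N, tau_AC, spec)
      B <- wire_projection(N, N, tau_AC + g, spec)
      sA <- simulate_population(drive_events(N, spec), N, spec)$first_spike
      sB <- simulate_population(drive_events(N, spec), N, spec)$first_spike
      ev <- rbind(projection_events(sA, q0, A, spec$g_weak, spec$delta),
                  projection_events(sB, q0, B, spec$g_weak, spec$delta))
      resC <- simulate_population(ev, N, spec)
      out[[length(out) + 1L]] <- data.frame(
        gamma = g, trial = tr, fraction = mean(!is.na(resC$first_spike)))
    }
  }
  do.call(rbind, out)
}

#' Dynamic AND-gate in population form
#'
#' One input drives a chain of three populations (A -> C -> D, strong
#' projections), the other a single population B; D and B project weakly
#' onto the output population E.  Every neuron's outgoing delay stretches
#' by `delta` per evoked spike, so the three-population chain stretches
#' three times as fast as the one-population chain and the inter-arrival
#' lag at E first closes and then reopens: a NULL-AND-NULL transition.
#'
#' The initial lag is imposed by calibrating the mean B-to-E delay against
#' a jitter-free dry run (the experimental protocol likewise sets initial
#' delays by construction).
#'
#' @param spec A [population_spec()].
#' @param n_stim Number of simultaneous input stimulations; default 50.
#' @param initial_lag Initial mean lag between the chain-side and B-side
#'   arrival times at E (ms, chain earlier); default 2.
#' @param stage_delay Mean delay of each inter-population stage (ms);
#'   default 4.
#' @param seed Integer root seed.
#' @return Data frame per stimulation: `stim`, `lag` (absolute mean
#'   arrival-time difference at E), `signed_lag` (B minus chain),
#'   `fraction_fired` (of population E), `tau_chain`, `tau_B` (mean
#'   arrival times, ms).
#' @export
dynamic_population_and <- function(spec, n_stim = 50, initial_lag = 2,
                                   stage_delay = 4, seed = 1L) {
  N <- spec$size
  set.seed(derive_seed(seed, "population-wiring"))
  pAC <- wire_projection(N, N, stage_delay, spec)
  pCD <- wire_projection(N, N, stage_delay, spec)
  pDE <- wire_projection(N, N, stage_delay, spec)
  # jitter-free dry run over the actual chain wiring to find the mean
  # chain-side arrival time at E, then place the mean B-to-E delay so the
  # initial inter-arrival lag is exactly `initial_lag` (the study sets the
  # initial delay difference by construction)
  flat <- function(p, center) {
    p$delays[p$mask] <- center; p$delays[!p$mask] <- NA_real_; p
  }
  sA0 <- simulate_population(drive_events(N, spec), N, spec)$first_spike
  sC0 <- simulate_population(projection_events(sA0, numeric(N),
                                               flat(pAC, stage_delay),
                                               spec$g_strong, 0),
                             N, spec)$first_spike
  sD0 <- simulate_population(projection_events(sC0, numeric(N),
                                               flat(pCD, stage_delay),
                                               spec$g_strong, 0),
                             N, spec)$first_spike
  chain_arr <- mean(projection_events(sD0, numeric(N),
                                      flat(pDE, stage_delay),
                                      spec$g_weak, 0)$time)
  sB0 <- simulate_population(drive_events(N, spec), N, spec)$first_spike
  d_BE <- chain_arr + initial_lag - mean(sB0, na.rm = TRUE)
  pBE <- wire_projection(N, N, d_BE, spec)
  qA <- numeric(N); qB <- numeric(N); qC <- numeric(N); qD <- numeric(N)
  rows <- vector("list", n_stim)
  for (s in seq_len(n_stim)) {
    sA <- simulate_population(drive_events(N, spec), N, spec)$first_spike
    sB <- simulate_population(drive_events(N, spec), N, spec)$first_spike
    evC <- projection_events(sA, qA, pAC, spec$g_strong, spec$delta)
    sC <- simulate_population(evC, N, spec)$first_spike
    evD <- projection_events(sC, qC, pCD, spec$g_strong, spec$delta)
    sD <- simulate_population(evD, N, spec)$first_spike
    evE_chain <- projection_events(sD, qD, pDE, spec$g_weak, spec$delta)
    evE_B <- projection_events(sB, qB, pBE, spec$g_weak, spec$delta)
    resE <- simulate_population(rbind(evE_chain, evE_B), N, spec)
    tau_chain <- mean(evE_chain$time)
    tau_B <- mean(evE_B$time)
    rows[[s]] <- data.frame(stim = s, lag = abs(tau_B - tau_chain),
                            signed_lag = tau_B - tau_chain,
                            fraction_fired = mean(!is.na(resE$first_spike)),
                            tau_chain = tau_chain, tau_B = tau_B)
    qA <- qA + !is.na(sA); qB <- qB + !is.na(sB)
    qC <- qC + !is.na(sC); qD <- qD + !is.na(sD)
  }
  do.call(rbind, rows)
}
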