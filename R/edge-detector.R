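# Edge detector: a bank of dynamic AND-gates over consecutive input pairs.
# Rate-coding the brightness vector into stimulation counts makes the
# latency of each input chain a record of its accumulated activity; after
# the charging period, a probe stimulation lights up every gate whose two
# inputs stayed within the summation window -- gates at brightness
# discontinuities have drifted apart and stay NULL.

#' Create an edge detector
#'
#' `n` input neurons; each consecutive pair feeds a shared dynamic AND-gate
#' (weak terminal stimulations, common summation window).  Initially all
#' delays are equal, so a probe fires every gate.
#'
#' @param n Number of input positions (`>= 2`).
#' @param delta Latency increment (ms/spike); default 0.006.
#' @param window Summation window of the gate outputs (ms); default 0.4.
#' @param l0 Initial input-neuron latency (ms); default 1.
#' @param base_delay Common input-to-gate link delay (ms); default 10.
#' @param strength Weak terminal strength; default 0.5.
#' @param threshold Gate firing threshold; default 1.
#' @return Object of class `edge_detector`.
#' @export
edge_detector <- function(n, delta = 0.006, window = 0.4, l0 = 1,
                          base_delay = 10, strength = 0.5, threshold = 1) {
  if (n < 2) stop("an edge detector needs at least two input positions")
  structure(list(n = as.integer(n), delta = delta, window = window,
                 l0 = l0, base_delay = base_delay, strength = strength,
                 threshold = threshold, q = numeric(n)),
            class = "edge_detector")
}

#' Charge an edge detector with a brightness vector
#'
#' Each input neuron is stimulated a number of times proportional to the
#' brightness of its position, over a common charging period.
#' `mode = "count"` uses the deterministic count
#' `round(duration * b_i / max(b))`; `mode = "probability"` keeps a single
#' global clock of `duration` ticks and delivers each tick to input `i`
#' with probability `b_i / max(b)` (inter-spike intervals then vary
#' little, as rate coding assumes).  Every delivered stimulation evokes a
#' spike and stretches that input's latency by `delta`.
#'
#' @param detector An [edge_detector()].
#' @param brightness Non-negative numeric vector of length `n`.
#' @param duration Charging budget (stimulation ticks).
#' @param mode `"count"` (default) or `"probability"`.
#' @param seed Seed for the probabilistic mode.
#' @return The charged detector.
#' @export
charge <- function(detector, brightness, duration,
                   mode = c("count", "probability"), seed = 1L) {
  mode <- match.arg(mode)
  if (length(brightness) != detector$n)
    stop("brightness vector must have length ", detector$n)
  if (any(brightness < 0)) stop("brightness values must be non-negative")
  if (max(brightness) == 0) return(detector)
  p <- brightness / max(brightness)
  counts <- if (mode == "count") {
    round(duration * p)
  } else {
    set.seed(derive_seed(seed, "edge-charging"))
    rbinom(detector$n, size = duration, prob = p)
  }
  detector$q <- detector$q + counts
  detector
}

#' Probe a charged edge detector
#'
#' Simultaneous stimulation of all input neurons; each gate fires (AND)
#' iff its two arrivals coincide within the summation window and their
#' summed weak strengths reach the threshold -- the detection criterion is
#' exactly the gates' own summation rule.  Probing is non-perturbing: the
#' detector's state is not advanced.
#'
#' @param detector A (possibly charged) [edge_detector()].
#' @return Data frame with one row per adjacent pair: `pair` (index of the
#'   left position), `delay_diff` (ms), `mode` (`"AND"` or `"NULL"`),
#'   `edge` (logical: `TRUE` where the gate stayed NULL).
#' @export
probe_edges <- function(detector) {
  d <- detector
  delays <- d$l0 + d$q * d$delta + d$base_delay
  out <- vector("list", d$n - 1L)
  for (i in seq_len(d$n - 1L)) {
    arr <- list(time = delays[c(i, i + 1L)], strength = rep(d$strength, 2))
    dec <- summation_decision(arr, d$threshold, d$window)
    out[[i]] <- data.frame(pair = i,
                           delay_diff = delays[i + 1L] - delays[i],
                           mode = if (dec$fires) "AND" else "NULL",
                           edge = !dec$fires)
  }
  do.call(rbind, out)
}

#' Reset an edge detector for reuse
#'
#' Latency stretching is reversible; after a short rest the detector
#' recovers its initial equal delays.
#'
#' @param detector An [edge_detector()].
#' @return The reset detector.
#' @export
reset_detector <- function(detector) {
  detector$q <- numeric(detector$n)
  detector
}

#' Detect edges in a brightness vector
#'
#' Convenience wrapper: charge a fresh detector and probe it.
#'
#' @param brightness Non-negative numeric vector.
#' @param duration Charging budget; longer periods give higher contrast
#'   sensitivity.
#' @param ... Passed to [edge_detector()] and [charge()].
#' @param mode Charging mode.
#' @param seed Seed for the probabilistic mode.
#' @return The probe report (see [probe_edges()]).
#' @export
detect_edges <- function(brightness, duration = 500,
                         mode = c("count", "probability"), seed = 1L, ...) {
  det <- edge_detector(length(brightness), ...)
  det <- charge(det, brightness, duration, mode = mode, seed = seed)
  probe_edges(det)
}
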