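# Analytic engine: closed-form delay-line diagrams, pairwise intersections,
# firing regions and mode timelines, all under the 1:1 response assumption
# (every stimulation evokes a spike in every chain neuron, so each chain's
# delay to any node is an exact straight line in the stimulation count q).

#' Construct a delay line
#'
#' @param chain_id Label of the originating input chain.
#' @param intercept Initial delay `tau0` (ms).
#' @param slope Delay growth per stimulation (ms): `n * delta` for a chain
#'   of `n` stretching neurons.
#' @param strength Terminal stimulation strength.
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @param target Node the line is referenced at (where the stimulation
#'   arrives).
#' @return A one-row data frame of class `delay_line`.
#' @export
delay_line <- function(chain_id, intercept, slope, strength = 1,
                       sign = "excitatory", target = NA_character_) {
  if (slope < 0) stop("delay-line slope must be >= 0")
  structure(data.frame(chain_id = chain_id, intercept = intercept,
                       slope = slope, strength = strength, sign = sign,
                       target = target, stringsAsFactors = FALSE),
            class = c("delay_line", "data.frame"))
}

#' Evaluate delay lines at stimulation counts
#'
#' @param lines Data frame of delay lines.
#' @param q Numeric vector of stimulation counts.
#' @return Matrix with one row per line, one column per `q`.
#' @export
line_delays <- function(lines, q) {
  outer(lines$intercept, rep(1, length(q))) + outer(lines$slope, q)
}

# All simple paths from `from` that reach `node`, following excitatory links
# except possibly a final inhibitory link into `node`.  Returns a list of
# character vectors of neuron ids (path excluding `node`), with attributes
# for the terminal link.
paths_to_node <- function(circuit, from, node) {
  ld <- circuit$links
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    nxt <- which(ld$source == cur)
    for (j in nxt) {
      tgt <- ld$target[j]
      if (tgt == node) {
        p <- path
        attr(p, "strength") <- ld$strength[j]
        attr(p, "sign") <- ld$sign[j]
        out[[length(out) + 1L]] <<- p
      } else if (ld$sign[j] == "excitatory" && !(tgt %in% path)) {
        walk(c(path, tgt))
      }
    }
  }
  walk(from)
  out
}

line_from_path <- function(circuit, path, delta = NULL) {
  nd <- circuit$neurons
  idx <- match(path, nd$id)
  ld <- circuit$links
  # base delays along the path plus the terminal link into the node
  base <- 0
  if (length(path) > 1L) {
    for (i in seq_len(length(path) - 1L)) {
      j <- which(ld$source == path[i] & ld$target == path[i + 1L] &
                   ld$sign == "excitatory")[1]
      base <- base + ld$delay[j]
    }
  }
  term <- attr(path, "terminal_delay")
  slopes <- if (is.null(delta)) nd$delta[idx] else rep(delta, length(idx))
  list(intercept = sum(nd$l0[idx]) + base + term,
       slope = sum(slopes))
}

#' Build delay lines for a circuit
#'
#' Under 1:1 response, each simple input-to-node path defines one straight
#' line `tau0 + n*q*delta` where `n` counts the path's neurons excluding the
#' node itself (the stimulated input neuron is included).  Multiple paths
#' from one input each become their own line.
#'
#' @param circuit A [circuit_spec()].
#' @param delta Latency increment (ms/spike) applied to every neuron;
#'   `NULL` uses the per-neuron values stored in the circuit.
#' @param node Reference node; default the circuit's output neuron.
#' @param sources Input labels to trace; default the logical inputs plus any
#'   outer neurons.
#' @return Data frame with columns `chain_id`, `intercept`, `slope`,
#'   `strength`, `sign`, `target`, `source`, `n`.
#' @export
build_lines <- function(circuit, delta = NULL, node = circuit$output,
                        sources = c(circuit$inputs, circuit$outer)) {
  rows <- list()
  for (src in sources) {
    paths <- paths_to_node(circuit, src, node)
    for (k in seq_along(paths)) {
      p <- paths[[k]]
      j <- which(circuit$links$source == p[length(p)] &
                   circuit$links$target == node)
      # terminal link delay: re-find the matching link (same sign/strength)
      jj <- j[circuit$links$sign[j] == attr(p, "sign") &
                circuit$links$strength[j] == attr(p, "strength")][1]
      attr(p, "terminal_delay") <- circuit$links$delay[jj]
      ln <- line_from_path(circuit, p, delta)
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = if (length(paths) > 1L) paste0(src, ".", k) else src,
        intercept = ln$intercept, slope = ln$slope,
        strength = attr(p, "strength"), sign = attr(p, "sign"),
        target = node, source = src, n = length(p),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise intersections of delay lines
#'
#' Every pair of non-parallel lines whose delay difference changes sign at a
#' positive stimulation count `q* = (tau0_i - tau0_j) / (slope_j - slope_i)`
#' inside `(0, Q)` marks a transition to an AND operating mode of the
#' corresponding input pair.
#'
#' @param lines Data frame of delay lines.
#' @param horizon Upper bound `Q` on the stimulation count.
#' @return Data frame with columns `chain_i`, `chain_j`, `q`.
#' @export
pairwise_intersections <- function(lines, horizon = Inf) {
  stopifnot(horizon > 0)
  k <- nrow(lines)
  out <- list()
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        ds <- lines$slope[j] - lines$slope[i]
        if (ds == 0) next
        qs <- (lines$intercept[i] - lines$intercept[j]) / ds
        if (qs > 0 && qs < horizon) {
          out[[length(out) + 1L]] <- data.frame(
            chain_i = lines$chain_id[i], chain_j = lines$chain_id[j],
            q = qs, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chain_i = character(), chain_j = character(), q = numeric())
}

# Open interval of q where |(i1 + s1 q) - (i2 + s2 q)| < w, or NULL when it
# does not meet [0, Q].  Bounds are returned unclipped so that membership
# tests stay open only at true transition abscissae, never at a clip to the
# physical range (q = 0 can be interior to a region that straddles zero).
pair_interval <- function(i1, s1, i2, s2, w, Q) {
  o <- i1 - i2; s <- s1 - s2
  if (s == 0) {
    if (abs(o) < w) c(-Inf, Inf) else NULL
  } else {
    b <- sort(c((-w - o) / s, (w - o) / s))
    if (b[2] <= 0 || b[1] >= Q) NULL else b
  }
}

union_intervals <- function(iv) {
  if (!length(iv)) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, iv)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  out
}

#' Firing regions of an output neuron under simultaneous 1:1 drive
#'
#' Finds the intervals of the (continuous) stimulation count `q` where some
#' subset of excitatory delay lines lies pairwise within the summation
#' window `w` and has summed strengths reaching the threshold.  For a pair
#' with slope difference `s` the region is the interval of half-width `w/|s|`
#' around the intersection abscissa.
#'
#' Both views are returned: per qualifying subset (minimal subsets only,
#' used for transition counting) and merged into disjoint regions (used for
#' mode labeling).
#'
#' @param lines Data frame of delay lines (excitatory ones are used).
#' @param threshold Firing threshold of the output neuron.
#' @param window Summation window `w` (ms).
#' @param horizon Upper bound `Q`.
#' @return List with `regions` (data frame `q_start`, `q_end`, merged and
#'   disjoint), `subsets` (per minimal qualifying subset: members and
#'   interval), and a membership function `fires_at(q)`.
#' @export
firing_regions <- function(lines, threshold = 1, window = 0.4, horizon) {
  ex <- lines[lines$sign == "excitatory", , drop = FALSE]
  k <- nrow(ex)
  subsets <- list()
  if (k >= 1L && threshold <= 0) {
    subsets[[1]] <- list(members = ex$chain_id, interval = c(-Inf, Inf))
  } else if (k >= 1L) {
    all_idx <- seq_len(k)
    qualifying <- list()
    for (m in seq_len(k)) {
      combos <- utils::combn(all_idx, m, simplify = FALSE)
      for (S in combos) {
        if (sum(ex$strength[S]) < threshold) next
        # minimality: no qualifying proper subset
        is_min <- !any(vapply(qualifying, function(T) all(T %in% S), logical(1)))
        if (!is_min) next
        iv <- c(-Inf, Inf)
        ok <- TRUE
        if (length(S) > 1L) {
          for (a in seq_len(length(S) - 1L)) {
            for (b in seq.int(a + 1L, length(S))) {
              pi <- pair_interval(ex$intercept[S[a]], ex$slope[S[a]],
                                  ex$intercept[S[b]], ex$slope[S[b]],
                                  window, horizon)
              if (is.null(pi)) { ok <- FALSE; break }
              iv <- c(max(iv[1], pi[1]), min(iv[2], pi[2]))
              if (iv[1] >= iv[2]) { ok <- FALSE; break }
            }
            if (!ok) break
          }
        }
        if (ok && max(iv[1], 0) < min(iv[2], horizon)) {
          qualifying[[length(qualifying) + 1L]] <- S
          subsets[[length(subsets) + 1L]] <-
            list(members = ex$chain_id[S], interval = iv)
        }
      }
    }
  }
  merged <- union_intervals(lapply(subsets, `[[`, "interval"))
  regions <- data.frame(q_start = pmax(merged[, 1], 0),
                        q_end = pmin(merged[, 2], horizon))
  fires_at <- function(q) {
    res <- rep(FALSE, length(q))
    for (s in subsets) {
      res <- res | (q > s$interval[1] & q < s$interval[2])
    }
    res
  }
  list(regions = regions, subsets = subsets, fires_at = fires_at)
}

#' Inhibition region of an excitatory line against an inhibitory line
#'
#' The excitatory arrival is vetoed where `excitatory - inhibitory` lies in
#' the inhibition window `[a, b]`.  With offset `d0 = exc_intercept -
#' inh_intercept` and relative slope `s`, the closed form is
#' `q` in `[(a - d0)/s, (b - d0)/s]` (bounds ordered by the sign of `s`).
#'
#' @param excitatory,inhibitory One-row delay-line data frames (referenced
#'   at the same node).
#' @param window Length-2 numeric `(a, b)`, `a < b`.
#' @param horizon Upper bound `Q`.
#' @return Matrix with columns `q_start`, `q_end` (possibly zero rows; the
#'   whole horizon when the lines are parallel and the offset sits inside
#'   the window).
#' @export
inhibition_regions <- function(excitatory, inhibitory, window = c(1, 7),
                               horizon) {
  stopifnot(window[1] < window[2])
  d0 <- excitatory$intercept - inhibitory$intercept
  s <- excitatory$slope - inhibitory$slope
  if (s == 0) {
    if (d0 >= window[1] && d0 <= window[2]) {
      m <- matrix(c(0, horizon), ncol = 2)
    } else {
      m <- matrix(numeric(0), ncol = 2)
    }
  } else {
    b <- sort(c((window[1] - d0) / s, (window[2] - d0) / s))
    b <- c(max(b[1], 0), min(b[2], horizon))
    m <- if (b[1] < b[2]) matrix(b, ncol = 2) else matrix(numeric(0), ncol = 2)
  }
  colnames(m) <- c("q_start", "q_end")
  m
}

# Evaluate the truth table of a circuit at one continuous stimulation count
# q, analytically: all chains respond 1:1, arrivals are line values.
# Returns data.frame(combo columns, fired, spikes).
truth_table_at <- function(circuit, delta, q, lines_out = NULL) {
  ins <- circuit$inputs
  k <- length(ins)
  nd <- circuit$neurons
  outn <- nd[nd$id == circuit$output, ]
  iw <- circuit$inhibition_window
  combos <- expand.grid(rep(list(c(0L, 1L)), k))
  names(combos) <- ins
  # lines from every driver to the output
  if (is.null(lines_out))
    lines_out <- build_lines(circuit, delta, node = circuit$output)
  # inhibitory links anywhere: lines referenced at their targets
  inh_ld <- circuit$links[circuit$links$sign == "inhibitory", , drop = FALSE]
  inh_info <- list()
  if (nrow(inh_ld)) {
    for (tgt in unique(inh_ld$target)) {
      ltgt <- build_lines(circuit, delta, node = tgt)
      inh_info[[tgt]] <- ltgt
    }
  }
  fired <- integer(nrow(combos)); spikes <- integer(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    active <- c(ins[combos[ci, ] == 1L], circuit$outer)
    if (!length(active)) { fired[ci] <- 0L; spikes[ci] <- 0L; next }
    # determine which excitatory output lines are suppressed by inhibition
    # at some mid-path node, and blackout intervals at the output itself
    blk_lo <- numeric(0); blk_hi <- numeric(0)
    suppressed_nodes <- character(0)
    for (tgt in names(inh_info)) {
      ltgt <- inh_info[[tgt]]
      inh_lines <- ltgt[ltgt$sign == "inhibitory" & ltgt$source %in% active, ,
                        drop = FALSE]
      if (!nrow(inh_lines)) next
      inh_arr <- inh_lines$intercept + inh_lines$slope * q
      if (tgt == circuit$output) {
        blk_lo <- c(blk_lo, inh_arr + iw[1])
        blk_hi <- c(blk_hi, inh_arr + iw[2])
      } else {
        exc_lines <- ltgt[ltgt$sign == "excitatory" & ltgt$source %in% active, ,
                          drop = FALSE]
        if (!nrow(exc_lines)) next
        exc_arr <- exc_lines$intercept + exc_lines$slope * q
        for (e in seq_along(exc_arr)) {
          d <- exc_arr[e] - inh_arr
          if (any(d >= iw[1] & d <= iw[2])) {
            suppressed_nodes <- c(suppressed_nodes, tgt)
          }
        }
      }
    }
    act_lines <- lines_out[lines_out$sign == "excitatory" &
                             lines_out$source %in% active, , drop = FALSE]
    if (length(suppressed_nodes)) {
      keep <- vapply(seq_len(nrow(act_lines)), function(i) {
        p <- paths_to_node(circuit, act_lines$source[i], circuit$output)
        # a line is suppressed if its path passes through a vetoed node
        !any(vapply(p, function(pp) any(suppressed_nodes %in% pp), logical(1)))
      }, logical(1))
      act_lines <- act_lines[keep, , drop = FALSE]
    }
    arr <- data.frame(time = act_lines$intercept + act_lines$slope * q,
                      strength = act_lines$strength)
    blk <- if (length(blk_lo)) cbind(blk_lo, blk_hi) else NULL
    res <- resolve_firing(arr, numeric(0), outn$window, outn$threshold,
                          outn$refractory, iw, blackouts = blk)
    fired[ci] <- as.integer(length(res$fires) > 0)
    spikes[ci] <- length(res$fires)
  }
  cbind(combos, fired = fired, spikes = spikes)
}

# Candidate breakpoints in q where the truth table can change: boundaries of
# pairwise proximity (|diff| = w), inhibition-window crossings, and
# refractory-gap crossings, for lines referenced at the relevant nodes.
timeline_breakpoints <- function(circuit, delta, horizon) {
  nd <- circuit$neurons
  outn <- nd[nd$id == circuit$output, ]
  iw <- circuit$inhibition_window
  bp <- numeric(0)
  add_pair_bps <- function(i1, s1, i2, s2, offs) {
    o <- i1 - i2; s <- s1 - s2
    if (s == 0) return()
    for (d in offs) bp <<- c(bp, (d - o) / s)
  }
  nodes <- unique(c(circuit$output,
                    circuit$links$target[circuit$links$sign == "inhibitory"]))
  for (nodei in nodes) {
    ln <- build_lines(circuit, delta, node = nodei)
    if (is.null(ln) || nrow(ln) < 1L) next
    wn <- nd$window[nd$id == nodei]
    rn <- nd$refractory[nd$id == nodei]
    n <- nrow(ln)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          si <- ln$sign[i]; sj <- ln$sign[j]
          if (si == "excitatory" && sj == "excitatory") {
            add_pair_bps(ln$intercept[i], ln$slope[i],
                         ln$intercept[j], ln$slope[j],
                         c(-wn, wn, -rn, rn))
          } else if (si != sj) {
            # excitatory vs inhibitory: window entry/exit (both orders)
            add_pair_bps(ln$intercept[i], ln$slope[i],
                         ln$intercept[j], ln$slope[j],
                         c(iw[1], iw[2], -iw[1], -iw[2]))
          }
        }
      }
    }
  }
  sort(unique(c(0, bp[bp > 0 & bp < horizon], horizon)))
}

table_signature <- function(tt) {
  paste(tt$fired, tt$spikes, collapse = ";", sep = ",")
}

#' Mode timeline of a gate
#'
#' Partitions the stimulation axis `[0, Q]` into intervals of constant truth
#' table, evaluated analytically over all `2^k` input combinations (outer
#' stimulations always on), and labels each interval with its logic
#' operating mode.  The table is piecewise constant in `q`; interval
#' boundaries are found in closed form from the delay-line arrangement and
#' each interval is classified at its midpoint.
#'
#' @param circuit A [circuit_spec()].
#' @param delta Latency increment (ms/spike), applied to every neuron.
#' @param horizon Upper bound `Q` on the stimulation count.
#' @return Object of class `mode_timeline`: data frame with `q_start`,
#'   `q_end` (continuous bounds), `label`, `boolean_label` (multiplicity
#'   ignored), plus the truth tables as an attribute.
#' @export
mode_timeline <- function(circuit, delta = NULL, horizon) {
  stopifnot(horizon > 0)
  bp <- timeline_breakpoints(circuit, delta, horizon)
  lines_out <- build_lines(circuit, delta, node = circuit$output)
  rows <- list(); tables <- list()
  for (i in seq_len(length(bp) - 1L)) {
    qm <- (bp[i] + bp[i + 1L]) / 2
    tt <- truth_table_at(circuit, delta, qm, lines_out = lines_out)
    rows[[i]] <- data.frame(q_start = bp[i], q_end = bp[i + 1L],
                            label = classify_table(tt),
                            boolean_label = classify_table(tt, multiplicity = FALSE),
                            stringsAsFactors = FALSE)
    tables[[i]] <- tt
  }
  df <- do.call(rbind, rows)
  # merge consecutive intervals with identical truth tables
  sig <- vapply(tables, table_signature, character(1))
  keep <- c(TRUE, sig[-1] != sig[-length(sig)])
  grp <- cumsum(keep)
  merged <- do.call(rbind, lapply(split(seq_along(grp), grp), function(ix) {
    data.frame(q_start = df$q_start[ix[1]], q_end = df$q_end[ix[length(ix)]],
               label = df$label[ix[1]], boolean_label = df$boolean_label[ix[1]],
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  attr(merged, "tables") <- tables[keep]
  class(merged) <- c("mode_timeline", "data.frame")
  merged
}

#' @export
print.mode_timeline <- function(x, ...) {
  cat("<mode_timeline> ", nrow(x), " intervals over q in [",
      x$q_start[1], ", ", x$q_end[nrow(x)], "]\n", sep = "")
  print(as.data.frame(x[, c("q_start", "q_end", "label")]), ...)
  cat("mode sequence: ", paste(x$label, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Discretize a mode timeline onto the integer stimulation grid
#'
#' Continuous interval boundaries falling between integers are assigned to
#' the later integer.
#'
#' @param timeline A [mode_timeline()].
#' @return Data frame `q` (integer), `label`, `boolean_label`.
#' @export
discretize_timeline <- function(timeline) {
  qmax <- floor(timeline$q_end[nrow(timeline)])
  q <- 0:qmax
  idx <- findInterval(q, timeline$q_start)
  data.frame(q = q, label = timeline$label[idx],
             boolean_label = timeline$boolean_label[idx],
             stringsAsFactors = FALSE)
}

#' Check rescaling invariance of firing regions under a change of Delta
#'
#' The delay-line geometry depends on `q` only through `q * delta`, so
#' region boundaries under `delta2` must equal those under `delta1`
#' multiplied by `delta1/delta2` -- unless a `delta`-independent time scale
#' (e.g. the refractory period against absolute delay gaps) interferes.
#'
#' @param circuit A [circuit_spec()].
#' @param delta1,delta2 Latency increments to compare (ms/spike).
#' @param horizon Upper bound `Q` (applies to the `delta1` axis; the
#'   `delta2` run uses the rescaled horizon).
#' @param tol Relative tolerance on the boundary comparison.
#' @return Logical: `TRUE` iff all merged region boundaries rescale.
#' @export
rescale_check <- function(circuit, delta1, delta2, horizon, tol = 1e-9) {
  stopifnot(delta1 > 0, delta2 > 0)
  outn <- circuit$neurons[circuit$neurons$id == circuit$output, ]
  f1 <- firing_regions(build_lines(circuit, delta1), outn$threshold,
                       outn$window, horizon)
  f2 <- firing_regions(build_lines(circuit, delta2), outn$threshold,
                       outn$window, horizon * delta1 / delta2)
  b1 <- as.matrix(f1$regions); b2 <- as.matrix(f2$regions)
  if (!all(dim(b1) == dim(b2))) return(FALSE)
  if (!length(b1)) return(TRUE)
  expected <- b1 * delta1 / delta2
  all(abs(b2 - expected) <= tol * pmax(abs(expected), 1))
}

#' Synfire equivalence of two gates
#'
#' Two gates have identical mode-transition stimulation counts whenever the
#' pairwise differences of their chain lengths and of their initial delays
#' match -- long synfire chains with short per-link delays reproduce the
#' transition timings of short chains with long delays.
#'
#' @param circuit_a,circuit_b Circuits to compare.
#' @param delta Latency increment (ms/spike).
#' @param horizon Upper bound `Q`.
#' @param tol Absolute tolerance on transition abscissae (stimulations).
#' @return Logical.
#' @export
synfire_equivalent <- function(circuit_a, circuit_b, delta, horizon,
                               tol = 1e-9) {
  ta <- mode_timeline(circuit_a, delta, horizon)
  tb <- mode_timeline(circuit_b, delta, horizon)
  if (nrow(ta) != nrow(tb)) return(FALSE)
  if (!all(ta$label == tb$label)) return(FALSE)
  all(abs(ta$q_start - tb$q_start) <= tol) &&
    all(abs(ta$q_end - tb$q_end) <= tol)
}
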