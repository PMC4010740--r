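# Fixture generator: programmatic reconstruction of the canonical study
# configurations.  Each fixture returns the exact parameterization used by
# the package's validation suite (circuit or detector plus the matching
# stimulation protocol and analysis parameters).

fixture_builders <- function() {
  list(
    fig2_and = function() {
      circ <- build_and(chains = c(3, 1), tau2 = 80, gap = 1.6,
                        delta = 0.005, window = 0.5)
      list(circuit = circ, delta = 0.005, horizon = 600,
           protocol = periodic_protocol(600, 10, circ$inputs))
    },
    fig3_or = function() {
      circ <- build_or(chains = c(4, 1), tau2 = 80, gap = 8, delta = 0.005)
      list(circuit = circ, delta = 0.005, horizon = 1000,
           protocol = periodic_protocol(1000, 10, circ$inputs))
    },
    fig4_not = function() {
      circ <- build_not(inh_chain = 2, tau_exc = 80, tau_inh = 70,
                        delta = 0.005)
      list(circuit = circ, delta = 0.005, horizon = 2200,
           protocol = periodic_protocol(2200, 10, circ$inputs))
    },
    fig6c = function() {
      circ <- build_generalized_and(c(1, 2, 5), c(30, 27, 25),
                                    delta = 0.004, window = 0.4)
      list(circuit = circ, delta = 0.004, horizon = 1000,
           protocol = periodic_protocol(1000, 10, circ$inputs))
    },
    fig6d = function() {
      circ <- build_generalized_and(c(1, 2, 5), c(30, 27, 25),
                                    delta = 0.006, window = 0.4)
      list(circuit = circ, delta = 0.006, horizon = 1000,
           protocol = periodic_protocol(1000, 10, circ$inputs))
    },
    fig6e = function() {
      circ <- build_generalized_and(c(1, 2, 3), c(30, 27, 25),
                                    delta = 0.006, window = 0.4)
      list(circuit = circ, delta = 0.006, horizon = 1000,
           protocol = periodic_protocol(1000, 10, circ$inputs))
    },
    fig7a = function() {
      # strictly decreasing initial delays in general position: no three
      # lines concurrent, distinct intersection abscissae
      circ <- build_generalized_and(c(1, 2, 4, 6), c(30, 27.8, 25.2, 22.1),
                                    delta = 0.006, window = 0.4)
      list(circuit = circ, delta = 0.006, horizon = 1000,
           protocol = periodic_protocol(1000, 10, circ$inputs))
    },
    fig7b = function() {
      circ <- build_generalized_and(c(1, 2, 5), c(30, 27, 25),
                                    strengths = c(0.3, 0.75, 0.5),
                                    delta = 0.004, window = 0.4)
      list(circuit = circ, delta = 0.004, horizon = 1000,
           protocol = periodic_protocol(1000, 10, circ$inputs))
    },
    fig8_xor = function() {
      circ <- build_xor(chains = c(2, 5), taus = c(36, 30), tau_inh = 32,
                        delta = 0.006)
      list(circuit = circ, delta = 0.006, horizon = 1000,
           protocol = periodic_protocol(1000, 10, circ$inputs))
    },
    fig9_multimode = function() {
      circ <- build_multimode(delays = c(30, 42, 40, 10),
                              lengths = c(5, 2, 3), delta = 0.006)
      list(circuit = circ, delta = 0.006, horizon = 2000,
           protocol = periodic_protocol(2000, 10, circ$inputs))
    },
    fig10_varying = function() {
      circ <- build_generalized_and(c(3, 6), c(30, 28), delta = 0.006,
                                    window = 0.4)
      proto <- periodic_protocol(700, 10, circ$inputs)
      proto <- moderate_protocol(proto, "in2", c(250, 475), 0.1)
      list(circuit = circ, delta = 0.006, horizon = 700, protocol = proto,
           moderated_input = "in2", moderation_interval = c(250, 475),
           moderation_probability = 0.1)
    },
    fig11_edges = function() {
      list(detector = edge_detector(8, delta = 0.006, window = 0.4),
           brightness = c(1, 1, 1, 1, 5, 5, 5, 5), duration = 500)
    },
    fig12a = function() {
      circ <- build_generalized_and(c(1, 2, 5), c(30, 27, 25),
                                    delta = 0.006, window = 0.4)
      list(circuit = circ, delta = 0.006, horizon = 600,
           protocol = periodic_protocol(600, 10, circ$inputs))
    },
    fig12b = function() {
      # long synfire chains with 5-6 ms per-relay delays; chain-length and
      # initial-delay differences match fig12a (27-26 = 2-1, 30-26 = 5-1)
      circ <- build_generalized_and(c(26, 27, 30), c(156, 153, 151),
                                    delta = 0.006, window = 0.4)
      list(circuit = circ, delta = 0.006, horizon = 600,
           protocol = periodic_protocol(600, 10, circ$inputs))
    },
    fig13_population = function() {
      list(population = population_spec(size = 40,
                                        connection_probability = 0.1,
                                        delay_jitter = 0.15,
                                        g_strong = 1.6,
                                        E_syn = 0, delta = 0.04),
           initial_lag = 2, n_stim = 50)
    })
}

#' Named study fixtures
#'
#' Returns the exact parameterization of one of the canonical gate and
#' population configurations, seeded and ready to run.  `dlg_fixture()`
#' with no argument lists the available names.
#'
#' @param name Fixture name (see `dlg_fixture()` for the list).
#' @return A list whose components depend on the fixture: typically
#'   `circuit`, `protocol`, `delta`, `horizon`; the edge-detector fixture
#'   returns `detector`, `brightness`, `duration`; the population fixture
#'   returns `population`, `initial_lag`, `n_stim`.
#' @export
dlg_fixture <- function(name) {
  builders <- fixture_builders()
  if (missing(name)) return(names(builders))
  if (!name %in% names(builders))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  builders[[name]]()
}
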