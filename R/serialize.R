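# Serialization: circuits and population specs round-trip through YAML or
# JSON; stimulation protocols through CSV.

circuit_to_list <- function(circuit) {
  nd <- circuit$neurons
  list(
    neurons = lapply(seq_len(nrow(nd)), function(i) {
      list(id = nd$id[i], l0 = nd$l0[i], delta = nd$delta[i],
           window = nd$window[i], threshold = nd$threshold[i],
           refractory = nd$refractory[i])
    }),
    links = lapply(seq_len(nrow(circuit$links)), function(i) {
      l <- circuit$links[i, ]
      list(source = l$source, target = l$target, delay = l$delay,
           strength = l$strength, sign = l$sign)
    }),
    inputs = as.list(circuit$inputs),
    output = circuit$output,
    outer = as.list(circuit$outer),
    inhibition_window = as.list(circuit$inhibition_window))
}

circuit_from_list <- function(x) {
  need <- function(obj, fields, what) {
    miss <- setdiff(fields, names(obj))
    if (length(miss)) stop("malformed ", what, ": missing field(s) ",
                           paste(miss, collapse = ", "))
  }
  need(x, c("neurons", "links", "inputs", "output"), "circuit document")
  neurons <- lapply(x$neurons, function(n) {
    need(n, c("id", "l0", "delta"), paste0("neuron '", n$id %||% "?", "'"))
    neuron_spec(n$id, l0 = n$l0, delta = n$delta,
                window = n$window %||% 0.4, threshold = n$threshold %||% 1,
                refractory = n$refractory %||% 4)
  })
  links <- lapply(x$links, function(l) {
    need(l, c("source", "target", "delay"),
         paste0("link ", l$source %||% "?", " -> ", l$target %||% "?"))
    link_spec(l$source, l$target, delay = l$delay,
              strength = l$strength %||% 1, sign = l$sign %||% "excitatory")
  })
  circuit_spec(neurons, links, inputs = unlist(x$inputs),
               output = x$output, outer = unlist(x$outer) %||% character(),
               inhibition_window = unlist(x$inhibition_window) %||% c(1, 7))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a circuit to YAML or JSON
#'
#' The format follows the file extension (`.yaml`/`.yml` or `.json`).
#' Round-trips are lossless.
#'
#' @param circuit A [circuit_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(circuit, path) {
  x <- circuit_to_list(circuit)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    writeLines(yaml::as.yaml(x, precision = 15), path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported extension (use .yaml, .yml or .json): ", path)
  }
  invisible(path)
}

#' Read a circuit from YAML or JSON
#'
#' @param path Input file path.
#' @return A validated [circuit_spec()].
#' @export
read_circuit <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    stop("unsupported extension (use .yaml, .yml or .json): ", path)
  }
  circuit_from_list(x)
}

#' Write a stimulation protocol to CSV
#'
#' One row per (stimulation, input): columns `stim_index`, `input_id`,
#' `time_ms`, `probability`.
#'
#' @param protocol A [stimulation_protocol()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  k <- length(protocol$inputs)
  Q <- length(protocol$times)
  df <- data.frame(stim_index = rep(seq_len(Q), each = k),
                   input_id = rep(protocol$inputs, Q),
                   time_ms = rep(protocol$times, each = k),
                   probability = as.vector(t(protocol$probability)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a stimulation protocol from CSV
#'
#' Accepts either the long form written by [write_protocol()] or a compact
#' form with columns `input_id`, `rate_hz`, `count`, `probability` (one row
#' per input, periodic stimulation).
#'
#' @param path Input file path.
#' @return A [stimulation_protocol()].
#' @export
read_protocol <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("rate_hz", "count") %in% names(df))) {
    inputs <- df$input_id
    n <- unique(df$count); rate <- unique(df$rate_hz)
    if (length(n) != 1L || length(rate) != 1L)
      stop("compact protocol form requires a single rate_hz and count")
    p <- if ("probability" %in% names(df)) df$probability else 1
    return(periodic_protocol(n, rate, inputs, probability = p))
  }
  need <- c("stim_index", "input_id", "time_ms", "probability")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("protocol CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  inputs <- unique(df$input_id)
  s <- sort(unique(df$stim_index))
  times <- df$time_ms[match(s, df$stim_index)]
  p <- matrix(1, length(s), length(inputs), dimnames = list(NULL, inputs))
  for (i in seq_len(nrow(df))) {
    p[match(df$stim_index[i], s), df$input_id[i]] <- df$probability[i]
  }
  stimulation_protocol(times, inputs, p)
}

#' Write a population spec to YAML or JSON
#' @param spec A [population_spec()].
#' @param path Output path (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_population_spec <- function(spec, path) {
  x <- unclass(spec)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    writeLines(yaml::as.yaml(x, precision = 15), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a population spec from YAML or JSON
#' @param path Input path.
#' @return A [population_spec()].
#' @export
read_population_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  do.call(population_spec, c(x[setdiff(names(x), "hh")],
                             list(hh = x$hh)))
}
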