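#' Network configuration
#'
#' Describes a fully connected recurrent network: which neurons receive the
#' two-channel external signal, which two are read out as the response, and
#' the steepness of the odd activation function. All remaining neurons are
#' associative (hidden); their count `K` drives the functional-symmetry
#' cluster formula `2^K * K!`.
#'
#' @param n_total total neuron count (>= 4: two input and two output neurons
#'   are always present).
#' @param input_ids ordered indices of the two neurons receiving the external
#'   signal channels.
#' @param output_ids ordered indices of the two neurons read as the response.
#' @param steepness_a positive steepness of the activation `tanh(a * rho)`.
#' @return an object of class `nnmo_config`.
#' @export
network_config <- function(n_total, input_ids = c(1L, 2L),
                           output_ids = c(3L, 4L), steepness_a = 1) {
  n_total <- as.integer(n_total)
  input_ids <- as.integer(input_ids)
  output_ids <- as.integer(output_ids)
  stopifnot(n_total >= 4L, length(input_ids) == 2L, length(output_ids) == 2L,
            steepness_a > 0)
  ids <- c(input_ids, output_ids)
  if (anyDuplicated(ids) || any(ids < 1L) || any(ids > n_total))
    stop("input_ids and output_ids must be distinct indices in 1..n_total")
  hidden_ids <- setdiff(seq_len(n_total), ids)
  structure(list(n_total = n_total, input_ids = input_ids,
                 output_ids = output_ids, hidden_ids = hidden_ids,
                 steepness_a = as.numeric(steepness_a)),
            class = "nnmo_config")
}

#' @export
print.nnmo_config <- function(x, ...) {
  cat("<nnmo_config> ", x$n_total, " neurons: input ",
      paste(x$input_ids, collapse = ","), "; output ",
      paste(x$output_ids, collapse = ","), "; hidden ",
      if (length(x$hidden_ids)) paste(x$hidden_ids, collapse = ",") else "-",
      "; a = ", x$steepness_a, "\n", sep = "")
  invisible(x)
}

#' Weight matrix (the heritable structure)
#'
#' `x[i, j]` is the synapse from neuron `j` to neuron `i` (receiver-row
#' convention). `frozen` marks synapses pinned to exactly zero; the
#' complexity-reduction procedure grows this mask and every evolutionary
#' operator respects it.
#'
#' @param x square numeric matrix of synapse weights.
#' @param frozen logical matrix of the same shape; `TRUE` entries must hold
#'   weight exactly 0. Defaults to an all-`FALSE` mask.
#' @return an object of class `nnmo_weights` (a list with elements `x`,
#'   `frozen`).
#' @export
weight_matrix <- function(x, frozen = NULL) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) == ncol(x))
  if (is.null(frozen))
    frozen <- matrix(FALSE, nrow(x), ncol(x))
  frozen <- matrix(as.logical(frozen), nrow(x), ncol(x))
  if (any(x[frozen] != 0))
    stop("frozen synapses must be exactly zero")
  structure(list(x = unname(x), frozen = unname(frozen)),
            class = "nnmo_weights")
}

#' @export
print.nnmo_weights <- function(x, ...) {
  cat("<nnmo_weights> ", nrow(x$x), "x", ncol(x$x), ", ",
      sum(x$x != 0), " non-zero, ", sum(x$frozen), " frozen\n", sep = "")
  invisible(x)
}

#' Count of non-zero synapses
#'
#' The functional-complexity measure of a structure.
#'
#' @param w an `nnmo_weights` object.
#' @return integer count of non-zero entries.
#' @export
n_synapses <- function(w) {
  sum(w$x != 0)
}

#' Odd sigmoid activation
#'
#' `f(rho) = tanh(a * rho)`: odd, strictly increasing, range (-1, 1). The
#' oddness is essential — it is what makes sign-change transforms of hidden
#' neurons functionally invariant.
#'
#' @param rho weighted input sum (vectorised).
#' @param steepness_a positive steepness coefficient.
#' @return activation value(s) in (-1, 1).
#' @export
activation <- function(rho, steepness_a = 1) {
  stopifnot(steepness_a > 0)
  tanh(steepness_a * rho)
}

#' One synchronous update tick
#'
#' Computes `rho_i = sum_j x[i,j] alpha_j + A_i` from the previous state and
#' applies the activation; `A_i` is the external signal component at the two
#' input neurons and 0 elsewhere. All neurons update from the previous state
#' simultaneously.
#'
#' @param weights an `nnmo_weights` object.
#' @param state numeric state vector (previous activations `alpha`).
#' @param external length-2 numeric vector, the signal code at this tick.
#' @param config an `nnmo_config`.
#' @return the new state vector.
#' @export
nn_step <- function(weights, state, external, config) {
  n <- config$n_total
  if (nrow(weights$x) != n || length(state) != n)
    stop("dimension mismatch between weights, state and config")
  stopifnot(length(external) == 2L)
  drive <- numeric(n)
  drive[config$input_ids] <- external
  rho <- as.vector(weights$x %*% state) + drive
  activation(rho, config$steepness_a)
}

#' Run a network over an event stream
#'
#' Drives the network tick-by-tick through the stream's input sequence from
#' the given initial state (all zeros by default) and records the two output
#' neurons' activations at every tick.
#'
#' @param weights an `nnmo_weights` object.
#' @param stream an `nnmo_stream` (see [generate_stream()]).
#' @param config an `nnmo_config`.
#' @param initial optional initial state vector; default all zeros.
#' @return a numeric matrix with one row per tick and two columns
#'   (`out1`, `out2`) — the output trace.
#' @export
run_stream <- function(weights, stream, config, initial = NULL) {
  n <- config$n_total
  if (nrow(weights$x) != n)
    stop("weight matrix does not match config")
  if (is.null(initial)) initial <- numeric(n)
  stopifnot(length(initial) == n)
  trace <- cpp_run_stream(weights$x, config$input_ids, config$output_ids,
                          config$steepness_a, stream$inputs, initial)
  colnames(trace) <- c("out1", "out2")
  trace
}

#' Goal (loss) function of a trace
#'
#' The evolutionary fitness surrogate: the sum over ticks and over the two
#' output neurons of the squared difference between the output and the
#' required response (0 or 1). Lower is fitter; 0 only for an exact match.
#'
#' @param trace output trace from [run_stream()].
#' @param stream the stream the trace was produced on.
#' @return a non-negative scalar.
#' @export
goal_function <- function(trace, stream) {
  if (nrow(trace) != nrow(stream$targets))
    stop("trace and stream target lengths differ")
  sum((trace - stream$targets)^2)
}

#' Stimulus-recognition error count
#'
#' A tick is erroneous when thresholding either output (`alpha > threshold`)
#' disagrees with its binary target. Training stops only at zero errors on a
#' fresh validation stream.
#'
#' @param trace output trace from [run_stream()].
#' @param stream the stream the trace was produced on.
#' @param threshold classification threshold in (0, 1).
#' @return integer number of erroneous ticks.
#' @export
recognition_errors <- function(trace, stream, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (nrow(trace) != nrow(stream$targets))
    stop("trace and stream target lengths differ")
  pred <- trace > threshold
  want <- stream$targets > 0.5
  sum(pred[, 1] != want[, 1] | pred[, 2] != want[, 2])
}

#' Goal and error count in one pass
#'
#' Convenience wrapper used throughout the trainer: evaluates a weight matrix
#' on a stream (from the all-zero state) and returns the goal value and
#' recognition-error count without materialising the trace in R.
#'
#' @inheritParams run_stream
#' @param threshold classification threshold.
#' @return named numeric vector `c(goal = , errors = )`.
#' @export
evaluate_network <- function(weights, stream, config, threshold = 0.5) {
  v <- cpp_eval_stream(weights$x, config$input_ids, config$output_ids,
                       config$steepness_a, stream$inputs, stream$targets,
                       threshold)
  c(goal = v[1], errors = v[2])
}
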