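#' Remove the smallest-magnitude synapse
#'
#' Sets the non-frozen synapse of smallest absolute value to exactly zero and
#' freezes it; ties are broken by the lowest flat (row-major) index. One
#' stage of the complexity-reduction procedure.
#'
#' @param w an `nnmo_weights` with at least one non-frozen synapse.
#' @return list: `weights` (pruned, mask grown by one) and `index` (flat
#'   row-major index of the removed synapse).
#' @export
prune_smallest <- function(w) {
  n <- nrow(w$x)
  v <- flatten_weights(w)                       # row-major
  free <- !as.vector(t(w$frozen))
  if (!any(free)) stop("no non-frozen synapse left to prune")
  cand <- which(free)
  idx <- cand[which.min(abs(v[cand]))]          # which.min: lowest index on ties
  i <- (idx - 1) %/% n + 1
  j <- (idx - 1) %% n + 1
  x <- w$x; fr <- w$frozen
  x[i, j] <- 0; fr[i, j] <- TRUE
  list(weights = weight_matrix(x, fr), index = idx)
}

#' Complexity reduction by iterative pruning and retraining
#'
#' Starting from a trained (zero-error) structure, repeatedly removes the
#' smallest-magnitude synapse and retrains the network — warm-started from
#' the pruned weights, under the grown frozen mask — back to the full
#' training criterion. Each stage allows several retraining restarts (fresh
#' seeds, same pruned start); the procedure stops at the first stage where
#' all restarts fail, and returns the last structure that still performed
#' the function without errors. The final non-zero synapse count estimates
#' the functional complexity of the task; the total synapse count of the
#' configuration is its potential complexity.
#'
#' @param w trained `nnmo_weights` (zero recognition errors).
#' @param config an `nnmo_config`.
#' @param task an `nnmo_task`.
#' @param cfg an `nnmo_train_config` used for retraining.
#' @param retrain_budget generation budget per retraining attempt.
#' @param restarts retraining attempts per stage.
#' @param base_seed master seed for the per-attempt seed derivation.
#' @return list: `weights` (the minimal functional structure), `history`
#'   (data.frame: stage, removed flat index, success, generations used,
#'   non-zero count after the stage), and `report` (list with
#'   `functional_complexity`, `potential_complexity`, `redundancy`).
#' @export
reduce_network <- function(w, config, task, cfg = train_config(),
                           retrain_budget = 2L * cfg$max_generations,
                           restarts = 5L, base_seed = 1L) {
  current <- w
  history <- data.frame(stage = integer(), removed_index = integer(),
                        success = logical(), generations = integer(),
                        nonzero_after = integer())
  stage <- 0L
  attempt_id <- 0L
  repeat {
    if (!any(!as.vector(current$frozen))) break
    stage <- stage + 1L
    pr <- prune_smallest(current)
    retrain_cfg <- cfg
    retrain_cfg$max_generations <- as.integer(retrain_budget)
    ok <- NULL
    gens <- 0L
    for (r in seq_len(restarts)) {
      attempt_id <- attempt_id + 1L
      retrain_cfg$mutation_seed <- .derive_seed(base_seed, "mutation", attempt_id)
      retrain_cfg$stream_seed <- .derive_seed(base_seed, "stream", attempt_id)
      res <- evolve(config, task, retrain_cfg, init = pr$weights)
      gens <- gens + res$generations
      if (res$success) { ok <- res$weights; break }
    }
    succ <- !is.null(ok)
    history <- rbind(history, data.frame(
      stage = stage, removed_index = pr$index, success = succ,
      generations = gens,
      nonzero_after = if (succ) n_synapses(ok) else n_synapses(current)))
    if (!succ) break
    current <- ok
  }
  potential <- config$n_total^2
  functional <- n_synapses(current)
  list(weights = current, history = history,
       report = list(functional_complexity = functional,
                     potential_complexity = potential,
                     redundancy = potential - functional))
}

#' Compact a reduced structure into a smaller configuration
#'
#' Hidden neurons whose weight-matrix row and column are entirely zero take
#' no part in the dynamics; deleting those rows and columns (and relabelling
#' the survivors) yields a smaller network with an identical output trace on
#' every stream. Input and output neurons are never removed.
#'
#' @param w an `nnmo_weights` (typically a reduced structure).
#' @param config the owning `nnmo_config`.
#' @return list: `weights`, `config` of the compacted network, and `kept`,
#'   the original indices of the surviving neurons.
#' @export
compact_network <- function(w, config) {
  n <- config$n_total
  dead <- vapply(config$hidden_ids, function(i)
    all(w$x[i, ] == 0) && all(w$x[, i] == 0), logical(1))
  drop_ids <- config$hidden_ids[dead]
  if (!length(drop_ids))
    return(list(weights = w, config = config, kept = seq_len(n)))
  kept <- setdiff(seq_len(n), drop_ids)
  remap <- match(seq_len(n), kept)              # old id -> new id
  new_config <- network_config(length(kept),
                               input_ids = remap[config$input_ids],
                               output_ids = remap[config$output_ids],
                               steepness_a = config$steepness_a)
  list(weights = weight_matrix(w$x[kept, kept, drop = FALSE],
                               w$frozen[kept, kept, drop = FALSE]),
       config = new_config, kept = kept)
}

#' Randomised-synapse negative control
#'
#' Tests whether a reduced structure's topology alone suffices for learning:
#' the surviving non-zero synapses are replaced by random values (magnitudes
#' uniform over the surviving weights' magnitude range, signs preserved or
#' random) and the network is retrained under the same frozen mask and
#' budget. For genuinely minimal structures learning does not occur — the
#' pruned degrees of freedom that let evolution route around fitness-landscape
#' obstacles are gone.
#'
#' @param w_reduced reduced `nnmo_weights` (frozen mask from a completed
#'   reduction).
#' @param config an `nnmo_config`.
#' @param task an `nnmo_task`.
#' @param cfg an `nnmo_train_config` (its `max_generations` is the attempt
#'   budget).
#' @param n_attempts number of randomise-and-retrain attempts.
#' @param preserve_sign keep each surviving synapse's sign.
#' @param base_seed master seed.
#' @return list: `successes`, `n_attempts`, `success_rate`, and `attempts`, a
#'   data.frame with per-attempt success flags and final goal values.
#' @export
randomize_control <- function(w_reduced, config, task, cfg = train_config(),
                              n_attempts = 10L, preserve_sign = TRUE,
                              base_seed = 1L) {
  nz <- which(t(w_reduced$x) != 0)              # flat row-major indices
  stopifnot(length(nz) > 0)
  mags <- abs(flatten_weights(w_reduced)[nz])
  lo <- min(mags); hi <- max(mags)
  n <- nrow(w_reduced$x)
  attempts <- data.frame(attempt = seq_len(n_attempts), success = FALSE,
                         final_goal = NA_real_, final_errors = NA_integer_,
                         generations = NA_integer_)
  for (k in seq_len(n_attempts)) {
    set.seed(.derive_seed(base_seed, "control", k) %% .Machine$integer.max)
    mag <- stats::runif(length(nz), lo, hi)
    sgn <- if (preserve_sign) sign(flatten_weights(w_reduced)[nz]) else
      sample(c(-1, 1), length(nz), replace = TRUE)
    v <- numeric(n * n)
    v[nz] <- sgn * mag
    x <- matrix(v, n, n, byrow = TRUE)
    w0 <- weight_matrix(x, w_reduced$frozen)
    run_cfg <- cfg
    run_cfg$mutation_seed <- .derive_seed(base_seed, "mutation", k)
    run_cfg$stream_seed <- .derive_seed(base_seed, "stream", k)
    res <- evolve(config, task, run_cfg, init = w0)
    attempts$success[k] <- res$success
    attempts$final_goal[k] <- utils::tail(res$trajectory$goal, 1)
    attempts$final_errors[k] <- utils::tail(res$trajectory$errors, 1)
    attempts$generations[k] <- res$generations
  }
  list(successes = sum(attempts$success), n_attempts = n_attempts,
       success_rate = mean(attempts$success), attempts = attempts)
}

#' Search for the minimal trainable network size
#'
#' For each candidate total neuron count (always 2 input + 2 output, the rest
#' hidden), runs several independent evolutions from random starts and
#' reports how many reached error-free performance, plus the smallest size
#' with at least one success.
#'
#' @param task an `nnmo_task`.
#' @param sizes integer vector of total neuron counts (each >= 4).
#' @param cfg an `nnmo_train_config`.
#' @param restarts independent runs per size.
#' @param base_seed master seed.
#' @return list: `table`, a data.frame (`size`, `restarts`, `successes`), and
#'   `min_size`, the smallest size with a success (`NA` if none).
#' @export
min_network_search <- function(task, sizes, cfg = train_config(),
                               restarts = 10L, base_seed = 1L) {
  stopifnot(all(sizes >= 4L))
  restarts <- as.integer(restarts)
  rows <- lapply(sizes, function(sz) {
    config <- network_config(sz)
    results <- train_ensemble(restarts, config, task, cfg,
                              base_seed = base_seed + 10000L * sz)
    data.frame(size = sz, restarts = restarts,
               successes = sum(vapply(results, `[[`, logical(1), "success")))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$size[tab$successes > 0]
  list(table = tab, min_size = if (length(ok)) min(ok) else NA_integer_)
}
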