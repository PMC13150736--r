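#' Training (evolution) configuration
#'
#' Parameters of the mirrored random-search algorithm. Each generation, one
#' increment matrix is drawn and added to every non-frozen synapse with both
#' signs, giving two offspring; parent and offspring are evaluated on one
#' common 100-symbol stream fragment and the fittest (minimum goal) survives.
#' Training ends when the survivor makes zero recognition errors and its goal
#' is at most `epsilon_per_tick * n_ticks`, confirmed on
#' `validation_fragments` independent fresh fragments.
#'
#' @param mutation_scale half-width of the uniform synapse increment
#'   distribution (default 0.05).
#' @param stream an `nnmo_stream_config` for the training fragments (default
#'   100 symbols).
#' @param epsilon_per_tick per-tick goal tolerance used in the stopping
#'   criterion (default 0.25^2: each output within 0.25 of its target on
#'   average).
#' @param max_generations generation budget.
#' @param init_scale half-width of the uniform initial-weight distribution
#'   ("modulo close to 0"; default 0.01).
#' @param regenerate_stream if `TRUE` (default) a fresh quasi-random fragment
#'   is generated each generation — the non-reproducible flow of events; if
#'   `FALSE`, one fixed fragment is reused, making the goal trajectory
#'   monotone non-increasing.
#' @param threshold recognition threshold for error counting.
#' @param snapshot_stride record a full weight snapshot every this many
#'   generations (0 = none).
#' @param validation_fragments number of independent fresh fragments (with
#'   early exit at the first error) that must all be error-free before
#'   success is declared (default 100, i.e. 10000 symbols). Error-free
#'   functioning must be a robust property of the network, not luck on one
#'   fragment: validation is attempted every time the training fragment is
#'   clean, so a marginal network with a small residual error rate would
#'   eventually pass any short validation by chance.
#' @param mutation_seed,stream_seed seeds of the two independent random
#'   streams (mutations vs environment), so the two sources of trajectory
#'   divergence can be controlled separately.
#' @return an object of class `nnmo_train_config`.
#' @export
train_config <- function(mutation_scale = 0.05, stream = stream_config(),
                         epsilon_per_tick = 0.0625,
                         max_generations = 20000L, init_scale = 0.01,
                         regenerate_stream = TRUE, threshold = 0.5,
                         snapshot_stride = 0L, validation_fragments = 100L,
                         mutation_seed = 1L, stream_seed = 2L) {
  stopifnot(mutation_scale > 0, max_generations >= 1L, init_scale >= 0,
            epsilon_per_tick > 0, threshold > 0, threshold < 1,
            validation_fragments >= 1L)
  structure(list(mutation_scale = mutation_scale, stream = stream,
                 epsilon_per_tick = epsilon_per_tick,
                 max_generations = as.integer(max_generations),
                 init_scale = init_scale,
                 regenerate_stream = isTRUE(regenerate_stream),
                 threshold = threshold,
                 snapshot_stride = as.integer(snapshot_stride),
                 validation_fragments = as.integer(validation_fragments),
                 mutation_seed = as.numeric(mutation_seed),
                 stream_seed = as.numeric(stream_seed)),
            class = "nnmo_train_config")
}

#' Random initial weights
#'
#' Entries i.i.d. uniform on `[-init_scale, init_scale]` — a starting point
#' "modulo close to 0" in structure space. Uses R's global RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param config an `nnmo_config`.
#' @param init_scale half-width of the uniform support.
#' @return an `nnmo_weights` with an all-`FALSE` frozen mask.
#' @export
init_weights <- function(config, init_scale = 0.01) {
  n <- config$n_total
  x <- matrix(stats::runif(n * n, -init_scale, init_scale), n, n)
  weight_matrix(x)
}

#' Mirrored mutation pair
#'
#' Draws one increment matrix `Delta` (i.i.d. uniform on
#' `[-scale, scale]`, exactly zero on frozen synapses) and returns the two
#' offspring `w + Delta` and `w - Delta`: the same modulo increments with
#' opposite signs, so `(w_plus + w_minus) / 2` recovers `w` (exactly in
#' exact arithmetic; to machine rounding in doubles).
#'
#' @param w parent `nnmo_weights`.
#' @param scale increment half-width.
#' @param delta optional explicit increment matrix (for controlled
#'   experiments); drawn from R's RNG when `NULL`.
#' @return list with elements `plus`, `minus` (both `nnmo_weights`) and
#'   `delta`.
#' @export
mutate_pair <- function(w, scale = 0.05, delta = NULL) {
  n <- nrow(w$x)
  if (is.null(delta))
    delta <- matrix(stats::runif(n * n, -scale, scale), n, n)
  delta[w$frozen] <- 0
  list(plus = weight_matrix(w$x + delta, w$frozen),
       minus = weight_matrix(w$x - delta, w$frozen),
       delta = delta)
}

#' One selection step of the random search
#'
#' Reference (plain-R) implementation of a single generation: mutate, run all
#' three networks on one common stream fragment, keep the minimum-goal
#' network. Ties are broken in favour of the parent, then the `+` offspring.
#'
#' @param parent parent `nnmo_weights`.
#' @param config an `nnmo_config`.
#' @param stream the common evaluation fragment (an `nnmo_stream`).
#' @param scale mutation scale.
#' @param delta optional explicit increment matrix.
#' @param threshold recognition threshold.
#' @return list: `weights` (the survivor), `goal`, `errors`,
#'   `which` (`"parent"`, `"plus"` or `"minus"`).
#' @export
select_step <- function(parent, config, stream, scale = 0.05, delta = NULL,
                        threshold = 0.5) {
  off <- mutate_pair(parent, scale, delta)
  ep <- evaluate_network(parent, stream, config, threshold)
  e1 <- evaluate_network(off$plus, stream, config, threshold)
  e2 <- evaluate_network(off$minus, stream, config, threshold)
  if (ep["goal"] <= e1["goal"] && ep["goal"] <= e2["goal"])
    list(weights = parent, goal = unname(ep["goal"]),
         errors = unname(ep["errors"]), which = "parent")
  else if (e1["goal"] <= e2["goal"])
    list(weights = off$plus, goal = unname(e1["goal"]),
         errors = unname(e1["errors"]), which = "plus")
  else
    list(weights = off$minus, goal = unname(e2["goal"]),
         errors = unname(e2["errors"]), which = "minus")
}

.as_train_result <- function(raw, w, config, task, cfg) {
  snaps <- raw$snapshots
  traj <- data.frame(generation = seq_along(raw$goal) - 1L,
                     goal = raw$goal, errors = raw$errors)
  structure(list(
    weights = weight_matrix(raw$x, w$frozen),
    config = config, task = task, train_config = cfg,
    generations = raw$generations, success = raw$success,
    trajectory = traj,
    snapshot_generations = raw$snapshot_generations,
    snapshots = snaps), class = "nnmo_train_result")
}

#' @export
print.nnmo_train_result <- function(x, ...) {
  cat("<nnmo_train_result> task ", x$task$name, ": ",
      if (x$success) "success" else "no convergence", " after ",
      x$generations, " generations; final goal ",
      signif(utils::tail(x$trajectory$goal, 1), 4), ", ",
      utils::tail(x$trajectory$errors, 1), " errors\n", sep = "")
  invisible(x)
}

#' Evolve a network by mirrored random search
#'
#' Iterates the mutate/evaluate/select generation from a random initial
#' structure (or a supplied warm start) until the stopping criterion — zero
#' recognition errors and goal below tolerance on the training fragment,
#' confirmed on a batch of fresh validation fragments — or until
#' `max_generations`.
#' Frozen synapses stay exactly zero throughout. Fully deterministic given
#' the seeds in `cfg`.
#'
#' @param config an `nnmo_config`.
#' @param task an `nnmo_task`.
#' @param cfg an `nnmo_train_config`.
#' @param init optional starting `nnmo_weights` (e.g. a pruned structure);
#'   when `NULL`, drawn by [init_weights()] from R's RNG.
#' @param stop_on_success set `FALSE` to run the full generation budget
#'   regardless (used by trajectory-divergence experiments so that all
#'   replicates have snapshots at the same generations).
#' @return an `nnmo_train_result`: final `weights`, `generations` used,
#'   `success` flag, per-generation `trajectory` (goal, errors), and weight
#'   `snapshots` if requested.
#' @export
evolve <- function(config, task, cfg = train_config(), init = NULL,
                   stop_on_success = TRUE) {
  if (is.null(init)) init <- init_weights(config, cfg$init_scale)
  stopifnot(nrow(init$x) == config$n_total)
  fixed_in <- NULL; fixed_tg <- NULL
  if (!cfg$regenerate_stream) {
    fixed <- generate_stream(task, cfg$stream)
    fixed_in <- fixed$inputs; fixed_tg <- fixed$targets
  }
  correct <- match(task$correct_signal, .sym_names) - 1L
  raw <- cpp_evolve(init$x, init$frozen, config$input_ids, config$output_ids,
                    config$steepness_a, correct, task$window,
                    cfg$stream$length_symbols, cfg$stream$pause_min,
                    cfg$stream$pause_max, cfg$stream$stimulus_ticks,
                    fixed_in, fixed_tg,
                    cfg$mutation_scale, cfg$epsilon_per_tick, cfg$threshold,
                    cfg$max_generations, cfg$mutation_seed, cfg$stream_seed,
                    stop_on_success, cfg$snapshot_stride,
                    cfg$validation_fragments)
  .as_train_result(raw, init, config, task, cfg)
}

# Deterministic seed derivation: every stochastic component of a multi-run
# experiment draws its seed from the master seed plus a fixed component
# offset, keeping the three xoshiro streams (init / mutation / environment)
# disjoint across runs.  Offsets are < 2^22 apart so any master seed below
# 2^31 stays far below 2^53 (exactly representable as a double).
.derive_seed <- function(base_seed, component, run) {
  offset <- c(init = 1e6, mutation = 2e6, stream = 3e6, control = 4e6)[[component]]
  base_seed + offset + run
}

#' Evolve with restarts until success
#'
#' The full training protocol: if a run exhausts its generation budget
#' without reaching error-free performance, the algorithm is restarted from
#' a fresh random initial structure (new derived seeds), up to
#' `max_attempts` times.
#'
#' @inheritParams evolve
#' @param max_attempts restart budget.
#' @param base_seed master seed for the per-attempt seed derivation.
#' @return the first successful `nnmo_train_result` (with an `attempts`
#'   field), or the last failed one (`success = FALSE`) if all attempts
#'   fail.
#' @export
evolve_restarts <- function(config, task, cfg = train_config(),
                            max_attempts = 5L, base_seed = 1L) {
  res <- NULL
  for (a in seq_len(max_attempts)) {
    run_cfg <- cfg
    run_cfg$mutation_seed <- .derive_seed(base_seed, "mutation", a)
    run_cfg$stream_seed <- .derive_seed(base_seed, "stream", a)
    set.seed(.derive_seed(base_seed, "init", a) %% .Machine$integer.max)
    res <- evolve(config, task, run_cfg)
    res$attempts <- a
    if (res$success) break
  }
  res
}

#' Train an ensemble of independent NNMOs
#'
#' `n` independent runs of [evolve()] with distinct derived seeds and
#' independent random initial structures — the ensemble of evolutionary
#' outcomes whose geometry the symmetry module analyses.
#'
#' @param n ensemble size.
#' @param config an `nnmo_config`.
#' @param task an `nnmo_task`.
#' @param cfg an `nnmo_train_config` (its seeds are overridden per run).
#' @param base_seed master seed; per-run seeds are derived deterministically
#'   from it.
#' @return list of `nnmo_train_result`, with per-run seeds recorded in each
#'   result's `train_config`.
#' @export
train_ensemble <- function(n, config, task, cfg = train_config(),
                           base_seed = 1L) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    run_cfg <- cfg
    run_cfg$mutation_seed <- .derive_seed(base_seed, "mutation", i)
    run_cfg$stream_seed <- .derive_seed(base_seed, "stream", i)
    init <- local({
      set.seed(.derive_seed(base_seed, "init", i) %% .Machine$integer.max)
      init_weights(config, cfg$init_scale)
    })
    evolve(config, task, run_cfg, init = init)
  })
}

#' Divergence of evolutionary trajectories from a shared start
#'
#' Runs `n_replicates` evolutions from the same initial structure but with
#' distinct mutation and environment seeds (or identical seeds, as a
#' determinism control) for a fixed number of generations, and measures all
#' pairwise Euclidean distances between the replicate weight vectors at each
#' snapshot generation.
#'
#' @param start shared starting `nnmo_weights`.
#' @param config an `nnmo_config`.
#' @param task an `nnmo_task`.
#' @param cfg an `nnmo_train_config`; `snapshot_stride` must be positive.
#' @param n_replicates number of replicate trajectories (>= 2).
#' @param base_seed master seed for the per-replicate seed derivation.
#' @param identical_seeds if `TRUE`, all replicates share one seed pair (the
#'   distances must then stay exactly 0).
#' @return list with `distances` — a data.frame
#'   (`generation`, `i`, `j`, `distance`) of pairwise distances per snapshot
#'   generation — and `results`, the replicate `nnmo_train_result`s.
#' @export
trajectory_divergence <- function(start, config, task, cfg, n_replicates = 5L,
                                  base_seed = 1L, identical_seeds = FALSE) {
  stopifnot(n_replicates >= 2L, cfg$snapshot_stride >= 1L)
  results <- lapply(seq_len(n_replicates), function(i) {
    k <- if (identical_seeds) 1L else i
    run_cfg <- cfg
    run_cfg$mutation_seed <- .derive_seed(base_seed, "mutation", k)
    run_cfg$stream_seed <- .derive_seed(base_seed, "stream", k)
    evolve(config, task, run_cfg, init = start, stop_on_success = FALSE)
  })
  gens <- results[[1]]$snapshot_generations
  pairs <- utils::combn(n_replicates, 2)
  rows <- do.call(rbind, lapply(seq_along(gens), function(g) {
    data.frame(generation = gens[g], i = pairs[1, ], j = pairs[2, ],
               distance = apply(pairs, 2, function(p) {
                 sqrt(sum((results[[p[1]]]$snapshots[g, ] -
                           results[[p[2]]]$snapshots[g, ])^2))
               }))
  }))
  list(distances = rows, results = results)
}
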