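#' Save / load a weight matrix with its configuration
#'
#' The matrix is written as tab-separated text (one row per line, full
#' precision, `%.17g`), with a JSON sidecar `<path>.json` recording the
#' network configuration and the frozen mask (row-major 0/1 string). The
#' round trip is exact.
#'
#' @param w an `nnmo_weights`.
#' @param config an `nnmo_config`.
#' @param path file path for the matrix; the sidecar is `<path>.json`.
#' @return `save_weights` returns `path` invisibly; `load_weights` returns
#'   `list(weights, config)`.
#' @export
save_weights <- function(w, config, path) {
  stopifnot(nrow(w$x) == config$n_total)
  lines <- apply(w$x, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(lines, path)
  sidecar <- list(n_total = config$n_total, input_ids = config$input_ids,
                  output_ids = config$output_ids,
                  steepness_a = config$steepness_a,
                  frozen = paste(as.integer(t(w$frozen)), collapse = ""))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  lines <- readLines(path)
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], "\t")[[1]]))
    if (anyNA(v)) stop("malformed weight file ", path, " at line ", i)
    v
  })
  n <- length(rows)
  if (any(lengths(rows) != n))
    stop("malformed weight file ", path, ": expected ", n,
         " columns in each of ", n, " rows")
  x <- do.call(rbind, rows)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  config <- network_config(side$n_total, side$input_ids, side$output_ids,
                           side$steepness_a)
  mask <- as.integer(strsplit(side$frozen, "")[[1]]) == 1L
  frozen <- matrix(mask, n, n, byrow = TRUE)
  list(weights = weight_matrix(x, frozen), config = config)
}

#' Experiment configuration
#'
#' Bundles everything a scripted experiment needs; every stochastic
#' component derives its seed deterministically from `master_seed` plus a
#' fixed component offset, so a configuration reproduces its outputs
#' bit-for-bit.
#'
#' @param experiment one of `"train"`, `"ensemble"`, `"diverge"`,
#'   `"reduce"`, `"min-size"`, `"symmetry-analyze"`.
#' @param task task name (`"A3"`, `"C4"`, ...).
#' @param n_total network size.
#' @param n_runs ensemble size / replicate count / restarts, depending on
#'   the experiment.
#' @param train an `nnmo_train_config`.
#' @param master_seed master seed.
#' @param out_dir output directory (created if missing).
#' @param sizes candidate sizes for `"min-size"`.
#' @param retrain_budget,restarts reduction-stage parameters for `"reduce"`.
#' @param compact for `"reduce"`: also emit each reduced structure compacted
#'   into its minimal configuration (dead hidden neurons deleted).
#' @return an object of class `nnmo_experiment_config`.
#' @export
experiment_config <- function(experiment, task = "A3", n_total = 6L,
                              n_runs = 8L, train = train_config(),
                              master_seed = 1L, out_dir = tempfile("nnmo_"),
                              sizes = c(5L, 6L),
                              retrain_budget = 2L * train$max_generations,
                              restarts = 5L, compact = FALSE) {
  experiment <- match.arg(experiment, c("train", "ensemble", "diverge",
                                        "reduce", "min-size",
                                        "symmetry-analyze"))
  structure(list(experiment = experiment, task = task,
                 n_total = as.integer(n_total), n_runs = as.integer(n_runs),
                 train = train, master_seed = as.numeric(master_seed),
                 out_dir = out_dir, sizes = as.integer(sizes),
                 retrain_budget = as.integer(retrain_budget),
                 restarts = as.integer(restarts),
                 compact = isTRUE(compact)),
            class = "nnmo_experiment_config")
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run a scripted experiment end-to-end
#'
#' Executes the named experiment — ensemble training, trajectory divergence,
#' complexity reduction, minimal-size search, or symmetry analysis of a
#' saved ensemble — writing all tables and weight files into the output
#' directory together with a JSON manifest (configuration snapshot, per-run
#' seeds, produced files). Re-running the same configuration reproduces the
#' numeric outputs exactly.
#'
#' @param config an `nnmo_experiment_config`.
#' @param ensemble_dir for `"symmetry-analyze"` and `"reduce"`: directory of
#'   previously saved weight files (defaults to `config$out_dir`).
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_experiment <- function(config, ensemble_dir = config$out_dir) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  task <- task_spec(config$task)
  net <- network_config(config$n_total)
  files <- character()
  emit <- function(path) files[[length(files) + 1L]] <<- path
  seed <- config$master_seed

  if (config$experiment %in% c("train", "ensemble")) {
    n <- if (config$experiment == "train") 1L else config$n_runs
    results <- train_ensemble(n, net, task, config$train, base_seed = seed)
    for (i in seq_len(n)) {
      p <- file.path(config$out_dir, sprintf("weights_%03d.tsv", i))
      save_weights(results[[i]]$weights, net, p)
      emit(p); emit(paste0(p, ".json"))
      emit(.write_csv(results[[i]]$trajectory,
                      file.path(config$out_dir,
                                sprintf("trajectory_%03d.csv", i))))
    }
    summary <- data.frame(
      run = seq_len(n),
      success = vapply(results, `[[`, logical(1), "success"),
      generations = vapply(results, `[[`, integer(1), "generations"),
      final_goal = vapply(results, function(r)
        utils::tail(r$trajectory$goal, 1), numeric(1)))
    emit(.write_csv(summary, file.path(config$out_dir, "runs.csv")))
    ok <- results[vapply(results, `[[`, logical(1), "success")]
    if (length(ok) >= 2L) {
      geom <- pairwise_distances(lapply(ok, `[[`, "weights"))
      emit(.write_csv(data.frame(distance = as.vector(geom$distances)),
                      file.path(config$out_dir, "distances.csv")))
    }
  } else if (config$experiment == "diverge") {
    set.seed(.derive_seed(seed, "init", 0L) %% .Machine$integer.max)
    start <- init_weights(net, config$train$init_scale)
    cfg <- config$train
    if (cfg$snapshot_stride < 1L) cfg$snapshot_stride <- 10L
    div <- trajectory_divergence(start, net, task, cfg,
                                 n_replicates = config$n_runs,
                                 base_seed = seed)
    emit(.write_csv(div$distances, file.path(config$out_dir, "divergence.csv")))
  } else if (config$experiment == "reduce") {
    wfiles <- list.files(ensemble_dir, pattern = "^weights_.*\\.tsv$",
                         full.names = TRUE)
    if (!length(wfiles)) stop("no weight files found in ", ensemble_dir)
    hist_all <- list()
    for (i in seq_along(wfiles)) {
      loaded <- load_weights(wfiles[i])
      red <- reduce_network(loaded$weights, loaded$config, task, config$train,
                            retrain_budget = config$retrain_budget,
                            restarts = config$restarts,
                            base_seed = seed + i)
      p <- file.path(config$out_dir, sprintf("reduced_%03d.tsv", i))
      save_weights(red$weights, loaded$config, p)
      emit(p); emit(paste0(p, ".json"))
      if (config$compact) {
        cp <- compact_network(red$weights, loaded$config)
        pc <- file.path(config$out_dir, sprintf("compacted_%03d.tsv", i))
        save_weights(cp$weights, cp$config, pc)
        emit(pc); emit(paste0(pc, ".json"))
      }
      hist_all[[i]] <- cbind(replicate = i, red$history)
    }
    emit(.write_csv(do.call(rbind, hist_all),
                    file.path(config$out_dir, "reduction_history.csv")))
    counts <- vapply(seq_along(wfiles), function(i) {
      min(hist_all[[i]]$nonzero_after)
    }, numeric(1))
    report <- data.frame(replicate = seq_along(wfiles),
                         functional_complexity = counts,
                         potential_complexity = config$n_total^2)
    emit(.write_csv(report, file.path(config$out_dir, "complexity.csv")))
  } else if (config$experiment == "min-size") {
    res <- min_network_search(task, config$sizes, config$train,
                              restarts = config$n_runs, base_seed = seed)
    emit(.write_csv(res$table, file.path(config$out_dir, "min_size.csv")))
  } else if (config$experiment == "symmetry-analyze") {
    wfiles <- list.files(ensemble_dir, pattern = "^weights_.*\\.tsv$",
                         full.names = TRUE)
    if (length(wfiles) < 2L) stop("need >= 2 weight files in ", ensemble_dir)
    members <- lapply(wfiles, function(f) load_weights(f)$weights)
    geom <- pairwise_distances(members)
    emit(.write_csv(data.frame(distance = as.vector(geom$distances)),
                    file.path(config$out_dir, "distances.csv")))
    cl <- cluster_count(geom)
    emit(.write_csv(data.frame(member = basename(wfiles), cluster = cl$labels),
                    file.path(config$out_dir, "clusters.csv")))
    proj <- project3d(geom, c(25L, 26L, 31L))
    emit(.write_csv(proj, file.path(config$out_dir, "projection_25_26_31.csv")))
    mod <- distance_modality(geom)
    writeLines(c(sprintf("n_members: %d", length(members)),
                 sprintf("n_clusters: %d", cl$n_clusters),
                 sprintf("cluster_sizes: %s", paste(cl$sizes, collapse = " ")),
                 sprintf("n_modes: %d", mod$n_modes),
                 sprintf("multimodal: %s", mod$multimodal)),
               file.path(config$out_dir, "modality.txt"))
    emit(file.path(config$out_dir, "modality.txt"))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("nnmo")),
                   config = unclass(config)[setdiff(names(unclass(config)),
                                                    c("train"))],
                   train = unclass(config$train)[
                     setdiff(names(unclass(config$train)), "stream")],
                   stream = unclass(config$train$stream),
                   files = basename(unlist(files)),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
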