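#' @importFrom stats dist hclust cutree density median
#' @importFrom utils write.table read.table
#' @useDynLib nnmo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Signal alphabet: two-channel binary codes per symbol.
.signal_codes <- rbind(PAUSE = c(0, 0), A = c(1, 0), B = c(0, 1), C = c(1, 1))

#' Signal code lookup
#'
#' The discrete signal alphabet: pause = (0,0), A = (1,0), B = (0,1),
#' C = (1,1); the two components are the levels applied to the two input
#' neurons.
#'
#' @param name one of `"PAUSE"`, `"A"`, `"B"`, `"C"`.
#' @return length-2 numeric code.
#' @export
signal_code <- function(name) {
  name <- match.arg(toupper(name), rownames(.signal_codes))
  unname(.signal_codes[name, ])
}

#' Recognition task definition
#'
#' A task is named by the "correct" stimulus and the number of processing
#' ticks the network is given to raise its response: `A3` means "respond
#' (1,1) within a 3-tick window after stimulus A, (0,0) otherwise"; `C4`
#' likewise with stimulus C and a 4-tick window.
#'
#' @param correct_signal `"A"`, `"B"` or `"C"`; alternatively a compact name
#'   such as `"A3"` or `"C4"` (then `window` is taken from the name).
#' @param window processing window in ticks, 3 or 4.
#' @return an object of class `nnmo_task` with fields `correct_signal`,
#'   `window`, `name`.
#' @export
task_spec <- function(correct_signal, window = NULL) {
  if (is.null(window) && nchar(correct_signal) == 2L) {
    window <- as.integer(substr(correct_signal, 2, 2))
    correct_signal <- substr(correct_signal, 1, 1)
  }
  correct_signal <- match.arg(toupper(correct_signal), c("A", "B", "C"))
  window <- as.integer(window)
  stopifnot(window %in% c(3L, 4L))
  structure(list(correct_signal = correct_signal, window = window,
                 name = paste0(correct_signal, window)),
            class = "nnmo_task")
}

#' Stream generator configuration
#'
#' @param length_symbols number of stimulus symbols per stream fragment
#'   (default 100, the fragment length used for each fitness evaluation).
#' @param pause_min,pause_max bounds (ticks) of the uniformly drawn extra
#'   pause separating symbols; the response window itself always elapses
#'   before the next symbol, so windows never overlap.
#' @param stimulus_ticks duration of a stimulus presentation (default 1).
#' @param rng_seed non-negative integer seed for the stream generator.
#' @return an object of class `nnmo_stream_config`.
#' @export
stream_config <- function(length_symbols = 100L, pause_min = 1L,
                          pause_max = 4L, stimulus_ticks = 1L,
                          rng_seed = 1L) {
  stopifnot(length_symbols >= 1L, pause_min >= 1L, pause_max >= pause_min,
            stimulus_ticks >= 1L, rng_seed >= 0)
  structure(list(length_symbols = as.integer(length_symbols),
                 pause_min = as.integer(pause_min),
                 pause_max = as.integer(pause_max),
                 stimulus_ticks = as.integer(stimulus_ticks),
                 rng_seed = as.numeric(rng_seed)),
            class = "nnmo_stream_config")
}

.sym_names <- c("A", "B", "C")

.new_stream <- function(inputs, targets, annotations, task, cfg = NULL) {
  colnames(inputs) <- c("in1", "in2")
  colnames(targets) <- c("tgt1", "tgt2")
  structure(list(inputs = inputs, targets = targets,
                 annotations = annotations, task = task, cfg = cfg),
            class = "nnmo_stream")
}

#' Generate a quasi-random event stream
#'
#' Draws `length_symbols` stimuli uniformly from \{A, B, C\}. Each symbol
#' occupies `stimulus_ticks` ticks of its signal code, followed by the
#' task's `window` silent processing ticks and an extra pause of
#' `p ~ U\{pause_min..pause_max\}` silent ticks; a leading pause precedes the
#' first symbol. The required response at every tick is the classification
#' of the most recent stimulus whose processing window has elapsed: (1,1) if
#' it was the correct signal, (0,0) otherwise — so the network has `window`
#' ticks to process each stimulus and must then hold its answer until the
#' next stimulus is classified in turn. Deterministic given `cfg$rng_seed`.
#'
#' @param task an `nnmo_task`.
#' @param cfg an `nnmo_stream_config`.
#' @return an `nnmo_stream`: list with tick matrices `inputs`, `targets`
#'   (one row per tick), per-symbol `annotations`
#'   (`signal`, `onset`, `window`, `pause`), and the `task`/`cfg` used.
#' @export
generate_stream <- function(task, cfg = stream_config()) {
  stopifnot(inherits(task, "nnmo_task"), inherits(cfg, "nnmo_stream_config"))
  correct <- match(task$correct_signal, .sym_names) - 1L
  raw <- cpp_generate_stream(correct, task$window, cfg$length_symbols,
                             cfg$pause_min, cfg$pause_max,
                             cfg$stimulus_ticks, cfg$rng_seed)
  ann <- data.frame(signal = .sym_names[raw$sym + 1L], onset = raw$onset,
                    window = task$window, pause = raw$pause,
                    stringsAsFactors = FALSE)
  .new_stream(raw$inputs, raw$targets, ann, task, cfg)
}

#' Build a stream from an explicit symbol sequence
#'
#' Deterministic constructor used by fixtures and as an independent
#' re-derivation of the target-placement rule in tests: the same tick layout
#' as [generate_stream()], but with the symbols and pauses supplied.
#'
#' @param symbols character vector of stimulus names (`"A"`, `"B"`, `"C"`).
#' @param pauses integer vector of extra pause ticks after each symbol's
#'   window; its first element is also used as the leading pause unless
#'   `lead` is given.
#' @param task an `nnmo_task`.
#' @param stimulus_ticks stimulus duration in ticks.
#' @param lead leading pause ticks before the first symbol.
#' @return an `nnmo_stream`.
#' @export
stream_from_symbols <- function(symbols, pauses, task, stimulus_ticks = 1L,
                                lead = pauses[1]) {
  stopifnot(length(symbols) == length(pauses), all(symbols %in% .sym_names))
  blank <- function(k) matrix(0, nrow = k, ncol = 2)
  inputs <- blank(lead)
  onset <- integer(length(symbols))
  for (k in seq_along(symbols)) {
    onset[k] <- nrow(inputs) + 1L
    code <- signal_code(symbols[k])
    inputs <- rbind(inputs,
                    matrix(code, nrow = stimulus_ticks, ncol = 2, byrow = TRUE),
                    blank(task$window + pauses[k]))
  }
  # causal target rule: each tick answers the most recent stimulus whose
  # processing window has elapsed, holding until the next one is classified
  offset <- stimulus_ticks - 1L + task$window
  resp <- as.numeric(symbols == task$correct_signal)
  last <- findInterval(seq_len(nrow(inputs)), onset + offset)
  tg <- c(0, resp)[last + 1L]
  targets <- unname(cbind(tg, tg))
  ann <- data.frame(signal = symbols, onset = onset, window = task$window,
                    pause = as.integer(pauses), stringsAsFactors = FALSE)
  .new_stream(inputs, targets, ann, task)
}

#' Swap the two input channels of a stream
#'
#' Every input pair (p, q) becomes (q, p): A and B exchange roles while C and
#' pause are fixed. Targets are unchanged. Used to express the input-neuron
#' permutation symmetry of tasks whose correct stimulus has a symmetric code
#' (C4).
#'
#' @param stream an `nnmo_stream`.
#' @return the channel-swapped `nnmo_stream`.
#' @export
swap_AB <- function(stream) {
  out <- stream
  out$inputs <- stream$inputs[, c(2, 1), drop = FALSE]
  colnames(out$inputs) <- c("in1", "in2")
  sig <- stream$annotations$signal
  out$annotations$signal <- ifelse(sig == "A", "B", ifelse(sig == "B", "A", sig))
  out
}

#' Small deterministic test streams
#'
#' A registry of tiny hard-coded streams for unit tests.
#'
#' @param name `"a3_tiny"` or `"c4_tiny"`.
#' @return an `nnmo_stream`.
#' @export
fixture_stream <- function(name) {
  switch(name,
    a3_tiny = stream_from_symbols(c("A", "B", "A", "C", "B"),
                                  c(2L, 1L, 3L, 2L, 1L), task_spec("A3")),
    c4_tiny = stream_from_symbols(c("C", "A", "B", "C", "A"),
                                  c(1L, 2L, 2L, 1L, 3L), task_spec("C4")),
    stop("unknown fixture stream: ", name)
  )
}

#' @export
print.nnmo_stream <- function(x, ...) {
  cat("<nnmo_stream> task ", x$task$name, ": ", nrow(x$annotations),
      " symbols, ", nrow(x$inputs), " ticks\n", sep = "")
  invisible(x)
}

#' Write / read a stream as plain text
#'
#' One tick per line (`in1 in2 tgt1 tgt2`), preceded by a `#`-prefixed header
#' recording the task, seed and generator configuration; round-trips exactly.
#'
#' @param stream an `nnmo_stream`.
#' @param path file path.
#' @return `save_stream` returns `path` invisibly; `load_stream` returns the
#'   `nnmo_stream` (annotations are re-derivable but not stored).
#' @export
save_stream <- function(stream, path) {
  hdr <- c(paste0("# task: ", stream$task$name),
           paste0("# window: ", stream$task$window),
           if (!is.null(stream$cfg))
             paste0("# config: ",
                    jsonlite::toJSON(unclass(stream$cfg), auto_unbox = TRUE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(cbind(stream$inputs, stream$targets), con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname save_stream
#' @export
load_stream <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  task_name <- sub("^# task: ", "", grep("^# task: ", hdr, value = TRUE))
  task <- task_spec(task_name)
  body <- read.table(text = lines[!grepl("^#", lines)],
                     colClasses = "numeric")
  inputs <- as.matrix(body[, 1:2]); targets <- as.matrix(body[, 3:4])
  dimnames(inputs) <- NULL; dimnames(targets) <- NULL
  cfg <- NULL
  cfg_line <- grep("^# config: ", hdr, value = TRUE)
  if (length(cfg_line)) {
    cfg <- jsonlite::fromJSON(sub("^# config: ", "", cfg_line))
    cfg <- stream_config(cfg$length_symbols, cfg$pause_min, cfg$pause_max,
                         cfg$stimulus_ticks, cfg$rng_seed)
  }
  .new_stream(inputs, targets, annotations = NULL, task = task, cfg = cfg)
}
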