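test_that("signal codes are the printed bijection", {
  expect_identical(signal_code("PAUSE"), c(0, 0))
  expect_identical(signal_code("A"), c(1, 0))
  expect_identical(signal_code("B"), c(0, 1))
  expect_identical(signal_code("C"), c(1, 1))
})

test_that("task_spec parses compact names and validates the window", {
  t1 <- task_spec("A3")
  expect_identical(t1$correct_signal, "A")
  expect_identical(t1$window, 3L)
  expect_identical(task_spec("C", 4)$name, "C4")
  expect_error(task_spec("A", 5))
})

# Independent tick-by-tick re-scan of a stream: at each tick the target is
# the classification of the most recent stimulus whose processing window has
# elapsed (1 iff it was the correct signal), 0 before any classification.
rescan_targets <- function(stream, stimulus_ticks = 1L) {
  ann <- stream$annotations
  done <- ann$onset + stimulus_ticks - 1L + ann$window
  tg <- matrix(0, nrow(stream$inputs), 2)
  for (t in seq_len(nrow(tg))) {
    k <- which(done <= t)
    if (length(k)) {
      k <- max(k)
      tg[t, ] <- as.numeric(ann$signal[k] == stream$task$correct_signal)
    }
  }
  tg
}

test_that("a lone correct stimulus is answered after its window, held to the end", {
  s <- stream_from_symbols("A", 2L, task_spec("A3"), lead = 1L)
  # ticks: pause, A at 2, processing 3-4, response from 5 (= onset + window)
  expect_identical(which(s$targets[, 1] == 1), 5:7)
  expect_identical(unname(s$inputs[2, ]), c(1, 0))
  expect_identical(sum(s$inputs), 1)
  # a wrong stimulus is never answered
  s2 <- stream_from_symbols("B", 2L, task_spec("A3"), lead = 1L)
  expect_identical(sum(s2$targets), 0)
  # the answer to a correct stimulus holds until the NEXT one is classified
  s3 <- stream_from_symbols(c("A", "B"), c(1L, 2L), task_spec("A3"), lead = 1L)
  # A at 2 -> high from 5; B at 7 classified at 10 -> low from 10
  expect_identical(which(s3$targets[, 1] == 1), 5:9)
})

test_that("generated streams obey the target rule and are seed-deterministic", {
  task <- task_spec("C4")
  cfg <- stream_config(length_symbols = 50, rng_seed = 123)
  s <- generate_stream(task, cfg)
  expect_identical(nrow(s$annotations), 50L)
  expect_identical(unname(s$targets), unname(rescan_targets(s)))
  s2 <- generate_stream(task, cfg)
  expect_identical(s$inputs, s2$inputs)
  expect_identical(s$targets, s2$targets)
  s3 <- generate_stream(task, stream_config(length_symbols = 50, rng_seed = 124))
  expect_false(identical(s$inputs, s3$inputs))
})

test_that("the generator and the explicit-symbol constructor agree", {
  task <- task_spec("A3")
  cfg <- stream_config(length_symbols = 20, rng_seed = 9)
  s <- generate_stream(task, cfg)
  lead <- s$annotations$onset[1] - 1L
  rebuilt <- stream_from_symbols(s$annotations$signal, s$annotations$pause,
                                 task, lead = lead)
  expect_identical(unname(s$inputs), unname(rebuilt$inputs))
  expect_identical(unname(s$targets), unname(rebuilt$targets))
})

test_that("a 100-symbol stream annotates exactly 100 stimuli", {
  s <- generate_stream(task_spec("A3"), stream_config(rng_seed = 5))
  expect_identical(nrow(s$annotations), 100L)
})

test_that("stimulus marginals are uniform over {A,B,C}", {
  s <- generate_stream(task_spec("A3"),
                       stream_config(length_symbols = 12000, rng_seed = 31))
  counts <- table(s$annotations$signal)
  n <- sum(counts)
  # 3-sigma binomial band around 1/3
  sigma <- sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n / 3) < 3 * sigma))
})

test_that("pause lengths are uniform on [pause_min, pause_max]", {
  s <- generate_stream(task_spec("A3"),
                       stream_config(length_symbols = 12000, pause_min = 1,
                                     pause_max = 4, rng_seed = 77))
  p <- s$annotations$pause
  expect_true(all(p >= 1 & p <= 4))
  chisq <- suppressWarnings(stats::chisq.test(table(factor(p, levels = 1:4))))
  expect_gt(chisq$p.value, 0.01)
})

test_that("swap_AB swaps channels, fixes C/pause and is an involution", {
  s <- fixture_stream("c4_tiny")
  sw <- swap_AB(s)
  expect_identical(unname(sw$inputs), unname(s$inputs[, c(2, 1)]))
  expect_identical(sw$targets, s$targets)
  expect_identical(swap_AB(sw)$inputs, s$inputs)
  expect_identical(sw$annotations$signal,
                   c("C", "B", "A", "C", "B"))
  # stream of only C and pause is unchanged
  sc <- stream_from_symbols(c("C", "C"), c(2L, 2L), task_spec("C4"))
  expect_identical(swap_AB(sc)$inputs, sc$inputs)
})

test_that("fixture streams are stable and well-formed", {
  a <- fixture_stream("a3_tiny")
  expect_identical(a$annotations$signal, c("A", "B", "A", "C", "B"))
  expect_identical(nrow(a$inputs), nrow(a$targets))
  expect_identical(unname(a$targets), unname(rescan_targets(a)))
  c4 <- fixture_stream("c4_tiny")
  expect_true("C" %in% c4$annotations$signal)
  expect_error(fixture_stream("nope"))
})

test_that("the a3_tiny fixture matches its pinned serialized form", {
  path <- withr::local_tempfile(fileext = ".txt")
  save_stream(fixture_stream("a3_tiny"), path)
  expect_identical(readLines(path), c(
    "# task: A3", "# window: 3",
    "0 0 0 0", "0 0 0 0", "1 0 0 0", "0 0 0 0", "0 0 0 0", "0 0 1 1",
    "0 0 1 1", "0 0 1 1", "0 1 1 1", "0 0 1 1", "0 0 1 1", "0 0 0 0",
    "0 0 0 0", "1 0 0 0", "0 0 0 0", "0 0 0 0", "0 0 1 1", "0 0 1 1",
    "0 0 1 1", "0 0 1 1", "1 1 1 1", "0 0 1 1", "0 0 1 1", "0 0 0 0",
    "0 0 0 0", "0 0 0 0", "0 1 0 0", "0 0 0 0", "0 0 0 0", "0 0 0 0",
    "0 0 0 0"))
})

test_that("stream serialization round-trips", {
  s <- generate_stream(task_spec("C4"), stream_config(length_symbols = 10,
                                                      rng_seed = 4))
  path <- withr::local_tempfile(fileext = ".txt")
  save_stream(s, path)
  s2 <- load_stream(path)
  expect_identical(unname(s2$inputs), unname(s$inputs))
  expect_identical(unname(s2$targets), unname(s$targets))
  expect_identical(s2$task$name, "C4")
  expect_identical(s2$cfg$rng_seed, s$cfg$rng_seed)
})
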