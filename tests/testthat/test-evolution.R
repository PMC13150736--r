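test_that("init_weights respects the support bound and seeding", {
  cfg <- test_config6()
  set.seed(5); w1 <- init_weights(cfg, 0.01)
  expect_true(all(abs(w1$x) <= 0.01))
  expect_false(any(w1$frozen))
  set.seed(5); w2 <- init_weights(cfg, 0.01)
  expect_identical(w1, w2)
  set.seed(5); w0 <- init_weights(cfg, 0)
  expect_identical(w0$x, matrix(0, 6, 6))
})

test_that("mutate_pair is an exact mirror and respects the frozen mask", {
  x <- matrix(rnorm(36), 6, 6)
  fr <- matrix(FALSE, 6, 6); fr[2, 3] <- TRUE; x[2, 3] <- 0
  w <- weight_matrix(x, fr)
  set.seed(8)
  off <- mutate_pair(w, scale = 0.1)
  # mirror identity: exact in exact arithmetic, machine-precision in doubles
  expect_equal((off$plus$x + off$minus$x) / 2, w$x, tolerance = 1e-14)
  expect_equal(abs(off$plus$x - w$x), abs(off$minus$x - w$x))
  expect_identical(off$plus$x[2, 3], 0)
  expect_identical(off$minus$x[2, 3], 0)
  expect_true(all(abs(off$delta) <= 0.1))
})

test_that("select_step returns the argmin with parent-first tie-breaking", {
  cfg <- test_config6()
  w <- test_weights(seed = 21)
  s <- fixture_stream("a3_tiny")
  # zero increment: all three identical, parent retained
  res0 <- select_step(w, cfg, s, delta = matrix(0, 6, 6))
  expect_identical(res0$which, "parent")
  expect_identical(res0$weights$x, w$x)
  # generic increment: survivor's goal is its own evaluation and is <= parent's
  set.seed(9)
  delta <- matrix(runif(36, -0.2, 0.2), 6, 6)
  res <- select_step(w, cfg, s, delta = delta)
  g_parent <- unname(evaluate_network(w, s, cfg)["goal"])
  g_plus <- unname(evaluate_network(weight_matrix(w$x + delta), s, cfg)["goal"])
  g_minus <- unname(evaluate_network(weight_matrix(w$x - delta), s, cfg)["goal"])
  expect_equal(res$goal, min(g_parent, g_plus, g_minus))
  expect_lte(res$goal, g_parent)
  expect_equal(unname(evaluate_network(res$weights, s, cfg)["goal"]), res$goal)
})

test_that("fixed-stream evolution has a monotone non-increasing goal", {
  cfg <- test_config6()
  tcfg <- train_config(stream = stream_config(length_symbols = 20, rng_seed = 3),
                       regenerate_stream = FALSE, max_generations = 300,
                       mutation_seed = 4, stream_seed = 5)
  set.seed(10)
  res <- evolve(cfg, task_spec("A3"), tcfg, stop_on_success = FALSE)
  expect_true(all(diff(res$trajectory$goal) <= 1e-12))
})

test_that("evolve is reproducible end-to-end given identical seeds", {
  cfg <- test_config6()
  tcfg <- test_train_cfg(max_generations = 200, mutation_seed = 6,
                         stream_seed = 7)
  set.seed(12); r1 <- evolve(cfg, task_spec("A3"), tcfg, stop_on_success = FALSE)
  set.seed(12); r2 <- evolve(cfg, task_spec("A3"), tcfg, stop_on_success = FALSE)
  expect_identical(r1$weights$x, r2$weights$x)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("frozen synapses stay exactly zero through a whole run", {
  cfg <- test_config6()
  x <- test_weights(seed = 30)$x
  fr <- matrix(FALSE, 6, 6); fr[1, 1] <- fr[5, 2] <- fr[6, 6] <- TRUE
  x[fr] <- 0
  w <- weight_matrix(x, fr)
  tcfg <- test_train_cfg(max_generations = 400, mutation_seed = 1,
                         stream_seed = 2)
  res <- evolve(cfg, task_spec("A3"), tcfg, init = w, stop_on_success = FALSE)
  expect_identical(res$weights$x[fr], c(0, 0, 0))
  expect_identical(res$weights$frozen, fr)
})

test_that("selection commutes with sign-flip transforms of the structure", {
  # the mechanism behind cluster symmetry: transforming parent and increment
  # together transforms the whole selection step
  cfg <- test_config6()
  w <- test_weights(seed = 33)
  tr <- invariant_transform(c(1, 2), c(-1, 1))
  s <- fixture_stream("a3_tiny")
  set.seed(14)
  delta <- matrix(runif(36, -0.05, 0.05), 6, 6)
  wd <- weight_matrix(delta)
  delta_t <- apply_transform(wd, tr, cfg)$x
  res <- select_step(w, cfg, s, delta = delta)
  res_t <- select_step(apply_transform(w, tr, cfg), cfg, s, delta = delta_t)
  expect_identical(res_t$which, res$which)
  expect_equal(res_t$weights$x,
               apply_transform(res$weights, tr, cfg)$x, tolerance = 1e-12)
  expect_equal(res_t$goal, res$goal, tolerance = 1e-9)
})

test_that("train_ensemble yields distinct, reproducible members", {
  cfg <- test_config6()
  tcfg <- test_train_cfg(max_generations = 150)
  ens <- train_ensemble(3, cfg, task_spec("A3"), tcfg, base_seed = 77)
  expect_length(ens, 3)
  d <- dist(do.call(rbind, lapply(ens, function(r) flatten_weights(r$weights))))
  expect_true(all(d > 0))
  ens2 <- train_ensemble(3, cfg, task_spec("A3"), tcfg, base_seed = 77)
  expect_identical(lapply(ens, function(r) r$weights$x),
                   lapply(ens2, function(r) r$weights$x))
})

test_that("trajectories diverge with distinct seeds and not with shared ones", {
  cfg <- test_config6()
  set.seed(99)
  start <- init_weights(cfg, 0.01)
  tcfg <- test_train_cfg(max_generations = 300, snapshot_stride = 50)
  div <- trajectory_divergence(start, cfg, task_spec("A3"), tcfg,
                               n_replicates = 3, base_seed = 5)
  d <- div$distances
  expect_true(all(d$distance[d$generation == 0] == 0))
  gmax <- max(d$generation)
  expect_gt(mean(d$distance[d$generation == gmax]),
            mean(d$distance[d$generation == min(d$generation[d$generation > 0])]))
  ctrl <- trajectory_divergence(start, cfg, task_spec("A3"), tcfg,
                                n_replicates = 3, base_seed = 5,
                                identical_seeds = TRUE)
  expect_true(all(ctrl$distances$distance == 0))
})
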