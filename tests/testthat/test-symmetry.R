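test_that("group enumeration has order 2^K * K! (times 2 with input swap)", {
  expect_length(enumerate_group(0), 1)
  expect_length(enumerate_group(1), 2)
  expect_length(enumerate_group(2), 8)
  expect_length(enumerate_group(2, input_swap_allowed = TRUE), 16)
  expect_length(enumerate_group(3), 48)
  # no duplicates
  key <- function(t) paste(c(t$hidden_perm, t$hidden_signs, t$input_swap),
                           collapse = "|")
  g <- enumerate_group(2, input_swap_allowed = TRUE)
  expect_identical(anyDuplicated(vapply(g, key, character(1))), 0L)
})

test_that("the enumerated transforms form a closed group", {
  g <- enumerate_group(2, input_swap_allowed = TRUE)
  key <- function(t) paste(c(t$hidden_perm, t$hidden_signs, t$input_swap),
                           collapse = "|")
  keys <- vapply(g, key, character(1))
  for (t1 in g[c(1, 5, 9, 16)])
    for (t2 in g) expect_true(key(compose_transforms(t2, t1)) %in% keys)
})

test_that("predicted cluster counts follow 2^K * K!", {
  expect_identical(predicted_cluster_count(1), 2)
  expect_identical(predicted_cluster_count(2), 8)
  expect_identical(predicted_cluster_count(2, input_swap_allowed = TRUE), 16)
  expect_identical(predicted_cluster_count(3), 48)
})

test_that("apply_transform: identity, involution, and composition", {
  cfg <- test_config6()
  w <- test_weights(seed = 50)
  id <- invariant_transform(c(1, 2), c(1, 1))
  expect_identical(apply_transform(w, id, cfg)$x, w$x)
  flip <- invariant_transform(c(1, 2), c(-1, 1))
  expect_identical(apply_transform(apply_transform(w, flip, cfg), flip, cfg)$x,
                   w$x)
  t1 <- invariant_transform(c(2, 1), c(-1, 1))
  t2 <- invariant_transform(c(2, 1), c(1, -1), input_swap = TRUE)
  lhs <- apply_transform(apply_transform(w, t1, cfg), t2, cfg)$x
  rhs <- apply_transform(w, compose_transforms(t2, t1), cfg)$x
  expect_equal(lhs, rhs)
})

test_that("hidden sign/permutation transforms leave the output trace invariant", {
  cfg <- test_config6()
  group <- enumerate_group(2)
  streams <- list(fixture_stream("a3_tiny"), fixture_stream("c4_tiny"))
  for (seed in c(1, 2, 3)) {
    w <- test_weights(seed = seed, scale = 1.5)
    for (s in streams) {
      base <- run_stream(w, s, cfg)
      for (t in group) {
        tr <- run_stream(apply_transform(w, t, cfg), s, cfg)
        expect_lt(max(abs(tr - base)), 1e-9)
      }
    }
  }
})

test_that("an asymmetric sign change is not an invariance", {
  # flipping only the incoming weights of a hidden neuron (not its outgoing
  # column) changes the function; the full row+column flip does not
  cfg <- test_config6()
  w <- test_weights(seed = 60, scale = 1.5)
  s <- fixture_stream("a3_tiny")
  base <- run_stream(w, s, cfg)
  x_bad <- w$x; x_bad[5, ] <- -x_bad[5, ]
  expect_gt(max(abs(run_stream(weight_matrix(x_bad), s, cfg) - base)), 1e-3)
  x_good <- w$x; x_good[5, ] <- -x_good[5, ]; x_good[, 5] <- -x_good[, 5]
  expect_lt(max(abs(run_stream(weight_matrix(x_good), s, cfg) - base)), 1e-9)
})

test_that("goal is equal across a whole orbit", {
  cfg <- test_config6()
  w <- test_weights(seed = 70, scale = 1.2)
  s <- fixture_stream("c4_tiny")
  g0 <- goal_function(run_stream(w, s, cfg), s)
  for (t in enumerate_group(2)) {
    g <- goal_function(run_stream(apply_transform(w, t, cfg), s, cfg), s)
    expect_lt(abs(g - g0), 1e-9)
  }
})

test_that("input swap is a task-level symmetry via the swapped stream", {
  cfg <- test_config6()
  w <- test_weights(seed = 80, scale = 1.2)
  s <- generate_stream(task_spec("C4"), stream_config(length_symbols = 30,
                                                      rng_seed = 15))
  t_swap <- invariant_transform(c(1, 2), c(1, 1), input_swap = TRUE)
  w_swapped <- apply_transform(w, t_swap, cfg)
  e1 <- evaluate_network(w, s, cfg)
  e2 <- evaluate_network(w_swapped, swap_AB(s), cfg)
  expect_equal(unname(e1["errors"]), unname(e2["errors"]))
  expect_equal(unname(e1["goal"]), unname(e2["goal"]), tolerance = 1e-9)
})

test_that("canonicalize is idempotent and constant on orbits", {
  cfg <- test_config6()
  w <- test_weights(seed = 90)
  can <- canonicalize(w, cfg)
  expect_identical(canonicalize(can$weights, cfg)$weights$x, can$weights$x)
  for (t in enumerate_group(2)) {
    can_t <- canonicalize(apply_transform(w, t, cfg), cfg)
    expect_equal(can_t$weights$x, can$weights$x, tolerance = 1e-12)
  }
  z <- weight_matrix(matrix(0, 6, 6))
  expect_identical(canonicalize(z, cfg)$weights$x, z$x)
  # the reported transform actually achieves the canonical form
  expect_identical(apply_transform(w, can$transform, cfg)$x, can$weights$x)
})

test_that("pairwise distances match a brute-force double loop", {
  ens <- lapply(1:4, function(i) test_weights(seed = i))
  geom <- pairwise_distances(ens)
  m <- as.matrix(geom$distances)
  for (i in 1:4)
    for (j in 1:4) {
      ref <- sqrt(sum((flatten_weights(ens[[i]]) - flatten_weights(ens[[j]]))^2))
      expect_equal(m[i, j], ref, tolerance = 1e-12)
    }
  # duplicated member at distance 0
  geom2 <- pairwise_distances(c(ens, ens[1]))
  expect_equal(as.matrix(geom2$distances)[1, 5], 0)
  # single-coordinate difference
  a <- weight_matrix(matrix(0, 6, 6))
  b <- weight_matrix(matrix(c(0.7, rep(0, 35)), 6, 6))
  expect_equal(as.vector(pairwise_distances(list(a, b))$distances), 0.7)
})

# Build the full K=2 orbit of one structure with a little jitter: the
# canonical constructed ensemble with exactly 8 ground-truth clusters.
orbit_ensemble <- function(w, cfg, jitter = 0.01, copies = 3, seed = 1) {
  set.seed(seed)
  out <- list()
  for (t in enumerate_group(2)) {
    base <- apply_transform(w, t, cfg)
    for (k in seq_len(copies)) {
      noise <- matrix(runif(36, -jitter, jitter), 6, 6)
      out[[length(out) + 1L]] <- weight_matrix(base$x + noise)
    }
  }
  out
}

test_that("cluster_count recovers the 8 orbit clusters and 1 for a blob", {
  cfg <- test_config6()
  w <- test_weights(seed = 100, scale = 1)
  ens <- orbit_ensemble(w, cfg)
  cl <- cluster_count(pairwise_distances(ens))
  expect_identical(cl$n_clusters, 8L)
  expect_identical(cl$sizes, rep(3L, 8))
  # one tight blob
  set.seed(3)
  blob <- lapply(1:20, function(i)
    weight_matrix(w$x + matrix(rnorm(36, sd = 0.01), 6, 6)))
  expect_identical(cluster_count(pairwise_distances(blob))$n_clusters, 1L)
  # degenerate all-identical ensemble
  same <- lapply(1:5, function(i) w)
  expect_identical(cluster_count(pairwise_distances(same))$n_clusters, 1L)
  # after canonicalization the orbit collapses to one cluster
  cl_can <- cluster_count(pairwise_distances(ens, cfg, canonical = TRUE))
  expect_identical(cl_can$n_clusters, 1L)
})

test_that("project3d selects the requested flat coordinates", {
  ens <- lapply(1:3, function(i) test_weights(seed = i))
  pr <- project3d(ens, c(25, 26, 31))
  # synapse 25 is row 5, col 1 in a 6-neuron matrix (row-major, 1-based)
  expect_equal(pr$x, vapply(ens, function(w) w$x[5, 1], numeric(1)))
  expect_equal(pr$y, vapply(ens, function(w) w$x[5, 2], numeric(1)))
  expect_equal(pr$z, vapply(ens, function(w) w$x[6, 1], numeric(1)))
  expect_error(project3d(ens, c(0, 1, 2)))
  # sign-flip coordinates separate orbit images into >= 2 centroids
  cfg <- test_config6()
  w <- test_weights(seed = 101)
  w$x[5, 1] <- 1; w$x[6, 1] <- 0.9
  orb <- orbit_ensemble(w, cfg)
  pr2 <- project3d(orb, c(25, 26, 31))
  expect_setequal(unique(sign(pr2$x)), c(-1, 1))
})

test_that("distance modality separates blobs from clusters", {
  cfg <- test_config6()
  set.seed(4)
  blob <- lapply(1:15, function(i)
    weight_matrix(matrix(rnorm(36, sd = 0.05), 6, 6)))
  expect_false(distance_modality(pairwise_distances(blob))$multimodal)
  # two well-separated blobs: within vs between distances
  two <- c(blob, lapply(1:15, function(i)
    weight_matrix(matrix(5 + rnorm(36, sd = 0.05), 6, 6))))
  expect_true(distance_modality(pairwise_distances(two))$multimodal)
  # orbit-constructed ensemble is multimodal
  orb <- orbit_ensemble(test_weights(seed = 102, scale = 1), cfg)
  expect_true(distance_modality(pairwise_distances(orb))$multimodal)
})
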