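#' Flatten a weight matrix to a structure-space point
#'
#' Row-major, 1-based flattening: synapse number `s` corresponds to row
#' `ceiling(s / n)`, column `(s - 1) %% n + 1` (e.g. synapse 25 of a 6-neuron
#' network is row 5, column 1). This is the coordinate convention of all
#' ensemble geometry.
#'
#' @param w an `nnmo_weights` or a plain square matrix.
#' @return numeric vector of length `n^2`.
#' @export
flatten_weights <- function(w) {
  x <- if (inherits(w, "nnmo_weights")) w$x else w
  as.vector(t(x))
}

#' Functionally invariant transform
#'
#' An element of the functional-symmetry group: a permutation of the hidden
#' (associative) neurons, a sign flip (+1/-1) per hidden neuron, and
#' optionally a swap of the two input neurons. Because the activation is odd
#' and hidden neurons are interchangeable, these transforms change the
#' structure without changing the function.
#'
#' @param hidden_perm permutation of `1..K` (positions within the hidden set).
#' @param hidden_signs vector of +1/-1 of length `K`.
#' @param input_swap whether to swap the two input neurons (only a task-level
#'   symmetry for tasks whose correct stimulus has a symmetric code, e.g. C4).
#' @return an object of class `nnmo_transform`.
#' @export
invariant_transform <- function(hidden_perm, hidden_signs,
                                input_swap = FALSE) {
  hidden_perm <- as.integer(hidden_perm)
  K <- length(hidden_perm)
  stopifnot(length(hidden_signs) == K, all(sort(hidden_perm) == seq_len(K)),
            all(hidden_signs %in% c(-1, 1)))
  structure(list(hidden_perm = hidden_perm,
                 hidden_signs = as.numeric(hidden_signs),
                 input_swap = isTRUE(input_swap)),
            class = "nnmo_transform")
}

#' @export
print.nnmo_transform <- function(x, ...) {
  cat("<nnmo_transform> perm (", paste(x$hidden_perm, collapse = " "),
      "), signs (", paste(ifelse(x$hidden_signs > 0, "+", "-"), collapse = ""),
      ")", if (x$input_swap) ", input swap", "\n", sep = "")
  invisible(x)
}

#' Apply a functionally invariant transform to a structure
#'
#' Relabels neurons by the (hidden, optionally input) permutation and negates
#' the row and column of every sign-flipped hidden neuron:
#' `x'[sigma(i), sigma(j)] = s_i s_j x[i, j]`. Output neurons are never
#' permuted or sign-flipped. The frozen mask is transported identically.
#' With `input_swap = FALSE` the transformed network's output trace equals
#' the original's on every stream.
#'
#' @param w an `nnmo_weights`.
#' @param t an `nnmo_transform`.
#' @param config the owning `nnmo_config`.
#' @return the transformed `nnmo_weights`.
#' @export
apply_transform <- function(w, t, config) {
  n <- config$n_total
  K <- length(config$hidden_ids)
  stopifnot(length(t$hidden_perm) == K, nrow(w$x) == n)
  sigma <- seq_len(n)
  sigma[config$hidden_ids] <- config$hidden_ids[t$hidden_perm]
  if (t$input_swap) sigma[config$input_ids] <- rev(config$input_ids)
  s <- rep(1, n)
  s[config$hidden_ids] <- t$hidden_signs
  xp <- matrix(0, n, n); fp <- matrix(FALSE, n, n)
  xp[sigma, sigma] <- (s %o% s) * w$x
  fp[sigma, sigma] <- w$frozen
  weight_matrix(xp, fp)
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying `t1` first, then `t2`.
#'
#' @param t1,t2 `nnmo_transform` objects over the same hidden count.
#' @return an `nnmo_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  K <- length(t1$hidden_perm)
  stopifnot(length(t2$hidden_perm) == K)
  # neuron at position k goes to t1$perm[k], then to t2$perm[t1$perm[k]]
  perm <- t2$hidden_perm[t1$hidden_perm]
  signs <- t1$hidden_signs * t2$hidden_signs[t1$hidden_perm]
  invariant_transform(perm, signs, xor(t1$input_swap, t2$input_swap))
}

.permutations <- function(K) {
  if (K == 0L) return(list(integer(0)))
  if (K == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (p in .permutations(K - 1L)) {
      q <- integer(K)
      q[1] <- i
      rest <- setdiff(seq_len(K), i)
      q[-1] <- rest[p]
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

#' Enumerate the functional-symmetry group
#'
#' All distinct invariant transforms for `K` hidden neurons: every
#' combination of per-neuron sign flips with every hidden-neuron
#' permutation, doubled by the input swap when allowed. The group order is
#' `2^K * K!` (times 2 with input swap).
#'
#' @param K number of hidden (associative) neurons.
#' @param input_swap_allowed include the input-neuron swap.
#' @return list of `nnmo_transform` objects.
#' @export
enumerate_group <- function(K, input_swap_allowed = FALSE) {
  K <- as.integer(K)
  stopifnot(K >= 0L)
  perms <- .permutations(K)
  signs <- if (K == 0L) list(numeric(0)) else
    asplit(as.matrix(expand.grid(rep(list(c(-1, 1)), K))), 1)
  swaps <- if (input_swap_allowed) c(FALSE, TRUE) else FALSE
  out <- list()
  for (sw in swaps)
    for (p in perms)
      for (s in signs)
        out[[length(out) + 1L]] <- invariant_transform(p, as.numeric(s), sw)
  out
}

#' Predicted number of structural clusters
#'
#' For networks with an odd activation function, every element of the
#' functional-symmetry group maps a solution to a distinct, equally fit
#' solution, so an ensemble of independently evolved structures falls into
#' `N = 2^K * K!` clusters (`K` = hidden-neuron count); the sign flips give
#' the power of two and the hidden-neuron permutations the factorial. Tasks
#' with identical input-neuron signals (C4) double this via the input swap.
#'
#' @inheritParams enumerate_group
#' @return integer cluster count.
#' @export
predicted_cluster_count <- function(K, input_swap_allowed = FALSE) {
  2^K * factorial(K) * (if (input_swap_allowed) 2 else 1)
}

#' Canonical orbit representative
#'
#' Maps a structure to the lexicographically smallest flattened matrix over
#' its full symmetry orbit (exhaustive search over the enumerated group).
#' All members of one orbit map to the same representative, so canonical
#' forms identify functionally equivalent structures.
#'
#' @param w an `nnmo_weights`.
#' @param config an `nnmo_config`.
#' @param input_swap_allowed include the input swap in the orbit.
#' @return list: `weights` (the representative) and `transform` (an
#'   `nnmo_transform` achieving it).
#' @export
canonicalize <- function(w, config, input_swap_allowed = FALSE) {
  group <- enumerate_group(length(config$hidden_ids), input_swap_allowed)
  best <- NULL; best_v <- NULL; best_t <- NULL
  for (t in group) {
    cand <- apply_transform(w, t, config)
    v <- flatten_weights(cand)
    if (is.null(best_v) || .lex_less(v, best_v)) {
      best <- cand; best_v <- v; best_t <- t
    }
  }
  list(weights = best, transform = best_t)
}

.lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' Ensemble geometry in structure space
#'
#' Flattens the ensemble members to points in structure space and computes
#' all pairwise Euclidean distances — the proximity measure between NNMO
#' structures. Optionally canonicalizes members first, which collapses the
#' symmetry orbits so that only genuine (non-symmetry) structural variation
#' remains.
#'
#' @param ensemble list of `nnmo_weights` (or matrices), equal dimensions.
#' @param config an `nnmo_config`; required if `canonical = TRUE`.
#' @param canonical canonicalize members before measuring.
#' @param input_swap_allowed passed to [canonicalize()].
#' @return an object of class `nnmo_geometry`: list with `points` (members x
#'   coordinates matrix) and `distances` (a [stats::dist]).
#' @export
pairwise_distances <- function(ensemble, config = NULL, canonical = FALSE,
                               input_swap_allowed = FALSE) {
  stopifnot(length(ensemble) >= 2L)
  if (canonical) {
    stopifnot(!is.null(config))
    ensemble <- lapply(ensemble, function(w)
      canonicalize(w, config, input_swap_allowed)$weights)
  }
  pts <- do.call(rbind, lapply(ensemble, flatten_weights))
  if (any(apply(pts, 1, length) != ncol(pts)))
    stop("ensemble members have unequal dimensions")
  structure(list(points = pts, distances = dist(pts)),
            class = "nnmo_geometry")
}

#' @export
print.nnmo_geometry <- function(x, ...) {
  cat("<nnmo_geometry> ", nrow(x$points), " members in ", ncol(x$points),
      "-dimensional structure space\n", sep = "")
  invisible(x)
}

#' Count structural clusters
#'
#' Single-linkage agglomerative clustering of the ensemble, cut at the
#' largest gap in the sorted merge heights. The cut is only accepted when
#' that gap exceeds `gap_ratio` times the next-largest gap (otherwise the
#' ensemble is reported as one cluster); symmetry-orbit clusters are compact
#' and well separated, so the gap is unambiguous when clusters exist.
#'
#' @param geometry an `nnmo_geometry` (or a [stats::dist]).
#' @param gap_ratio significance factor for the largest height gap.
#' @return list: `n_clusters`, integer `labels` per member, `sizes`, and the
#'   `cut_height` used (NA when a single cluster is reported).
#' @export
cluster_count <- function(geometry, gap_ratio = 2) {
  d <- if (inherits(geometry, "nnmo_geometry")) geometry$distances else geometry
  n <- attr(d, "Size")
  if (max(d) == 0)
    return(list(n_clusters = 1L, labels = rep(1L, n), sizes = n,
                cut_height = NA_real_))
  hc <- hclust(d, method = "single")
  h <- sort(hc$height)
  gaps <- diff(h)
  if (length(gaps) == 0L || max(gaps) <= 0)
    return(list(n_clusters = 1L, labels = rep(1L, n), sizes = n,
                cut_height = NA_real_))
  i <- which.max(gaps)
  second <- if (length(gaps) > 1L) max(gaps[-i]) else 0
  if (gaps[i] < gap_ratio * second)
    return(list(n_clusters = 1L, labels = rep(1L, n), sizes = n,
                cut_height = NA_real_))
  cut_height <- (h[i] + h[i + 1]) / 2
  labels <- cutree(hc, h = cut_height)
  list(n_clusters = max(labels), labels = labels,
       sizes = as.integer(table(labels)), cut_height = cut_height)
}

#' Project an ensemble onto three synapse coordinates
#'
#' Selects three coordinates of the flattened (row-major, 1-based) weight
#' vectors for 3-D visualisation of the cluster structure.
#'
#' @param ensemble list of `nnmo_weights`, or an `nnmo_geometry`.
#' @param synapse_numbers three flat synapse indices in `1..n^2`.
#' @return data.frame with columns `x`, `y`, `z` (one row per member).
#' @export
project3d <- function(ensemble, synapse_numbers) {
  pts <- if (inherits(ensemble, "nnmo_geometry")) ensemble$points
         else do.call(rbind, lapply(ensemble, flatten_weights))
  stopifnot(length(synapse_numbers) == 3L)
  if (any(synapse_numbers < 1L) || any(synapse_numbers > ncol(pts)))
    stop("synapse number out of range 1..", ncol(pts))
  out <- as.data.frame(pts[, synapse_numbers, drop = FALSE])
  names(out) <- c("x", "y", "z")
  out
}

#' Modality of the pairwise-distance distribution
#'
#' Bi- or polymodality of the distribution of pairwise structure distances is
#' an indicator of cluster structure: within-cluster and between-cluster
#' distances form separate modes. Smooths the distance sample with a
#' fixed-bandwidth kernel density and counts local maxima above a small
#' height floor.
#'
#' @param geometry an `nnmo_geometry` (or a [stats::dist]).
#' @param bins number of histogram bins reported.
#' @param bw kernel bandwidth; default is the data-driven [stats::bw.nrd0()]
#'   rule.
#' @param floor local maxima below `floor * max(density)` are ignored.
#' @return list: `n_modes`, `multimodal`, `histogram` (a [hist()] object,
#'   not plotted), `density` (the smoothed curve).
#' @export
distance_modality <- function(geometry, bins = 30L, bw = NULL, floor = 0.05) {
  d <- if (inherits(geometry, "nnmo_geometry")) geometry$distances else geometry
  d <- as.vector(d)
  stopifnot(length(d) >= 3L)
  if (is.null(bw)) bw <- stats::bw.nrd0(d)
  hg <- graphics::hist(d, breaks = bins, plot = FALSE)
  den <- density(d, bw = bw)
  y <- den$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] > floor * max(y)]
  list(n_modes = length(peaks), multimodal = length(peaks) >= 2L,
       histogram = hg, density = den)
}
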