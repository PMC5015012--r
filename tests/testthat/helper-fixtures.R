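# Shared fixtures and tiny independent oracles for the test suite. All
# fixtures are generated in code; nothing is read from disk.

# Deterministic toy volume: a two-region step image with optional noise.
step_volume <- function(nr = 9, nc = 9, lo = 50, hi = 150, noise_sd = 0,
                        seed = 1) {
  set.seed(seed)
  m <- matrix(lo, nr, nc)
  m[, (nc %/% 2 + 1):nc] <- hi
  if (noise_sd > 0) m <- m + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  volume(m, mask = array(TRUE, dim(m)))
}

# Three-cluster 1D sample with known ground truth.
three_cluster_sample <- function(n_per = 1000, means = c(50, 120, 200),
                                 sd_ = 5, seed = 42) {
  set.seed(seed)
  y <- c(rnorm(n_per, means[1], sd_), rnorm(n_per, means[2], sd_),
         rnorm(n_per, means[3], sd_))
  truth <- rep(1:3, each = n_per)
  list(y = y, truth = truth, means = means)
}

# A volume whose voxels are an arbitrary 1D sample (single row layout
# keeps spatial structure irrelevant).
sample_volume <- function(y) {
  volume(matrix(y, nrow = 1), mask = matrix(TRUE, 1, length(y)))
}

# Scalar reference for the normalized posterior of one intensity under a
# mixture model (independent of the package's vectorized path).
oracle_posterior <- function(y, weights, means, vars) {
  d <- weights * stats::dnorm(y, means, sqrt(vars))
  if (sum(d) == 0) rep(1 / length(weights), length(weights)) else d / sum(d)
}

# Scalar reference for the Gaussian-weighted patch distance on a 2D
# image with edge replication, written as plain loops.
oracle_patch_distance <- function(img, i, j, p, r) {
  d <- dim(img)
  clamp <- function(v, hi) pmin(pmax(v, 1), hi)
  tot <- 0
  wsum <- 0
  for (qx in -p:p) {
    for (qy in -p:p) {
      w <- exp(-(qx^2 + qy^2) / (2 * r^2))
      ai <- img[clamp(i[1] + qx, d[1]), clamp(i[2] + qy, d[2])]
      aj <- img[clamp(j[1] + qx, d[1]), clamp(j[2] + qy, d[2])]
      tot <- tot + w * (ai - aj)^2
      wsum <- wsum + w
    }
  }
  tot / wsum
}

# All-pairs scalar evaluation of the nonlocal weights at voxel i over the
# whole masked image (windowless), replicating the max-neighbor self rule.
oracle_nl_weights_allpairs <- function(vol, i, p, r, h) {
  d <- dim(vol$data)
  js <- which(vol$mask)
  subs <- arrayInd(js, d)
  wun <- numeric(length(js))
  self <- which(subs[, 1] == i[1] & subs[, 2] == i[2])
  for (t in seq_along(js)) {
    if (t == self) next
    dist <- oracle_patch_distance(vol$data, i, subs[t, ], p, r)
    wun[t] <- exp(-dist / h^2)
  }
  wun[self] <- max(wun[-self])
  list(index = js, w = wun / sum(wun))
}

# Column-major linear index of a 2D subscript (test-local convenience).
sub2ind_test <- function(sub, d) sub[1] + (sub[2] - 1) * d[1]

# Connected-component check by breadth-first flood fill (face adjacency).
is_connected_mask <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  idx <- which(mask)
  if (!length(idx)) return(FALSE)
  visited <- array(FALSE, d)
  queue <- idx[1]
  visited[idx[1]] <- TRUE
  strides <- cumprod(c(1, d[-nd]))
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    sub <- arrayInd(cur, d)
    for (ax in seq_len(nd)) {
      for (s in c(-1L, 1L)) {
        nb <- sub
        nb[ax] <- nb[ax] + s
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        lin <- 1L + sum((nb - 1L) * strides)
        if (mask[lin] && !visited[lin]) {
          visited[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
  }
  sum(visited) == sum(mask)
}

# Small phantom used by several suites: fast but large enough for the
# grid machinery.
quick_phantom <- function(noise = 5, inu = 40, seed = 1, shape = c(64, 64)) {
  simulate_phantom(phantom_spec(shape = shape, noise_level = noise,
                                inu_level = inu, seed = seed))
}
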