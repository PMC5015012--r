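# Internal n-dimensional array helpers shared by the nonlocal-means and
# multigrid code. Everything here works identically for 2D matrices and 3D
# arrays; `nd` is always taken from dim().

# S(v) = A(v + off); entries whose source falls outside A are set to `fill`.
nd_shift <- function(a, off, fill = 0) {
  d <- dim(a)
  nd <- length(d)
  off <- as.integer(off)
  src <- vector("list", nd)
  dst <- vector("list", nd)
  for (ax in seq_len(nd)) {
    lo <- max(1L, 1L - off[ax])
    hi <- min(d[ax], d[ax] - off[ax])
    if (lo > hi) {
      return(array(fill, d))
    }
    dst[[ax]] <- lo:hi
    src[[ax]] <- (lo + off[ax]):(hi + off[ax])
  }
  out <- array(fill, d)
  block <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(block)))
}

# Pad by p voxels on every side of every axis.
nd_pad <- function(a, p, mode = c("replicate", "zero")) {
  mode <- match.arg(mode)
  d <- dim(a)
  nd <- length(d)
  if (p == 0L) {
    return(a)
  }
  if (mode == "replicate") {
    idx <- lapply(seq_len(nd), function(ax) {
      c(rep(1L, p), seq_len(d[ax]), rep(d[ax], p))
    })
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  } else {
    out <- array(0, d + 2L * p)
    idx <- lapply(seq_len(nd), function(ax) p + seq_len(d[ax]))
    do.call(`[<-`, c(list(out), idx, list(a)))
  }
}

# Remove a border of p voxels, recovering an array of dimension d.
nd_crop <- function(a, p, d) {
  idx <- lapply(seq_along(d), function(ax) p + seq_len(d[ax]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# All integer offsets in [-s, s]^nd as a matrix (one row per offset,
# origin included), in a fixed deterministic order.
offset_grid <- function(s, nd) {
  g <- do.call(expand.grid, rep(list(seq.int(-s, s)), nd))
  unname(as.matrix(g))
}

# Gaussian kernel over patch offsets [-p, p]^nd with sd r, normalized to
# sum to one so that identical patches always have distance zero and the
# decay parameter h keeps intensity units.
gauss_patch_kernel <- function(p, r, nd) {
  q <- offset_grid(p, nd)
  w <- exp(-rowSums(q^2) / (2 * r^2))
  list(offsets = q, w = w / sum(w))
}

# D(v) = sum_q w(q) a(v + q) for a small kernel; zero fill off the edge.
kernel_correlate <- function(a, kern) {
  out <- array(0, dim(a))
  for (t in seq_along(kern$w)) {
    out <- out + kern$w[t] * nd_shift(a, kern$offsets[t, ], 0)
  }
  out
}

# Column-major linear index <-> array subscript conversions.
sub2ind <- function(sub, d) {
  sub <- rbind(sub)
  idx <- sub[, 1]
  mult <- 1
  for (ax in seq_along(d)[-1]) {
    mult <- mult * d[ax - 1]
    idx <- idx + (sub[, ax] - 1) * mult
  }
  as.integer(idx)
}

ind2sub <- function(ind, d) {
  nd <- length(d)
  out <- matrix(0L, length(ind), nd)
  rem <- as.integer(ind) - 1L
  for (ax in seq_len(nd)) {
    out[, ax] <- as.integer(rem %% d[ax]) + 1L
    rem <- rem %/% d[ax]
  }
  out
}
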