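#' Nonlocal weighting configuration
#'
#' Parameters of the patch-similarity weights used to regularize the
#' E-step posteriors. The weight between voxels i and j is
#' \deqn{W(i,j) \propto \exp\{-\|\Delta_i - \Delta_j\|^2_{2,r} / h^2\}}
#' where \eqn{\Delta_i} is the intensity patch of width `2*patch_radius+1`
#' around i, the patch norm is Gaussian-weighted with sd `r`, and `h`
#' controls the decay. Weights are restricted to a search window of
#' half-width `search_radius` and normalized to sum to 1 over the masked
#' voxels of the window.
#'
#' @param patch_radius patch half-width p (voxels), >= 1.
#' @param search_radius search-window half-width (voxels), >=
#'   `patch_radius`.
#' @param h decay parameter in intensity units, or `"auto"` (the default)
#'   for `10 *` the noise sd estimated from the image by
#'   [estimate_noise_sd()] (floored at 1% of the masked intensity range).
#' @param r standard deviation (voxels) of the Gaussian kernel weighting
#'   the patch norm.
#' @param self_weight_rule `"max-neighbor"` (classic nonlocal-means: the
#'   unnormalized self weight equals the maximum weight among the other
#'   window voxels, avoiding self-domination) or `"unit"` (self weight
#'   `exp(0) = 1`).
#' @return An object of class `mngmm_nl_config`.
#' @export
nonlocal_config <- function(patch_radius = 1L, search_radius = 5L,
                            h = "auto", r = 1.0,
                            self_weight_rule = c("max-neighbor", "unit")) {
  self_weight_rule <- match.arg(self_weight_rule)
  patch_radius <- as.integer(patch_radius)
  search_radius <- as.integer(search_radius)
  if (patch_radius < 1L) stop("patch_radius must be >= 1")
  if (search_radius < patch_radius) stop("search_radius must be >= patch_radius")
  if (!(identical(h, "auto") || (is.numeric(h) && h > 0))) {
    stop("h must be a positive number or \"auto\"")
  }
  if (!is.numeric(r) || r <= 0) stop("r must be > 0")
  structure(list(patch_radius = patch_radius, search_radius = search_radius,
                 h = h, r = r, self_weight_rule = self_weight_rule),
            class = "mngmm_nl_config")
}

#' Estimate the noise standard deviation of a masked image
#'
#' Robust estimate from the median absolute deviation of the discrete
#' Laplacian residual, evaluated only at voxels whose full face
#' neighborhood lies inside the mask; the MAD is divided by the L2 norm of
#' the Laplacian stencil so that the estimate is on the intensity scale.
#'
#' @param vol a [volume()].
#' @return Estimated noise sd (0 when no interior voxels exist).
#' @export
estimate_noise_sd <- function(vol) {
  vol <- as_volume(vol)
  require_brain(vol)
  d <- dim(vol$data)
  nd <- length(d)
  lap <- -2 * nd * vol$data
  inner <- array(TRUE, d)
  m <- vol$mask
  mnum <- array(as.numeric(m), d)
  for (ax in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      off <- integer(nd)
      off[ax] <- s
      lap <- lap + nd_shift(vol$data, off, 0)
      inner <- inner & (nd_shift(mnum, off, 0) > 0)
    }
  }
  inner <- inner & m
  if (!any(inner)) {
    return(0)
  }
  stencil_norm <- sqrt((2 * nd)^2 + 2 * nd)
  stats::mad(lap[inner]) / stencil_norm
}

resolve_h <- function(vol, cfg) {
  if (is.numeric(cfg$h)) {
    return(cfg$h)
  }
  y <- vol$data[vol$mask]
  rng <- diff(range(y))
  floor_h <- if (rng > 0) 0.01 * rng else 1
  max(2 * estimate_noise_sd(vol), floor_h)
}

#' Gaussian-weighted squared distance between two intensity patches
#'
#' \eqn{\|\Delta_i - \Delta_j\|^2_{2,r}}: the Gaussian-kernel-weighted
#' (sd `r`, kernel normalized to sum 1) sum of squared intensity
#' differences over the `(2p+1)^d` patches centered at voxels i and j.
#' Patches that overhang the image border are completed by edge
#' replication. Symmetric in (i, j) and zero for identical patches.
#'
#' @param vol a [volume()].
#' @param i,j voxel positions as integer subscript vectors (1-based).
#' @param cfg a [nonlocal_config()].
#' @return Scalar squared patch distance.
#' @export
patch_distance <- function(vol, i, j, cfg = nonlocal_config()) {
  vol <- as_volume(vol)
  d <- dim(vol$data)
  nd <- length(d)
  p <- cfg$patch_radius
  kern <- gauss_patch_kernel(p, cfg$r, nd)
  ipad <- nd_pad(vol$data, p, "replicate")
  pi_ <- matrix(as.integer(i) + p, nrow(kern$offsets), nd, byrow = TRUE)
  pj_ <- matrix(as.integer(j) + p, nrow(kern$offsets), nd, byrow = TRUE)
  ai <- ipad[kern$offsets + pi_]
  aj <- ipad[kern$offsets + pj_]
  sum(kern$w * (ai - aj)^2)
}

#' Nonlocal weights of one voxel over its search window
#'
#' Evaluates the normalized patch-similarity weights W(i, j) for all
#' masked voxels j in the search window centered at i (window clipped to
#' the image and the mask). The self weight follows
#' `cfg$self_weight_rule`; when the window contains only i itself the
#' weight is 1.
#'
#' @param vol a [volume()].
#' @param i voxel position, integer subscript vector; must be masked.
#' @param cfg a [nonlocal_config()].
#' @param h optional resolved decay parameter (otherwise taken from
#'   `cfg`, resolving `"auto"` from the image).
#' @return A list with `index` (linear indices of the window voxels,
#'   including i) and `w` (matching normalized weights summing to 1).
#' @export
nl_weights <- function(vol, i, cfg = nonlocal_config(), h = NULL) {
  vol <- as_volume(vol)
  d <- dim(vol$data)
  nd <- length(d)
  i <- as.integer(i)
  if (!vol$mask[matrix(i, 1)]) stop("voxel i must lie inside the mask")
  if (is.null(h)) h <- resolve_h(vol, cfg)
  offs <- offset_grid(cfg$search_radius, nd)
  jsub <- sweep(offs, 2, i, `+`)
  ok <- rep(TRUE, nrow(jsub))
  for (ax in seq_len(nd)) {
    ok <- ok & jsub[, ax] >= 1L & jsub[, ax] <= d[ax]
  }
  jsub <- jsub[ok, , drop = FALSE]
  jidx <- sub2ind(jsub, d)
  keep <- vol$mask[jidx]
  jsub <- jsub[keep, , drop = FALSE]
  jidx <- jidx[keep]
  self <- which(jidx == sub2ind(matrix(i, 1), d))
  if (length(jidx) == 1L) {
    return(list(index = jidx, w = 1))
  }
  wun <- numeric(length(jidx))
  for (t in seq_along(jidx)) {
    if (t == self) next
    wun[t] <- exp(-patch_distance(vol, i, jsub[t, ], cfg) / h^2)
  }
  wun[self] <- if (cfg$self_weight_rule == "max-neighbor") {
    max(wun[-self])
  } else {
    1
  }
  list(index = jidx, w = wun / sum(wun))
}

# Precompute the full stack of normalized nonlocal weights for a masked
# image: one weight array per search-window offset. The stack depends only
# on the intensities, so an NGMM fit computes it once and reuses it at
# every EM iteration. Offset t maps voxel i to neighbor j = i + offset[t,];
# weights at i are zero when j is outside the image or unmasked, and every
# masked voxel's weights sum to 1 across offsets.
compute_nl_stack <- function(data, mask, cfg, h) {
  d <- dim(data)
  nd <- length(d)
  p <- cfg$patch_radius
  kern <- gauss_patch_kernel(p, cfg$r, nd)
  ipad <- nd_pad(data, p, "replicate")
  mnum <- array(as.numeric(mask), d)
  offs <- offset_grid(cfg$search_radius, nd)
  origin <- which(rowSums(abs(offs)) == 0L)
  W <- vector("list", nrow(offs))
  for (t in seq_len(nrow(offs))) {
    if (t == origin) next
    off <- offs[t, ]
    sh <- nd_shift(ipad, off, 0)
    u <- (ipad - sh)^2
    dist <- nd_crop(kernel_correlate(u, kern), p, d)
    valid <- nd_shift(mnum, off, 0)
    W[[t]] <- exp(-dist / h^2) * valid
  }
  wmax <- Reduce(pmax, W[-origin])
  w0 <- wmax
  w0[wmax <= 0] <- 1  # isolated voxel: all weight on itself
  if (cfg$self_weight_rule == "unit") {
    w0 <- array(1, d)
  }
  W[[origin]] <- w0 * mnum
  tot <- Reduce(`+`, W)
  tot[tot <= 0] <- 1
  for (t in seq_along(W)) {
    W[[t]] <- W[[t]] / tot
  }
  list(offsets = offs, W = W, h = h)
}

# Apply a precomputed weight stack to a list of per-class posterior
# arrays (zero outside the mask): NLp_k(i) = sum_j W(i,j) p_k(j).
apply_nl_stack <- function(stack, fields) {
  out <- lapply(fields, function(f) array(0, dim(f)))
  for (t in seq_along(stack$W)) {
    wt <- stack$W[[t]]
    if (all(wt == 0)) next
    off <- stack$offsets[t, ]
    for (k in seq_along(fields)) {
      out[[k]] <- out[[k]] + wt * nd_shift(fields[[k]], off, 0)
    }
  }
  out
}

#' Nonlocal smoothing of a posterior field
#'
#' Replaces every masked voxel's class posteriors by their
#' nonlocal-weighted average over the search window,
#' \eqn{NLp(k \mid Y_i) = \sum_j W(i,j)\, p(k \mid Y_j)}. As a convex
#' combination of normalized rows, the output rows still sum to 1.
#'
#' @param post a [posterior_field()].
#' @param vol the [volume()] the posteriors were computed on.
#' @param cfg a [nonlocal_config()].
#' @param stack optional precomputed weight stack (internal use).
#' @return A smoothed [posterior_field()].
#' @export
smooth_posteriors <- function(post, vol, cfg = nonlocal_config(),
                              stack = NULL) {
  vol <- as_volume(vol)
  if (is.null(stack)) {
    h <- resolve_h(vol, cfg)
    stack <- compute_nl_stack(vol$data, vol$mask, cfg, h)
  }
  K <- ncol(post$values)
  d <- dim(vol$data)
  fields <- lapply(seq_len(K), function(k) {
    f <- array(0, d)
    f[post$idx] <- post$values[, k]
    f
  })
  sm <- apply_nl_stack(stack, fields)
  vals <- vapply(sm, function(f) f[post$idx], numeric(length(post$idx)))
  vals <- matrix(vals, ncol = K)
  # guard against float drift before re-validating the row sums
  vals <- vals / rowSums(vals)
  out <- posterior_field(vals, post$idx, d)
  out$loglik <- post$loglik
  out
}

#' Fit a nonlocal Gaussian mixture model (NGMM)
#'
#' Maximum-likelihood EM as in [fit_em()], followed by one nonlocal
#' adaptation of the converged posteriors: every voxel's class posterior
#' is replaced by its patch-similarity-weighted average over the search
#' window before classification. Keeping the parameter estimation and
#' the spatial regularization separate leaves the EM ascent property
#' intact and avoids the component collapse that feeding spatially
#' averaged responsibilities back into the M-step produces (each
#' averaging pass shrinks the between-class separation of the
#' responsibilities, so the EM fixed point degenerates to a single
#' effective component).
#'
#' @inheritParams fit_em
#' @param cfg a [nonlocal_config()].
#' @return A list with `model`, `posterior` (nonlocally smoothed
#'   posteriors under the fitted model), `loglik` trace, `converged` and
#'   the resolved decay `h`.
#' @export
fit_ngmm <- function(vol, init = NULL, cfg = nonlocal_config(),
                     max_iter = 100L, tol = 1e-6, var_floor = NULL) {
  vol <- as_volume(vol)
  require_brain(vol)
  if (is.null(init)) init <- init_mixture_fcm(vol)
  fit <- fit_em(vol, init = init, max_iter = max_iter, tol = tol,
                var_floor = var_floor)
  h <- resolve_h(vol, cfg)
  stack <- compute_nl_stack(vol$data, vol$mask, cfg, h)
  post <- smooth_posteriors(fit$posterior, vol, cfg, stack = stack)
  list(model = fit$model, posterior = post, loglik = fit$loglik,
       converged = fit$converged, h = h)
}
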