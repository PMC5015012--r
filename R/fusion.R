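#' Per-patch model set
#'
#' Bundles the fitted per-patch mixture models with the voxel-to-patch
#' assignment and the patch adjacency needed for fusion. Class
#' correspondence across patches is by ascending component mean
#' (CSF < GM < WM), so column k of every model refers to the same tissue.
#'
#' @param patches patch list from [merge_grids()].
#' @param models list of fitted, mean-sorted [mixture_model()]s, one per
#'   patch id.
#' @param dim dimensions of the underlying volume.
#' @return An object of class `mngmm_patch_models` with fields `models`,
#'   `home_patch` (integer array, 0 outside all patches) and
#'   `neighbor_ids`.
#' @export
patch_model_set <- function(patches, models, dim) {
  if (length(patches) != length(models)) {
    stop("need exactly one model per patch")
  }
  home <- array(0L, dim)
  for (p in patches) {
    if (any(home[p$voxels] != 0L)) {
      stop("patches overlap: every masked voxel must have exactly one home patch")
    }
    home[p$voxels] <- p$id
  }
  nb <- lapply(patches, function(p) p$neighbors)
  for (i in seq_along(nb)) {
    if (i %in% nb[[i]]) stop("a patch cannot be its own neighbor")
    for (j in nb[[i]]) {
      if (!(i %in% nb[[j]])) stop("patch neighbor relation must be symmetric")
    }
  }
  structure(list(models = models, home_patch = home, neighbor_ids = nb),
            class = "mngmm_patch_models")
}

# Posterior columns of one intensity vector under one model; underflow
# (all weighted densities zero) falls back to the uniform posterior.
model_posterior_cols <- function(y, model) {
  dens <- component_density_matrix(y, model)
  wdens <- sweep(dens, 2, model$weights, `*`)
  rs <- rowSums(wdens)
  bad <- !is.finite(rs) | rs <= 0
  out <- wdens / rs
  if (any(bad)) out[bad, ] <- 1 / model$K
  out
}

#' Posteriors of a voxel under its home and neighbor patch models
#'
#' For voxel i with home patch model \eqn{\theta_0} and neighbor models
#' \eqn{\theta_1, \dots, \theta_{N_i}}, evaluates
#' \eqn{p_{k,j} = \pi_{k,j} p(Y_i \mid \theta_{k,j}) /
#' \sum_m \pi_{m,j} p(Y_i \mid \theta_{m,j})} for every model j.
#'
#' @param vol a [volume()].
#' @param i voxel position (integer subscript vector) or linear index.
#' @param patchset a [patch_model_set()].
#' @return A K x (N_i + 1) matrix, first column the home model; model ids
#'   attached as attribute `model_ids`.
#' @export
neighbor_posteriors <- function(vol, i, patchset) {
  vol <- as_volume(vol)
  d <- dim(vol$data)
  idx <- if (length(i) > 1L) sub2ind(matrix(as.integer(i), 1), d) else as.integer(i)
  home <- patchset$home_patch[idx]
  if (home == 0L) stop("voxel has no home patch (outside the brain mask)")
  ids <- c(home, patchset$neighbor_ids[[home]])
  y <- vol$data[idx]
  cols <- vapply(ids, function(j) {
    as.numeric(model_posterior_cols(y, patchset$models[[j]]))
  }, numeric(patchset$models[[home]]$K))
  out <- matrix(cols, ncol = length(ids))
  attr(out, "model_ids") <- ids
  out
}

#' Likelihood-weighted fusion of per-model posteriors
#'
#' The fusion strategy: for every class k,
#' \deqn{F_k = \sum_{j=0}^{N_i} \frac{p(Y_i \mid \theta_{k,j})}
#' {\sum_{l=0}^{N_i} p(Y_i \mid \theta_{k,l})} \; p_{k,j}}
#' where \eqn{p(Y_i \mid \theta_{k,j})} is the weight-free class-k
#' component density under model j. Per class this is a convex
#' combination, so the fused value lies between the smallest and largest
#' contributing posterior. When every class-k density underflows, the
#' combination falls back to uniform weights. The fused vector is not
#' renormalized (the hard label is the raw argmax).
#'
#' @param y scalar intensity of the voxel.
#' @param p_cols K x M matrix of per-model posteriors (as from
#'   [neighbor_posteriors()]).
#' @param models list of the M [mixture_model()]s in matching column
#'   order.
#' @return Fused K-vector.
#' @export
fuse_posteriors <- function(y, p_cols, models) {
  K <- nrow(p_cols)
  M <- ncol(p_cols)
  dens <- vapply(models, function(mod) {
    exp(-(y - mod$means)^2 / (2 * mod$vars)) / sqrt(2 * pi * mod$vars)
  }, numeric(K))
  dens <- matrix(dens, nrow = K)
  tot <- rowSums(dens)
  w <- dens / tot
  bad <- !is.finite(tot) | tot <= 0
  if (any(bad)) w[bad, ] <- 1 / M
  rowSums(w * p_cols)
}

# Vectorized fusion for all voxels of one home patch: `vox` linear
# indices, `home_post` their smoothed home posteriors (n x K), `models`
# the home model followed by the neighbor models.
fuse_patch_voxels <- function(y, home_post, models) {
  n <- length(y)
  K <- ncol(home_post)
  M <- length(models)
  if (M == 1L) {
    return(home_post)
  }
  dens <- vector("list", M)
  pcols <- vector("list", M)
  for (m in seq_len(M)) {
    dens[[m]] <- component_density_matrix(y, models[[m]])
    pcols[[m]] <- if (m == 1L) home_post else
      model_posterior_cols(y, models[[m]])
  }
  tot <- Reduce(`+`, dens)
  fused <- matrix(0, n, K)
  for (m in seq_len(M)) {
    w <- dens[[m]] / tot
    w[tot <= 0 | !is.finite(tot)] <- 1 / M
    fused <- fused + w * pcols[[m]]
  }
  fused
}
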