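#' Segmentation result
#'
#' Container returned by the segmentation pipelines: per-class posterior
#' maps (renormalized for export), the hard label map (argmax of the raw
#' fused posteriors, ties toward the lower class), and the fitted
#' mixture model(s).
#'
#' @name segmentation_result
#' @keywords internal
NULL

make_segmentation <- function(fused, idx, d, models, mask, extras = list()) {
  K <- ncol(fused)
  k <- max.col(fused, ties.method = "first")
  lab <- array(0L, d)
  lab[idx] <- k
  norm <- fused / pmax(rowSums(fused), .Machine$double.xmin)
  posteriors <- lapply(seq_len(K), function(kk) {
    a <- array(0, d)
    a[idx] <- norm[, kk]
    a
  })
  names(posteriors) <- tissue_classes()[seq_len(K)]
  structure(c(list(posteriors = posteriors,
                   labels = label_map(lab, mask),
                   models = models),
              extras),
            class = "mngmm_segmentation")
}

#' @export
print.mngmm_segmentation <- function(x, ...) {
  tab <- tabulate(x$labels$labels + 1L, nbins = 4L)
  cat("<mngmm_segmentation> ", paste(dim(x$labels$labels), collapse = " x "),
      " | bg/CSF/GM/WM: ", paste(tab, collapse = "/"),
      " | patches: ", length(x$models), "\n", sep = "")
  invisible(x)
}

#' Plain Gaussian-mixture segmentation (baseline)
#'
#' FCM-initialized EM over all masked voxels followed by MAP
#' classification. Sensitive to both noise and intensity inhomogeneity;
#' serves as the reference the nonlocal and multigrid variants are
#' compared against.
#'
#' @param vol a [volume()].
#' @param K number of tissue classes.
#' @param max_iter,tol EM controls, see [fit_em()].
#' @return An `mngmm_segmentation`.
#' @export
segment_gmm <- function(vol, K = 3L, max_iter = 100L, tol = 1e-6) {
  vol <- as_volume(vol)
  require_brain(vol)
  fit <- fit_em(vol, init = init_mixture_fcm(vol, K = K),
                max_iter = max_iter, tol = tol)
  make_segmentation(fit$posterior$values, fit$posterior$idx, dim(vol$data),
                    list(fit$model), vol$mask,
                    extras = list(loglik = fit$loglik,
                                  converged = fit$converged))
}

#' Nonlocal Gaussian-mixture segmentation on the whole brain
#'
#' [fit_ngmm()] over all masked voxels followed by MAP classification.
#' Robust to noise but, lacking the multigrid decomposition, still
#' sensitive to strong intensity inhomogeneity.
#'
#' @param vol a [volume()].
#' @param cfg a [nonlocal_config()].
#' @param K number of tissue classes.
#' @param max_iter,tol EM controls.
#' @return An `mngmm_segmentation`.
#' @export
segment_ngmm <- function(vol, cfg = nonlocal_config(), K = 3L,
                         max_iter = 100L, tol = 1e-6) {
  vol <- as_volume(vol)
  require_brain(vol)
  fit <- fit_ngmm(vol, init = init_mixture_fcm(vol, K = K), cfg = cfg,
                  max_iter = max_iter, tol = tol)
  make_segmentation(fit$posterior$values, fit$posterior$idx, dim(vol$data),
                    list(fit$model), vol$mask,
                    extras = list(loglik = fit$loglik,
                                  converged = fit$converged, h = fit$h))
}

# Extract a patch as a standalone volume on its bounding box, with the
# mask restricted to the patch's own voxels so nonlocal windows never
# reach across patch borders (patch fits are therefore independent of
# each other and of execution order).
patch_subvolume <- function(vol, patch) {
  d <- dim(vol$data)
  sub <- ind2sub(patch$voxels, d)
  lo <- apply(sub, 2, min)
  hi <- apply(sub, 2, max)
  idx <- lapply(seq_along(d), function(ax) lo[ax]:hi[ax])
  data <- do.call(`[`, c(list(vol$data), idx, list(drop = FALSE)))
  mask <- array(FALSE, dim(data))
  local_sub <- sweep(sub, 2, lo - 1L)
  mask[local_sub] <- TRUE
  list(vol = volume(data, spacing = vol$spacing, mask = mask),
       lo = lo,
       local_idx = sub2ind(local_sub, dim(data)))
}

#' Multigrid nonlocal Gaussian-mixture segmentation (MNGMM)
#'
#' The full pipeline: the brain bounding box is tiled into an
#' `grid_n`-per-axis lattice, cells are merged into patches by the
#' inner-distance procedure ([merge_grids()]), a nonlocal Gaussian
#' mixture is fitted independently in every patch (initialized from that
#' patch's FCM centers), and every voxel's smoothed home posterior is
#' fused with the posteriors induced by the adjacent patches' models
#' using class-likelihood weights ([fuse_posteriors()]). Hard labels are
#' the argmax of the raw fused values (ties toward the lower class);
#' exported posterior maps are renormalized. A patch whose nonlocal fit
#' fails falls back to a plain EM fit with a warning.
#'
#' @param vol a [volume()] (skull-stripped, or with an explicit mask).
#' @param grid_n cells per axis of the initial grid (default 6).
#' @param alpha patch-growth control parameter (default 0.1).
#' @param n_search absorption rounds per patch; default derived via
#'   [default_n_search()].
#' @param min_fraction nonbrain-cell threshold, see [classify_nonbrain()].
#' @param cfg a [nonlocal_config()].
#' @param max_iter,tol EM controls for the per-patch fits.
#' @return An `mngmm_segmentation`; also carries `patches`, `partition`
#'   and `patch_models` for inspection.
#' @export
segment_mngmm <- function(vol, grid_n = 6L, alpha = 0.1, n_search = NULL,
                          min_fraction = 0.05, cfg = nonlocal_config(),
                          max_iter = 100L, tol = 1e-6) {
  vol <- as_volume(vol)
  require_brain(vol)
  d <- dim(vol$data)
  partition <- generate_grid(vol, grid_n)
  merged <- merge_grids(partition, vol, n_search = n_search, alpha = alpha,
                        min_fraction = min_fraction)
  patches <- merged$patches

  models <- vector("list", length(patches))
  home_post <- vector("list", length(patches))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    sv <- patch_subvolume(vol, p)
    y_local <- sv$vol$data[sv$vol$mask]
    init <- mixture_from_centers(y_local, p$stats$centers)
    fit <- tryCatch(
      fit_ngmm(sv$vol, init = init, cfg = cfg,
               max_iter = max_iter, tol = tol),
      error = function(e) {
        warning("nonlocal fit failed in patch ", p$id, " (",
                conditionMessage(e), "); falling back to plain EM")
        fit_em(sv$vol, init = init, max_iter = max_iter, tol = tol)
      }
    )
    models[[i]] <- fit$model
    # map the patch-local posterior rows back to global voxel order
    ord <- match(sv$local_idx, fit$posterior$idx)
    home_post[[i]] <- fit$posterior$values[ord, , drop = FALSE]
  }

  patchset <- patch_model_set(patches, models, d)

  idx_all <- which(vol$mask)
  K <- models[[1]]$K
  fused_all <- matrix(0, length(idx_all), K)
  row_of <- integer(prod(d))
  row_of[idx_all] <- seq_along(idx_all)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    y <- vol$data[p$voxels]
    mods <- c(list(models[[i]]), models[patchset$neighbor_ids[[i]]])
    fused <- fuse_patch_voxels(y, home_post[[i]], mods)
    fused_all[row_of[p$voxels], ] <- fused
  }

  make_segmentation(fused_all, idx_all, d, models, vol$mask,
                    extras = list(patches = patches,
                                  partition = partition,
                                  patch_models = patchset,
                                  labeling = merged$labeling,
                                  n_search = merged$n_search))
}
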