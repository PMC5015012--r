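#' Bounding box of the brain mask
#'
#' Tight axis-aligned bounding box of the masked voxels, as an integer
#' matrix with rows `lo` and `hi` (inclusive, 1-based) and one column per
#' axis.
#'
#' @param vol a [volume()].
#' @return 2 x nd integer matrix.
#' @export
brain_bbox <- function(vol) {
  vol <- as_volume(vol)
  require_brain(vol)
  d <- dim(vol$data)
  sub <- ind2sub(which(vol$mask), d)
  rbind(lo = apply(sub, 2, min), hi = apply(sub, 2, max))
}

#' Divide the brain bounding box into an N-per-axis grid
#'
#' Splits the bounding box into `n_per_axis` near-equal half-open slabs
#' per axis (remainder voxels go to the leading cells), producing an
#' N x N cell lattice for 2D images and an N x N x N lattice for volumes.
#' Cells tile the bounding box exactly and do not overlap.
#'
#' @param vol a [volume()].
#' @param n_per_axis number of cells per axis (default 6).
#' @return An object of class `mngmm_grid` with fields `n_per_axis`,
#'   `cell_dim`, `bounds` (per-cell 2 x nd lo/hi matrices, in volume
#'   coordinates), `brain_bbox`, `N_grid` (voxel count of a full cell)
#'   and `dim`.
#' @export
generate_grid <- function(vol, n_per_axis = 6L) {
  vol <- as_volume(vol)
  n <- as.integer(n_per_axis)
  if (n < 2L) stop("n_per_axis must be >= 2")
  bbox <- brain_bbox(vol)
  d <- dim(vol$data)
  nd <- length(d)
  ext <- bbox["hi", ] - bbox["lo", ] + 1L
  if (any(ext < n)) {
    stop("brain bounding box (", paste(ext, collapse = "x"),
         ") is smaller than ", n, " voxels on some axis")
  }
  widths <- vector("list", nd)
  starts <- vector("list", nd)
  for (ax in seq_len(nd)) {
    w <- rep(ext[ax] %/% n, n)
    rem <- ext[ax] %% n
    if (rem > 0L) w[seq_len(rem)] <- w[seq_len(rem)] + 1L
    widths[[ax]] <- as.integer(w)
    starts[[ax]] <- bbox["lo", ax] + c(0L, cumsum(w)[-n])
  }
  cell_dim <- rep(n, nd)
  ncell <- prod(cell_dim)
  bounds <- vector("list", ncell)
  csub <- ind2sub(seq_len(ncell), cell_dim)
  for (c_ in seq_len(ncell)) {
    lo <- hi <- integer(nd)
    for (ax in seq_len(nd)) {
      k <- csub[c_, ax]
      lo[ax] <- starts[[ax]][k]
      hi[ax] <- starts[[ax]][k] + widths[[ax]][k] - 1L
    }
    bounds[[c_]] <- rbind(lo = lo, hi = hi)
  }
  structure(list(n_per_axis = n, cell_dim = cell_dim, bounds = bounds,
                 brain_bbox = bbox, widths = widths, starts = starts,
                 N_grid = prod(vapply(widths, function(w) w[1], integer(1))),
                 dim = d),
            class = "mngmm_grid")
}

#' @export
print.mngmm_grid <- function(x, ...) {
  cat("<mngmm_grid> ", paste(x$cell_dim, collapse = " x "),
      " cells over bbox ",
      paste(x$brain_bbox["hi", ] - x$brain_bbox["lo", ] + 1L, collapse = "x"),
      " | full-cell size ", x$N_grid, "\n", sep = "")
  invisible(x)
}

# Integer array mapping every voxel to its cell id (NA outside the bbox).
cell_index_array <- function(partition, d) {
  nd <- length(d)
  axidx <- vector("list", nd)
  for (ax in seq_len(nd)) {
    v <- rep(NA_integer_, d[ax])
    lo <- partition$brain_bbox["lo", ax]
    hi <- partition$brain_bbox["hi", ax]
    v[lo:hi] <- rep(seq_len(partition$n_per_axis), times = partition$widths[[ax]])
    axidx[[ax]] <- v
  }
  sub <- ind2sub(seq_len(prod(d)), d)
  cs <- matrix(0L, nrow(sub), nd)
  for (ax in seq_len(nd)) {
    cs[, ax] <- axidx[[ax]][sub[, ax]]
  }
  out <- array(NA_integer_, d)
  ok <- rowSums(is.na(cs)) == 0
  out[ok] <- sub2ind(cs[ok, , drop = FALSE], partition$cell_dim)
  out
}

# Per-cell masked voxel linear indices.
cell_mask_voxels <- function(partition, vol) {
  cells <- cell_index_array(partition, dim(vol$data))
  idx <- which(vol$mask)
  split(idx, factor(cells[idx], levels = seq_len(prod(partition$cell_dim))))
}

# Face adjacency (4-neighborhood in 2D, 6 in 3D) between grid cells.
cell_adjacency <- function(cell_dim) {
  ncell <- prod(cell_dim)
  nd <- length(cell_dim)
  sub <- ind2sub(seq_len(ncell), cell_dim)
  adj <- vector("list", ncell)
  for (c_ in seq_len(ncell)) {
    nb <- integer(0)
    for (ax in seq_len(nd)) {
      for (s in c(-1L, 1L)) {
        q <- sub[c_, ]
        q[ax] <- q[ax] + s
        if (q[ax] >= 1L && q[ax] <= cell_dim[ax]) {
          nb <- c(nb, sub2ind(matrix(q, 1), cell_dim))
        }
      }
    }
    adj[[c_]] <- sort(nb)
  }
  adj
}

#' FCM statistics of a cell or patch
#'
#' Runs fuzzy c-means with K = 3 on a set of masked intensities and
#' reports the ascending centers `(C_CSF, C_GM, C_WM)` and the inner
#' distance `min(|C_CSF - C_GM|, |C_WM - C_GM|)`. A small inner distance
#' flags a region that is missing one of the three tissues. Degenerate
#' regions (fewer than 3 distinct intensities) get inner distance 0 so
#' that they merge earliest.
#'
#' @param vol a [volume()].
#' @param voxels integer linear indices of the region's masked voxels.
#' @param max_n deterministic stride cap on the FCM sample size.
#' @return A list with `centers`, `inner_distance`, `n_brain_voxels` and
#'   `degenerate`.
#' @export
grid_stats <- function(vol, voxels, max_n = 20000L) {
  vol <- as_volume(vol)
  y <- vol$data[voxels]
  n <- length(y)
  if (n < 1L) stop("grid_stats needs at least one masked voxel")
  if (length(unique(y)) < 3L) {
    cs <- rep(mean(y), 3)
    return(list(centers = cs, inner_distance = 0, n_brain_voxels = n,
                degenerate = TRUE))
  }
  ys <- if (n > max_n) y[round(seq(1L, n, length.out = max_n))] else y
  fc <- fcm_fit(ys, 3L)
  inner <- min(diff(fc$centers))
  list(centers = fc$centers, inner_distance = max(0, inner),
       n_brain_voxels = n, degenerate = fc$degenerate)
}

#' Mark grid cells with too little brain tissue as nonbrain
#'
#' Cells whose masked-voxel fraction is below `min_fraction` of the cell
#' volume get label -1 in the patch-label matrix L; all other cells start
#' unlabeled (0).
#'
#' @param partition a [generate_grid()] result.
#' @param vol the matching [volume()].
#' @param min_fraction minimum masked fraction for a cell to count as
#'   brain (default 0.05).
#' @return An object of class `mngmm_patch_labeling` with fields `L`
#'   (integer array over cells: -1 nonbrain, 0 unlabeled, >= 1 patch id)
#'   and `next_id`.
#' @export
classify_nonbrain <- function(partition, vol, min_fraction = 0.05) {
  vol <- as_volume(vol)
  cv <- cell_mask_voxels(partition, vol)
  counts <- lengths(cv)
  sizes <- vapply(partition$bounds, function(b) {
    prod(b["hi", ] - b["lo", ] + 1L)
  }, numeric(1))
  L <- array(0L, partition$cell_dim)
  L[counts / sizes < min_fraction] <- -1L
  if (all(L == -1L)) stop("every grid cell was classified as nonbrain")
  structure(list(L = L, next_id = 1L), class = "mngmm_patch_labeling")
}

#' Default number of grid-absorption rounds
#'
#' The per-patch growth budget `N_search = floor(alpha * N_brain /
#' N_grid)` (clamped to at least 1): each patch may absorb that many
#' cells during the growth phase, which keeps patches below an
#' `alpha` fraction of the brain.
#'
#' @param partition a [generate_grid()] result.
#' @param vol the matching [volume()].
#' @param alpha control parameter (default 0.1).
#' @return Integer count.
#' @export
default_n_search <- function(partition, vol, alpha = 0.1) {
  max(1L, as.integer(floor(alpha * n_brain(vol) / partition$N_grid)))
}

patch_bbox_of_cells <- function(partition, cells) {
  b <- partition$bounds[cells]
  lo <- apply(vapply(b, function(x) x["lo", ], numeric(ncol(b[[1]]))), 1, min)
  hi <- apply(vapply(b, function(x) x["hi", ], numeric(ncol(b[[1]]))), 1, max)
  rbind(lo = lo, hi = hi)
}

extent_ok <- function(partition, cells) {
  bb <- patch_bbox_of_cells(partition, cells)
  ext <- bb["hi", ] - bb["lo", ] + 1
  brain_ext <- partition$brain_bbox["hi", ] - partition$brain_bbox["lo", ] + 1
  all(ext <= ceiling(brain_ext / 2))
}

#' Merge grid cells into patches by the inner-distance procedure
#'
#' Implements the six-step combine process. After per-cell FCM scoring,
#' the loop repeatedly (Step 3) seeds a new patch at the unlabeled brain
#' cell with the smallest inner distance, then (Step 4) grows it
#' `n_search` times by tentatively combining each unlabeled adjacent cell
#' and permanently absorbing the one whose combined patch has the largest
#' inner distance, subject to the constraint that a patch spans at most
#' half of the brain region per axis. When all brain cells are labeled
#' (Step 5), single-cell patches are absorbed into the adjacent patch
#' with the largest combined inner distance (Step 6; the extent
#' constraint is relaxed there, since removing single cells takes
#' priority). All tie-breaks are deterministic: smallest cell id for the
#' worst grid, largest brain-voxel count then smallest cell id for the
#' preferred absorption.
#'
#' Masked voxels falling in nonbrain cells (below the `min_fraction`
#' threshold) are attached to the adjacent patch with the most brain
#' voxels, so the final patches partition all of `N_brain`.
#'
#' @param partition a [generate_grid()] result.
#' @param vol the matching [volume()].
#' @param n_search absorption rounds per patch; default
#'   [default_n_search()]. 0 is allowed (every brain cell seeds its own
#'   patch and Step 6 does all the merging).
#' @param alpha control parameter for the default `n_search`.
#' @param labeling optional [classify_nonbrain()] result.
#' @param min_fraction passed to [classify_nonbrain()] when `labeling` is
#'   not supplied.
#' @param degenerate_ratio after single-cell merging, a patch whose
#'   recomputed inner distance falls below `degenerate_ratio` times the
#'   median over all patches is treated as missing a tissue class and is
#'   absorbed into its preferred neighbor by the same rule (subject to
#'   the extent constraint). 0 disables the pass.
#' @param consistency_ratio cross-patch class-consistency threshold. The
#'   bias field is smooth, so the WM (and CSF) centers of adjacent
#'   patches may differ only by the local bias drift; a patch whose top
#'   center is below `consistency_ratio` times the median of its
#'   neighbors' top centers (or whose bottom center exceeds the
#'   neighbors' median by the inverse factor) has its three centers
#'   fitted to fewer than three real tissues, and it is absorbed like a
#'   single grid. The default 0.75 sits between the plausible
#'   adjacent-patch bias drift (under ~20%) and the GM/WM intensity
#'   ratio (~0.6) that a missing top class produces. 0 disables the
#'   pass.
#' @return A list with `labeling` (final `mngmm_patch_labeling`; ids
#'   contiguous 1..P), `patches` (list of patch objects with `id`,
#'   `cells`, `voxels`, `stats`, `bbox`, `n_voxels`, `neighbors`),
#'   `selection_order` (cell seeded first is the globally worst grid) and
#'   `n_search`.
#' @export
merge_grids <- function(partition, vol, n_search = NULL, alpha = 0.1,
                        labeling = NULL, min_fraction = 0.05,
                        degenerate_ratio = 0.5, consistency_ratio = 0.75) {
  vol <- as_volume(vol)
  if (is.null(labeling)) {
    labeling <- classify_nonbrain(partition, vol, min_fraction)
  }
  if (is.null(n_search)) {
    n_search <- default_n_search(partition, vol, alpha)
  }
  n_search <- as.integer(n_search)
  if (n_search * partition$N_grid > alpha * n_brain(vol) &&
      n_search > 1L) {
    warning("n_search * N_grid exceeds alpha * N_brain; ",
            "patches may grow beyond an alpha fraction of the brain")
  }
  L <- labeling$L
  ncell <- length(L)
  cv <- cell_mask_voxels(partition, vol)
  adj <- cell_adjacency(partition$cell_dim)
  brain <- which(L != -1L)
  inner0 <- rep(Inf, ncell)
  for (c_ in brain) {
    inner0[c_] <- grid_stats(vol, cv[[c_]])$inner_distance
  }
  patch_cells <- list()
  selection_order <- integer(0)
  next_id <- 1L

  combined_inner <- function(cells) {
    grid_stats(vol, unlist(cv[cells], use.names = FALSE))$inner_distance
  }

  # Steps 3-5: seed at the worst grid, grow n_search times
  repeat {
    unl <- which(L == 0L)
    if (!length(unl)) break
    seed <- unl[which.min(inner0[unl])]
    L[seed] <- next_id
    selection_order <- c(selection_order, seed)
    cells <- seed
    if (n_search > 0L) {
      for (round_ in seq_len(n_search)) {
        cand <- unique(unlist(adj[cells], use.names = FALSE))
        cand <- cand[L[cand] == 0L]
        cand <- cand[vapply(cand, function(c_) {
          extent_ok(partition, c(cells, c_))
        }, logical(1))]
        if (!length(cand)) break
        score <- vapply(cand, function(c_) combined_inner(c(cells, c_)),
                        numeric(1))
        nvox <- lengths(cv[cand])
        best <- order(-score, -nvox, cand)[1]
        cells <- c(cells, cand[best])
        L[cand[best]] <- next_id
      }
    }
    patch_cells[[next_id]] <- sort(cells)
    next_id <- next_id + 1L
  }

  # Step 6: absorb single-cell patches into their best neighbor patch
  kept_single <- integer(0)
  repeat {
    sizes <- lengths(patch_cells)
    singles <- setdiff(which(sizes == 1L), kept_single)
    if (!length(singles)) break
    s <- singles[1]
    cell <- patch_cells[[s]]
    nb_patches <- unique(L[adj[[cell]]])
    nb_patches <- nb_patches[nb_patches > 0L & nb_patches != s]
    if (!length(nb_patches)) {
      warning("grid cell ", cell, " is geometrically isolated; ",
              "it remains a single-cell patch")
      kept_single <- c(kept_single, s)
      next
    }
    score <- vapply(nb_patches, function(pid) {
      combined_inner(c(patch_cells[[pid]], cell))
    }, numeric(1))
    nvox <- vapply(nb_patches, function(pid) {
      sum(lengths(cv[patch_cells[[pid]]]))
    }, numeric(1))
    best <- nb_patches[order(-score, -nvox, nb_patches)[1]]
    patch_cells[[best]] <- sort(c(patch_cells[[best]], cell))
    L[cell] <- best
    patch_cells[[s]] <- integer(0)
  }

  # a patch whose inner distance is far below the median over patches is
  # missing a tissue class (its three FCM centers crowd together); such a
  # model cannot support per-class fusion, so absorb the patch into its
  # preferred neighbor exactly as in the single-grid step
  # absorbing a degenerate patch takes priority over the extent
  # constraint (as in the single-grid step): prefer extent-satisfying
  # neighbors, relax when none qualifies
  absorb_patch <- function(s) {
    nb_patches <- unique(L[unlist(adj[patch_cells[[s]]],
                                  use.names = FALSE)])
    nb_patches <- nb_patches[nb_patches > 0L & nb_patches != s]
    if (!length(nb_patches)) {
      return(FALSE)
    }
    fits <- nb_patches[vapply(nb_patches, function(pid) {
      extent_ok(partition, c(patch_cells[[pid]], patch_cells[[s]]))
    }, logical(1))]
    if (length(fits)) nb_patches <- fits
    score <- vapply(nb_patches, function(pid) {
      combined_inner(c(patch_cells[[pid]], patch_cells[[s]]))
    }, numeric(1))
    nvox <- vapply(nb_patches, function(pid) {
      sum(lengths(cv[patch_cells[[pid]]]))
    }, numeric(1))
    best <- nb_patches[order(-score, -nvox, nb_patches)[1]]
    patch_cells[[best]] <<- sort(c(patch_cells[[best]], patch_cells[[s]]))
    L[patch_cells[[s]]] <<- best
    patch_cells[[s]] <<- integer(0)
    TRUE
  }

  if (degenerate_ratio > 0) {
    stuck <- integer(0)
    repeat {
      alive <- setdiff(which(lengths(patch_cells) > 0L), stuck)
      if (length(alive) < 2L) break
      inner_p <- vapply(alive, function(pid) {
        combined_inner(patch_cells[[pid]])
      }, numeric(1))
      med <- stats::median(inner_p)
      bad <- alive[inner_p < degenerate_ratio * med]
      if (!length(bad)) break
      s <- bad[which.min(inner_p[match(bad, alive)])]
      if (!absorb_patch(s)) stuck <- c(stuck, s)
    }
  }

  # cross-patch class-consistency pass: under a smooth bias field the
  # rank-matched class centers of adjacent patches can only drift by the
  # local bias change; a patch whose extreme centers disagree with its
  # neighbors by more than that has fitted its K centers to fewer than K
  # real tissues and is absorbed into its preferred neighbor
  if (consistency_ratio > 0) {
    stuck <- integer(0)
    repeat {
      alive <- setdiff(which(lengths(patch_cells) > 0L), stuck)
      if (length(alive) < 2L) break
      centers_p <- lapply(alive, function(pid) {
        grid_stats(vol, unlist(cv[patch_cells[[pid]]],
                               use.names = FALSE))$centers
      })
      names(centers_p) <- alive
      nb_of <- lapply(alive, function(pid) {
        nb <- unique(L[unlist(adj[patch_cells[[pid]]], use.names = FALSE)])
        nb[nb > 0L & nb != pid]
      })
      offend <- rep(1, length(alive))
      for (t in seq_along(alive)) {
        nb <- intersect(nb_of[[t]], alive)
        if (!length(nb)) next
        nb_c <- centers_p[as.character(nb)]
        top_ratio <- centers_p[[t]][3] /
          stats::median(vapply(nb_c, function(cc) cc[3], numeric(1)))
        bot_ratio <- stats::median(vapply(nb_c, function(cc) cc[1],
                                          numeric(1))) /
          max(centers_p[[t]][1], .Machine$double.eps)
        offend[t] <- min(top_ratio, bot_ratio)
      }
      worst <- which.min(offend)
      if (offend[worst] >= consistency_ratio) break
      if (!absorb_patch(alive[worst])) stuck <- c(stuck, alive[worst])
    }
  }

  # renumber ids contiguously in order of first appearance
  keep <- which(lengths(patch_cells) > 0L)
  newL <- array(ifelse(L > 0L, match(L, keep), L), dim(L))
  patch_cells <- patch_cells[keep]

  # attach masked voxels stranded in nonbrain cells to the adjacent
  # patch with the most brain voxels (nearest patch cell if none adjacent)
  extra <- lapply(seq_along(patch_cells), function(i) integer(0))
  orphan_cells <- which(L == -1L & lengths(cv) > 0L)
  if (length(orphan_cells)) {
    patch_nvox <- vapply(patch_cells, function(cs) sum(lengths(cv[cs])),
                         numeric(1))
    csub_all <- ind2sub(seq_len(ncell), partition$cell_dim)
    for (c_ in orphan_cells) {
      nb <- unique(newL[adj[[c_]]])
      nb <- nb[nb > 0L]
      if (length(nb)) {
        target <- nb[order(-patch_nvox[nb], nb)[1]]
      } else {
        # nearest labeled cell by lattice distance
        labeled <- which(newL > 0L)
        dist <- rowSums(abs(csub_all[labeled, , drop = FALSE] -
                              matrix(csub_all[c_, ], length(labeled),
                                     ncol(csub_all), byrow = TRUE)))
        target <- newL[labeled[which.min(dist)]]
      }
      extra[[target]] <- c(extra[[target]], cv[[c_]])
    }
  }

  patches <- vector("list", length(patch_cells))
  for (i in seq_along(patch_cells)) {
    vox <- sort(c(unlist(cv[patch_cells[[i]]], use.names = FALSE),
                  extra[[i]]))
    relaxed <- !extent_ok(partition, patch_cells[[i]])
    patches[[i]] <- list(
      id = i,
      cells = patch_cells[[i]],
      voxels = vox,
      stats = grid_stats(vol, vox),
      bbox = patch_bbox_of_cells(partition, patch_cells[[i]]),
      n_voxels = length(vox),
      extent_relaxed = relaxed
    )
    if (relaxed) {
      message("patch ", i, " exceeds half the brain extent ",
              "(absorption of a degenerate patch took priority)")
    }
  }

  # patch adjacency via face-adjacent cells
  cell_patch <- as.integer(newL)
  for (i in seq_along(patches)) {
    nb <- unique(cell_patch[unlist(adj[patches[[i]]$cells],
                                   use.names = FALSE)])
    patches[[i]]$neighbors <- sort(nb[nb > 0L & nb != i])
  }

  labeling$L <- newL
  labeling$next_id <- length(patches) + 1L
  list(labeling = labeling, patches = patches,
       selection_order = selection_order, n_search = n_search)
}
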