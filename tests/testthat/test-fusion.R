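# Hand-built two-patch setting reused across the fusion tests.
two_patch_setting <- function() {
  m <- matrix(0, 10, 10)
  m[, 1:5] <- 100
  m[, 6:10] <- 120
  v <- volume(m, mask = matrix(TRUE, 10, 10))
  p1 <- list(id = 1L, cells = 1L, voxels = which(col(m) <= 5),
             neighbors = 2L, n_voxels = 50L)
  p2 <- list(id = 2L, cells = 2L, voxels = which(col(m) > 5),
             neighbors = 1L, n_voxels = 50L)
  m1 <- mixture_model(c(0.3, 0.4, 0.3), c(40, 100, 170), c(60, 80, 90))
  m2 <- mixture_model(c(0.2, 0.5, 0.3), c(55, 120, 200), c(70, 100, 120))
  list(vol = v, patchset = patch_model_set(list(p1, p2), list(m1, m2),
                                           dim(m)),
       models = list(m1, m2))
}

test_that("patch_model_set validates coverage and symmetry", {
  s <- two_patch_setting()
  expect_s3_class(s$patchset, "mngmm_patch_models")
  expect_true(all(s$patchset$home_patch %in% 1:2))

  bad <- list(list(id = 1L, voxels = 1:4, neighbors = 2L),
              list(id = 2L, voxels = 4:8, neighbors = 1L))
  expect_error(patch_model_set(bad, s$models, c(3, 3)), "overlap")

  asym <- list(list(id = 1L, voxels = 1:4, neighbors = 2L),
               list(id = 2L, voxels = 5:9, neighbors = integer(0)))
  expect_error(patch_model_set(asym, s$models, c(3, 3)), "symmetric")
})

test_that("neighbor posteriors match a scalar evaluation per model", {
  s <- two_patch_setting()
  for (i in list(c(3, 2), c(8, 9), c(1, 6))) {
    cols <- neighbor_posteriors(s$vol, i, s$patchset)
    ids <- attr(cols, "model_ids")
    y <- s$vol$data[i[1], i[2]]
    for (jj in seq_along(ids)) {
      mod <- s$models[[ids[jj]]]
      expect_equal(cols[, jj],
                   oracle_posterior(y, mod$weights, mod$means, mod$vars),
                   tolerance = 1e-12)
      expect_equal(sum(cols[, jj]), 1, tolerance = 1e-12)
    }
  }
})

test_that("a voxel with no neighbor patches keeps its home posterior", {
  m <- matrix(50, 6, 6)
  v <- volume(m, mask = matrix(TRUE, 6, 6))
  p <- list(id = 1L, voxels = seq_len(36), neighbors = integer(0))
  mod <- mixture_model(c(0.5, 0.5), c(40, 80), c(30, 30))
  ps <- patch_model_set(list(p), list(mod), c(6, 6))
  cols <- neighbor_posteriors(v, c(2, 2), ps)
  expect_equal(ncol(cols), 1L)
  fused <- fuse_posteriors(50, cols, list(mod))
  expect_equal(fused, as.numeric(cols[, 1]), tolerance = 1e-12)
})

test_that("identical models in all patches fuse to the home posterior", {
  mod <- mixture_model(c(0.3, 0.3, 0.4), c(30, 90, 150), c(40, 40, 40))
  pcols <- replicate(3, oracle_posterior(85, mod$weights, mod$means,
                                         mod$vars))
  fused <- fuse_posteriors(85, pcols, list(mod, mod, mod))
  expect_equal(fused, pcols[, 1], tolerance = 1e-12)
})

test_that("fusion matches an independent scalar evaluation of the strategy", {
  set.seed(61)
  models <- lapply(1:3, function(j) {
    mixture_model(rep(1 / 3, 3), sort(runif(3, 20, 220)), runif(3, 30, 120))
  })
  for (y in c(35, 88, 140, 210)) {
    pcols <- vapply(models, function(mod) {
      oracle_posterior(y, mod$weights, mod$means, mod$vars)
    }, numeric(3))
    # direct transcription of the fusion strategy
    want <- numeric(3)
    for (k in 1:3) {
      lik <- vapply(models, function(mod) {
        dnorm(y, mod$means[k], sqrt(mod$vars[k]))
      }, numeric(1))
      want[k] <- sum(lik / sum(lik) * pcols[k, ])
    }
    got <- fuse_posteriors(y, pcols, models)
    expect_equal(got, want, tolerance = 1e-12)
    # per-class convexity
    expect_true(all(got >= apply(pcols, 1, min) - 1e-12))
    expect_true(all(got <= apply(pcols, 1, max) + 1e-12))
  }
})

test_that("vectorized patch fusion equals the per-voxel operation", {
  s <- two_patch_setting()
  y <- c(60, 100, 145, 199)
  home <- t(vapply(y, function(yy) {
    oracle_posterior(yy, s$models[[1]]$weights, s$models[[1]]$means,
                     s$models[[1]]$vars)
  }, numeric(3)))
  got <- mngmm:::fuse_patch_voxels(y, home, s$models)
  for (i in seq_along(y)) {
    expect_equal(got[i, ],
                 fuse_posteriors(y[i], cbind(home[i, ],
                                             oracle_posterior(y[i],
                                               s$models[[2]]$weights,
                                               s$models[[2]]$means,
                                               s$models[[2]]$vars)),
                                 s$models),
                 tolerance = 1e-12)
  }
})

test_that("class-likelihood underflow falls back to uniform model weights", {
  m1 <- mixture_model(c(0.5, 0.5), c(0, 1), c(1e-4, 1e-4))
  m2 <- mixture_model(c(0.5, 0.5), c(0, 1), c(1e-4, 1e-4))
  pcols <- cbind(c(0.3, 0.7), c(0.6, 0.4))
  fused <- fuse_posteriors(1e5, pcols, list(m1, m2))
  expect_equal(fused, rowMeans(pcols), tolerance = 1e-12)
})

test_that("MNGMM equals plain GMM labels on a clean phantom", {
  ph <- quick_phantom(noise = 0, inu = 0, seed = 11, shape = c(64, 64))
  a <- segment_mngmm(ph$intensity)
  b <- segment_gmm(ph$intensity)
  expect_equal(a$labels$labels, b$labels$labels)
})

test_that("a single-patch configuration reduces MNGMM to NGMM", {
  # dense three-tissue disk in one corner plus a few stray voxels that
  # stretch the bounding box: every other grid cell is nonbrain, so the
  # merge yields exactly one patch and fusion must be the identity
  set.seed(19)
  m <- matrix(0, 60, 60)
  for (i in 5:25) {
    for (j in 5:25) {
      r2 <- (i - 15)^2 + (j - 15)^2
      if (r2 <= 100) {
        m[i, j] <- if (r2 <= 30) 180 else if (r2 <= 70) 110 else 50
      }
    }
  }
  m <- m + matrix(rnorm(3600, 0, 4), 60, 60) * (m > 0)
  m[c(2, 58), 58] <- 110
  m[58, 2] <- 110
  v <- volume(m, mask = m != 0)
  a <- suppressWarnings(segment_mngmm(v, grid_n = 2, n_search = 0))
  expect_equal(length(a$patches), 1L)
  b <- segment_ngmm(v)
  agree <- mean((a$labels$labels == b$labels$labels)[v$mask])
  expect_gt(agree, 0.999)
})

test_that("MNGMM beats plain GMM under a strong bias field", {
  ph <- simulate_phantom(phantom_spec(shape = c(96, 96), noise_level = 5,
                                      inu_level = 80, seed = 13))
  em <- evaluate_segmentation(segment_gmm(ph$intensity), ph$truth)
  mm <- evaluate_segmentation(segment_mngmm(ph$intensity), ph$truth)
  expect_true(all(mm$js_per_class > em$js_per_class))
})

test_that("fusion lowers label disagreement across patch boundaries", {
  ph <- simulate_phantom(phantom_spec(shape = c(96, 96), noise_level = 5,
                                      inu_level = 60, seed = 14))
  v <- ph$intensity
  res <- segment_mngmm(v)
  home <- res$patch_models$home_patch
  d <- dim(home)
  # voxel pairs straddling a patch boundary
  lab_fused <- res$labels$labels
  # unfused per-patch labels: argmax of each patch's own NGMM posterior
  lab_home <- array(0L, d)
  part <- res$partition
  mg_patches <- res$patches
  for (p in mg_patches) {
    sv <- mngmm:::patch_subvolume(v, p)
    fit <- fit_ngmm(sv$vol, init = mngmm:::mixture_from_centers(
      sv$vol$data[sv$vol$mask], p$stats$centers))
    k <- max.col(fit$posterior$values[match(sv$local_idx,
                                            fit$posterior$idx), ],
                 ties.method = "first")
    lab_home[p$voxels] <- k
  }
  boundary_disagreement <- function(lab) {
    bad <- 0L
    for (off in list(c(1, 0), c(0, 1))) {
      a <- lab
      b <- mngmm:::nd_shift(lab, off, 0L)
      hb <- mngmm:::nd_shift(home, off, 0L)
      sel <- home > 0 & hb > 0 & home != hb
      bad <- bad + sum(a[sel] != b[sel])
    }
    bad
  }
  expect_lt(boundary_disagreement(lab_fused),
            boundary_disagreement(lab_home))
})

test_that("exported posterior maps are renormalized and in range", {
  ph <- quick_phantom(noise = 5, inu = 40, seed = 15, shape = c(64, 64))
  res <- segment_mngmm(ph$intensity)
  msk <- ph$intensity$mask
  tot <- res$posteriors$CSF + res$posteriors$GM + res$posteriors$WM
  expect_equal(tot[msk], rep(1, sum(msk)), tolerance = 1e-9)
  for (p_ in res$posteriors) {
    expect_true(all(p_[msk] >= 0 & p_[msk] <= 1 + 1e-12))
  }
  expect_true(all(tot[!msk] == 0))
})

test_that("end-to-end segmentation is deterministic", {
  ph <- quick_phantom(noise = 7, inu = 40, seed = 16, shape = c(64, 64))
  a <- segment_mngmm(ph$intensity)
  b <- segment_mngmm(ph$intensity)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_equal(a$posteriors, b$posteriors, tolerance = 0)
})
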