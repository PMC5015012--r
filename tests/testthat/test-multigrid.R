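test_that("brain_bbox is the tight box of the mask", {
  m <- matrix(0, 12, 15)
  m[3:9, 4:11] <- 1
  v <- volume(m)
  expect_equal(brain_bbox(v), rbind(lo = c(3, 4), hi = c(9, 11)))

  single <- matrix(0, 10, 12)
  single[7, 9] <- 5
  expect_equal(brain_bbox(volume(single)), rbind(lo = c(7, 9), hi = c(7, 9)))

  set.seed(2)
  rand <- matrix(rbinom(20 * 20, 1, 0.2), 20, 20)
  rand[5, 5] <- 1
  sub <- which(rand == 1, arr.ind = TRUE)
  expect_equal(brain_bbox(volume(rand)),
               rbind(lo = apply(sub, 2, min), hi = apply(sub, 2, max)),
               ignore_attr = TRUE)
})

test_that("generate_grid tiles the bounding box exactly", {
  v <- volume(matrix(1, 12, 12))
  g <- generate_grid(v, 4)
  widths <- vapply(g$bounds, function(b) diff(b[, 1]) + 1, numeric(1))
  expect_true(all(widths == 3))
  expect_equal(length(g$bounds), 16L)
  expect_equal(g$N_grid, 9)

  v13 <- volume(matrix(1, 13, 13))
  g13 <- generate_grid(v13, 4)
  expect_equal(g13$widths[[1]], c(4L, 3L, 3L, 3L))
  expect_equal(g13$widths[[2]], c(4L, 3L, 3L, 3L))

  # exhaustive membership: cells disjoint, union = bbox
  cells <- mngmm:::cell_index_array(g13, dim(v13$data))
  expect_false(any(is.na(cells)))
  expect_equal(sort(unique(as.integer(cells))), 1:16)
  expect_equal(sum(table(cells)), 169)
})

test_that("generate_grid rejects boxes smaller than the grid", {
  v <- volume(matrix(1, 4, 20))
  expect_error(generate_grid(v, 6), "smaller than")
})

test_that("grid_stats recovers the inner distance of constructed clusters", {
  set.seed(14)
  y <- c(rnorm(120, 40, 3), rnorm(120, 110, 3), rnorm(120, 180, 3))
  v <- sample_volume(y)
  st <- grid_stats(v, which(v$mask))
  expect_equal(st$inner_distance, 70, tolerance = 5)
  expect_equal(st$centers, c(40, 110, 180), tolerance = 5)

  # one-tissue cell: collapsed centers, near-zero inner distance
  flat <- sample_volume(rnorm(200, 100, 1))
  expect_lt(grid_stats(flat, which(flat$mask))$inner_distance, 5)

  # two-tissue cell scores below a three-tissue cell of the same image
  two <- sample_volume(c(rnorm(150, 40, 3), rnorm(150, 110, 3)))
  expect_lt(grid_stats(two, which(two$mask))$inner_distance,
            st$inner_distance)
})

test_that("degenerate cells get inner distance zero", {
  v <- sample_volume(rep(7, 50))
  st <- grid_stats(v, which(v$mask))
  expect_true(st$degenerate)
  expect_equal(st$inner_distance, 0)
})

test_that("classify_nonbrain thresholds the masked fraction monotonically", {
  m <- matrix(0, 24, 24)
  m[1:12, ] <- 1  # top half brain
  v <- volume(m)
  g <- generate_grid(v, 4)
  lab_full <- classify_nonbrain(g, v, min_fraction = 0.0001)
  expect_true(all(lab_full$L == 0L))

  counts <- vapply(c(0.001, 0.05, 0.5, 0.999), function(f) {
    sum(classify_nonbrain(g, v, min_fraction = f)$L == -1L)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("default_n_search follows the floored budget formula", {
  # a full 60x55 rectangle: N_brain = 3300, full cell = 10x10, so the
  # brain holds 33 full cells and alpha = 0.1 budgets floor(3.3) = 3
  v <- volume(matrix(1, 60, 55))
  g <- generate_grid(v, 6)
  expect_equal(g$N_grid, 100)
  expect_equal(n_brain(v), 33 * g$N_grid)
  expect_equal(default_n_search(g, v, alpha = 0.1), 3L)
  expect_equal(default_n_search(g, v, alpha = 0.015), 1L)  # clamp to >= 1
  expect_equal(default_n_search(g, v, alpha = 1), 33L)
})

test_that("merging conserves voxels, keeps patches connected and bounded", {
  for (seed in c(1, 4)) {
    ph <- quick_phantom(noise = 5, inu = 40, seed = seed, shape = c(64, 64))
    v <- ph$intensity
    g <- generate_grid(v, 6)
    mg <- merge_grids(g, v)
    expect_equal(sum(vapply(mg$patches, function(p) p$n_voxels, numeric(1))),
                 n_brain(v))
    ids <- vapply(mg$patches, function(p) p$id, numeric(1))
    expect_equal(ids, seq_along(mg$patches))
    all_vox <- sort(unlist(lapply(mg$patches, function(p) p$voxels)))
    expect_equal(all_vox, which(v$mask))

    brain_ext <- g$brain_bbox["hi", ] - g$brain_bbox["lo", ] + 1
    for (p in mg$patches) {
      # connectivity of the patch's cells under face adjacency
      cm <- array(FALSE, g$cell_dim)
      cm[p$cells] <- TRUE
      expect_true(is_connected_mask(cm))
      ext <- p$bbox["hi", ] - p$bbox["lo", ] + 1
      # the growth phase enforces the half-extent bound; only flagged
      # degenerate-absorption patches may exceed it
      if (!p$extent_relaxed) {
        expect_true(all(ext <= ceiling(brain_ext / 2)))
      }
      expect_gt(length(p$cells), 1L)
    }
  }
})

test_that("merging is deterministic", {
  ph <- quick_phantom(noise = 5, inu = 40, seed = 9, shape = c(64, 64))
  g <- generate_grid(ph$intensity, 6)
  a <- merge_grids(g, ph$intensity)
  b <- merge_grids(g, ph$intensity)
  expect_identical(a$labeling$L, b$labeling$L)
  expect_identical(lapply(a$patches, `[[`, "cells"),
                   lapply(b$patches, `[[`, "cells"))
})

test_that("the first seeded cell is the globally worst grid", {
  ph <- quick_phantom(noise = 5, inu = 40, seed = 2, shape = c(64, 64))
  v <- ph$intensity
  g <- generate_grid(v, 6)
  labeling <- classify_nonbrain(g, v)
  cv <- mngmm:::cell_mask_voxels(g, v)
  inner <- rep(Inf, length(labeling$L))
  for (c_ in which(labeling$L == 0L)) {
    inner[c_] <- grid_stats(v, cv[[c_]])$inner_distance
  }
  mg <- merge_grids(g, v, labeling = labeling)
  expect_equal(mg$selection_order[1], which.min(inner))
  expect_equal(min(inner), inner[mg$selection_order[1]])
})

test_that("a single-tissue cell scores worst and merges first", {
  # uniform 3-tissue statistics everywhere except one cell holding a
  # single tissue
  set.seed(55)
  m <- matrix(0, 48, 48)
  msk <- matrix(TRUE, 48, 48)
  n <- length(m)
  m[] <- sample(c(rnorm(n, 40, 4), rnorm(n, 110, 4), rnorm(n, 180, 4)), n)
  g <- generate_grid(volume(m, mask = msk), 4)
  # cell covering rows 1..12, cols 37..48 becomes single-tissue
  m[1:12, 37:48] <- rnorm(144, 110, 2)
  v <- volume(m, mask = msk)
  cells <- mngmm:::cell_index_array(g, dim(m))
  target <- cells[1, 37]
  mg <- merge_grids(g, v, n_search = 1)
  expect_equal(mg$selection_order[1], target)
  # after the first Step-3/Step-4 round the cell sits in a multi-cell patch
  expect_gt(length(mg$patches[[mg$labeling$L[target]]]$cells), 1L)
})

test_that("n_search = 0 still yields a complete labeling via Step 6", {
  ph <- quick_phantom(noise = 5, inu = 0, seed = 3, shape = c(64, 64))
  v <- ph$intensity
  g <- generate_grid(v, 6)
  mg <- merge_grids(g, v, n_search = 0)
  expect_gte(length(mg$patches), 1L)
  expect_true(all(mg$labeling$L != 0L))
  expect_equal(sum(vapply(mg$patches, function(p) p$n_voxels, numeric(1))),
               n_brain(v))
})

test_that("patch neighbor relations are symmetric and irreflexive", {
  ph <- quick_phantom(noise = 5, inu = 40, seed = 6, shape = c(64, 64))
  mg <- merge_grids(generate_grid(ph$intensity, 6), ph$intensity)
  for (p in mg$patches) {
    expect_false(p$id %in% p$neighbors)
    for (q in p$neighbors) {
      expect_true(p$id %in% mg$patches[[q]]$neighbors)
    }
  }
})
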