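# Synthetic three-tissue brain phantom: forward model Y = X * B + N with a
# known label geometry, per-tissue mean intensities, a smooth multiplicative
# bias field ("INU level") and additive noise ("noise level"), following the
# conventions of the MNI/BrainWeb simulator so that noise and inhomogeneity
# sweeps map directly onto simulator percentages.

with_phantom_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' @param shape image dimensions (2 or 3 axes, each >= 32).
#' @param tissue_means strictly increasing `(mu_CSF, mu_GM, mu_WM)`
#'   intensities.
#' @param noise_level percent; the noise sd is `noise_level/100` of the
#'   brightest tissue mean (simulator convention).
#' @param inu_level percent; the bias field spans
#'   `[1 - inu_level/200, 1 + inu_level/200]`, so 40% means 0.8-1.2.
#' @param noise_model `"gaussian"` (default, keeps moments exact) or
#'   `"rician"` (MR magnitude noise).
#' @param bias_model `"polynomial"` (default) or `"gaussian-blobs"`.
#' @param seed RNG seed; a fixed seed reproduces the phantom bit for bit.
#' @return An object of class `mngmm_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         tissue_means = c(50, 110, 180),
                         noise_level = 5, inu_level = 80,
                         noise_model = c("gaussian", "rician"),
                         bias_model = c("polynomial", "gaussian-blobs"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  bias_model <- match.arg(bias_model)
  shape <- as.integer(shape)
  if (length(shape) < 2L || length(shape) > 3L) {
    stop("shape must have 2 or 3 axes")
  }
  if (any(shape < 32L)) stop("each axis must be at least 32 voxels")
  if (length(tissue_means) != 3L || any(diff(tissue_means) <= 0)) {
    stop("tissue_means must be 3 strictly increasing intensities")
  }
  if (noise_level < 0 || inu_level < 0) stop("levels must be >= 0")
  structure(list(shape = shape, tissue_means = as.numeric(tissue_means),
                 noise_level = noise_level, inu_level = inu_level,
                 noise_model = noise_model, bias_model = bias_model,
                 seed = as.integer(seed)),
            class = "mngmm_phantom_spec")
}

# Per-axis coordinate arrays, each mapped linearly onto [-1, 1].
normalized_coords <- function(shape) {
  nd <- length(shape)
  tmpl <- array(0L, shape)
  lapply(seq_len(nd), function(ax) {
    v <- (seq_len(shape[ax]) - (shape[ax] + 1) / 2) / ((shape[ax] - 1) / 2)
    array(v[slice.index(tmpl, ax)], shape)
  })
}

#' Deterministic three-tissue label geometry
#'
#' Builds a brain-like nested structure inside an elliptical mask: an
#' outer CSF rim, a GM ribbon with sinusoidal folding, a WM core, and
#' two interior CSF pockets standing in for the ventricles. Every tissue
#' occupies at least 5% of the brain voxels and the brain mask is a
#' single connected component.
#'
#' @param shape image dimensions (each >= 32).
#' @param seed seed for the fold phases and pocket placement.
#' @return A [label_map()].
#' @export
make_geometry <- function(shape, seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 32L)) stop("each axis must be at least 32 voxels")
  nd <- length(shape)
  if (nd < 2L || nd > 3L) stop("shape must have 2 or 3 axes")
  co <- normalized_coords(shape)
  u <- co[[1]] / 0.92
  v <- co[[2]] / 0.88
  w <- if (nd == 3L) co[[3]] / 0.92 else array(0, shape)
  rho <- sqrt(u^2 + v^2 + w^2)
  theta <- atan2(v, u)
  ph <- with_phantom_seed(seed, stats::runif(6, 0, 2 * pi))
  zmod <- if (nd == 3L) 1.2 * w else 0
  # deep gyral WM folds: white matter reaches toward the cortex in every
  # sector, as in real brains, so any patch-sized region of the brain
  # contains all three tissues (the regime the mixture models assume)
  r_wm <- 0.58 + 0.17 * sin(6 * theta + ph[1] + zmod) +
    0.07 * sin(11 * theta + ph[2])
  r_gm <- 0.86 + 0.04 * sin(5 * theta + ph[3] + zmod) +
    0.03 * sin(9 * theta + ph[4])
  lab <- array(0L, shape)
  lab[rho <= 1] <- 1L            # CSF rim
  lab[rho <= r_gm] <- 2L         # GM ribbon
  lab[rho <= r_wm] <- 3L         # WM core
  # two ventricle-like CSF pockets inside the WM core
  for (s in c(-1, 1)) {
    du <- (u - s * (0.16 + 0.04 * sin(ph[6]))) / 0.11
    dv <- (v - 0.05 * sin(ph[5])) / 0.24
    dw <- if (nd == 3L) w / 0.30 else 0
    pocket <- (du^2 + dv^2 + dw^2 <= 1) & (lab == 3L)
    lab[pocket] <- 1L
  }
  frac <- tabulate(lab[lab > 0L], nbins = 3L) / sum(lab > 0L)
  if (any(frac < 0.05)) {
    stop("internal error: a tissue class fell below 5% of the brain")
  }
  label_map(lab)
}

#' Smooth multiplicative bias field
#'
#' A smooth positive field rescaled to
#' `[1 - inu_level/200, 1 + inu_level/200]` (identically 1 at level 0).
#' The `"polynomial"` model is a quadratic with a dominant linear term;
#' `"gaussian-blobs"` sums 2-4 wide Gaussians whose sd is at least a
#' quarter of the image extent. Both constructions bound the
#' voxel-to-voxel change well below `inu_level/100 / (min(shape)/4)`.
#'
#' @param shape image dimensions.
#' @param inu_level percent (see [phantom_spec()]).
#' @param model `"polynomial"` or `"gaussian-blobs"`.
#' @param seed seed for the field coefficients.
#' @return Numeric array of the given shape.
#' @export
make_bias <- function(shape, inu_level,
                      model = c("polynomial", "gaussian-blobs"), seed = 1L) {
  model <- match.arg(model)
  shape <- as.integer(shape)
  nd <- length(shape)
  if (inu_level < 0) stop("inu_level must be >= 0")
  if (inu_level == 0) {
    return(array(1, shape))
  }
  co <- normalized_coords(shape)
  f <- with_phantom_seed(seed, {
    if (model == "polynomial") {
      # dominant linear terms keep the range large relative to the
      # gradient, which bounds the voxel-to-voxel change by construction
      a_lin <- stats::runif(nd, 0.8, 1) * sample(c(-1, 1), nd, replace = TRUE)
      a_quad <- stats::runif(nd, -0.15, 0.15)
      n_cross <- nd * (nd - 1) / 2
      a_cross <- stats::runif(n_cross, -0.15, 0.15)
      out <- array(0, shape)
      for (ax in seq_len(nd)) {
        out <- out + a_lin[ax] * co[[ax]] + a_quad[ax] * co[[ax]]^2
      }
      t <- 0L
      for (ax in seq_len(nd - 1L)) {
        for (bx in (ax + 1L):nd) {
          t <- t + 1L
          out <- out + a_cross[t] * co[[ax]] * co[[bx]]
        }
      }
      out
    } else {
      nb <- sample(2:4, 1)
      out <- array(0, shape)
      for (b in seq_len(nb)) {
        ctr <- stats::runif(nd, -0.6, 0.6)
        sd_ <- stats::runif(1, 0.6, 0.9)  # in normalized units: >= 1/4 extent
        amp <- stats::runif(1, 0.5, 1)
        d2 <- array(0, shape)
        for (ax in seq_len(nd)) {
          d2 <- d2 + (co[[ax]] - ctr[ax])^2
        }
        out <- out + amp * exp(-d2 / (2 * sd_^2))
      }
      out
    }
  })
  lo <- 1 - inu_level / 200
  hi <- 1 + inu_level / 200
  rng <- range(f)
  if (diff(rng) <= 0) {
    return(array(1, shape))
  }
  array(lo + (f - rng[1]) / diff(rng) * (hi - lo), shape)
}

#' Simulate a phantom
#'
#' Forward model `Y = X * B + N`: the clean signal X is assembled from
#' the label geometry and the tissue means, multiplied by the bias field
#' B and degraded by noise with sd `noise_level/100 * max(tissue_means)`
#' (Gaussian additive, or Rician:
#' `Y = sqrt((X*B + n1)^2 + n2^2)`). Background voxels stay exactly 0
#' and the ground-truth labels are untouched by bias or noise.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `mngmm_phantom` with fields `truth`
#'   ([label_map()]), `intensity` ([volume()] with the brain mask set
#'   from the truth), `bias` and `clean`.
#' @export
simulate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "mngmm_phantom_spec"))
  truth <- make_geometry(spec$shape, seed = spec$seed)
  bias <- make_bias(spec$shape, spec$inu_level, model = spec$bias_model,
                    seed = spec$seed + 1L)
  x <- array(0, spec$shape)
  for (k in 1:3) {
    x[truth$labels == k] <- spec$tissue_means[k]
  }
  clean <- x * bias
  mask <- truth$labels > 0L
  nmask <- sum(mask)
  sd_ <- spec$noise_level / 100 * max(spec$tissue_means)
  y <- clean
  if (sd_ > 0) {
    with_phantom_seed(spec$seed + 2L, {
      if (spec$noise_model == "gaussian") {
        y[mask] <- clean[mask] + stats::rnorm(nmask, 0, sd_)
      } else {
        n1 <- stats::rnorm(nmask, 0, sd_)
        n2 <- stats::rnorm(nmask, 0, sd_)
        y[mask] <- sqrt((clean[mask] + n1)^2 + n2^2)
      }
    })
  }
  structure(list(truth = truth,
                 intensity = volume(y, mask = mask),
                 bias = bias, clean = clean, spec = spec),
            class = "mngmm_phantom")
}

#' @export
print.mngmm_phantom <- function(x, ...) {
  cat("<mngmm_phantom> ", paste(x$spec$shape, collapse = " x "),
      " | noise ", x$spec$noise_level, "% | INU ", x$spec$inu_level,
      "% | seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}
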