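#' Gaussian mixture model over voxel intensities
#'
#' A K-component univariate Gaussian mixture: the intensity density is
#' \deqn{p(y \mid \theta) = \sum_{k=1}^K \pi_k \, \mathcal{N}(y; \mu_k, \sigma^2_k)}
#' with mixing weights `weights`, means `means` and variances `vars`.
#' After fitting, components are always sorted by ascending mean so that
#' component 1 is CSF, 2 is GM and 3 is WM on T1-weighted images.
#'
#' @param weights numeric vector of mixing proportions, summing to 1.
#' @param means numeric vector of component means (intensity units).
#' @param vars numeric vector of component variances (> 0).
#' @return An object of class `mngmm_mixture` with fields `weights`,
#'   `means`, `vars` and `K`.
#' @export
mixture_model <- function(weights, means, vars) {
  K <- length(means)
  if (length(weights) != K || length(vars) != K) {
    stop("weights, means and vars must all have length K")
  }
  weights <- as.numeric(weights)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("mixture weights must be non-negative and sum to 1")
  }
  if (any(!is.finite(means))) stop("component means must be finite")
  if (any(!is.finite(vars)) || any(vars <= 0)) {
    stop("component variances must be positive")
  }
  structure(list(weights = weights, means = as.numeric(means),
                 vars = as.numeric(vars), K = K),
            class = "mngmm_mixture")
}

#' @export
print.mngmm_mixture <- function(x, ...) {
  cat("<mngmm_mixture> K =", x$K, "\n")
  print(data.frame(weight = signif(x$weights, 4),
                   mean = signif(x$means, 5),
                   var = signif(x$vars, 5)))
  invisible(x)
}

sort_mixture <- function(model) {
  o <- order(model$means)
  mixture_model(model$weights[o], model$means[o], model$vars[o])
}

#' Gaussian component density
#'
#' Density of a single mixture component,
#' \eqn{(2\pi\sigma^2)^{-1/2} \exp\{-(y-\mu)^2 / 2\sigma^2\}}. The second
#' mixture parameter is treated as a variance throughout the package (its
#' M-step update is a weighted mean of squared deviations).
#'
#' @param y numeric intensity (vectorized).
#' @param comp a list with fields `mean` and `var` (a component of a
#'   [mixture_model()]), or a numeric `c(mean, var)` pair.
#' @return Density values, strictly positive and finite.
#' @export
component_pdf <- function(y, comp) {
  if (is.numeric(comp) && length(comp) == 2L) {
    comp <- list(mean = comp[1], var = comp[2])
  }
  if (any(!is.finite(y))) stop("intensity y must be finite")
  if (!is.finite(comp$var) || comp$var <= 0) stop("component variance must be positive")
  exp(-(y - comp$mean)^2 / (2 * comp$var)) / sqrt(2 * pi * comp$var)
}

# n x K matrix of component densities (weight-free) at intensities y.
component_density_matrix <- function(y, model) {
  K <- model$K
  out <- matrix(0, length(y), K)
  for (k in seq_len(K)) {
    out[, k] <- exp(-(y - model$means[k])^2 / (2 * model$vars[k])) /
      sqrt(2 * pi * model$vars[k])
  }
  out
}

#' Posterior responsibility field
#'
#' Per-voxel class posteriors over the masked voxels of a volume: row i
#' holds \eqn{p(k \mid Y_i, \theta)} for k = 1..K. `alpha` holds the
#' per-class posterior sums \eqn{\alpha_k = \sum_i p(k \mid Y_i, \theta)}.
#'
#' @param values numeric matrix, one row per masked voxel, one column per
#'   class; rows must sum to 1.
#' @param idx integer linear indices of the masked voxels in the volume.
#' @param dim dimensions of the underlying volume.
#' @return An object of class `mngmm_posterior` with fields `values`,
#'   `alpha`, `idx`, `dim`.
#' @export
posterior_field <- function(values, idx, dim) {
  values <- as.matrix(values)
  if (nrow(values) != length(idx)) {
    stop("posterior rows must match the number of masked voxels")
  }
  if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
    stop("posterior entries must lie in [0, 1]")
  }
  rs <- rowSums(values)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("posterior rows must sum to 1")
  }
  structure(list(values = values, alpha = colSums(values),
                 idx = as.integer(idx), dim = as.integer(dim)),
            class = "mngmm_posterior")
}

#' E-step: class posteriors under a mixture model
#'
#' Computes \eqn{p(k \mid Y_i, \theta) = \pi_k p_k(Y_i) / \sum_j \pi_j p_j(Y_i)}
#' at every masked voxel, together with the per-class sums
#' \eqn{\alpha_k}. Voxels at which every weighted component density
#' underflows to zero receive the uniform posterior 1/K.
#'
#' @param vol a [volume()].
#' @param model a [mixture_model()].
#' @return A [posterior_field()]; the model log-likelihood of the masked
#'   data is attached as field `loglik`.
#' @export
e_step <- function(vol, model) {
  vol <- as_volume(vol)
  require_brain(vol)
  idx <- which(vol$mask)
  y <- vol$data[idx]
  dens <- component_density_matrix(y, model)
  wdens <- sweep(dens, 2, model$weights, `*`)
  rs <- rowSums(wdens)
  bad <- !is.finite(rs) | rs <= 0
  vals <- wdens / rs
  if (any(bad)) {
    vals[bad, ] <- 1 / model$K
  }
  pf <- posterior_field(vals, idx, dim(vol$data))
  pf$loglik <- sum(log(pmax(rs, .Machine$double.xmin)))
  pf
}

#' M-step: mixture parameter update from posteriors
#'
#' Standard weighted-moment updates over the N masked voxels:
#' \eqn{\pi_k = \alpha_k / N}, \eqn{\mu_k = \sum_i Y_i p(k \mid Y_i) / \alpha_k},
#' \eqn{\sigma^2_k = \sum_i (Y_i - \mu_k)^2 p(k \mid Y_i) / \alpha_k}.
#' Variances are floored at `var_floor`. A component whose posterior mass
#' \eqn{\alpha_k} vanishes is reseeded at the most ambiguous intensity
#' (smallest maximum posterior), with the global variance and weight 1/K.
#'
#' @param vol a [volume()].
#' @param post a [posterior_field()] from [e_step()] over the same mask.
#' @param var_floor variance floor; defaults to `1e-4 *` the global
#'   intensity variance of the masked voxels.
#' @return A [mixture_model()] (unsorted; sorting happens at the end of
#'   [fit_em()]).
#' @export
m_step <- function(vol, post, var_floor = NULL) {
  vol <- as_volume(vol)
  y <- vol$data[post$idx]
  n <- length(y)
  K <- ncol(post$values)
  gvar <- stats::var(y)
  if (!is.finite(gvar) || gvar <= 0) gvar <- 1
  if (is.null(var_floor)) var_floor <- 1e-4 * gvar
  alpha <- colSums(post$values)
  weights <- alpha / n
  means <- numeric(K)
  vars <- numeric(K)
  reseeded <- integer(0)
  for (k in seq_len(K)) {
    if (alpha[k] <= n * 1e-12) {
      # empty component: reseed at the intensity with the lowest posterior
      # coverage (most ambiguous voxel under the current responsibilities)
      i0 <- which.min(apply(post$values, 1, max))
      means[k] <- y[i0]
      vars[k] <- gvar
      weights[k] <- 1 / K
      reseeded <- c(reseeded, k)
    } else {
      means[k] <- sum(y * post$values[, k]) / alpha[k]
      vars[k] <- sum((y - means[k])^2 * post$values[, k]) / alpha[k]
    }
  }
  if (length(reseeded)) {
    warning("reseeded empty mixture component(s): ",
            paste(reseeded, collapse = ", "))
    weights <- weights / sum(weights)
  }
  vars <- pmax(vars, var_floor)
  model <- mixture_model(weights, means, vars)
  model$reseeded <- reseeded
  model
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Alternates [e_step()] and [m_step()] until the relative change in the
#' total log-likelihood drops below `tol` or `max_iter` is reached. The
#' log-likelihood trace is non-decreasing (up to variance-floor slack).
#' Components are returned sorted by ascending mean.
#'
#' @param vol a [volume()].
#' @param init initial [mixture_model()]; defaults to an FCM-based
#'   initialization via [init_mixture_fcm()].
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change below which EM stops.
#' @param var_floor see [m_step()].
#' @return A list with `model` (sorted), `posterior` (final
#'   [posterior_field()] under the sorted model), `loglik` (per-iteration
#'   trace) and `converged`.
#' @export
fit_em <- function(vol, init = NULL, max_iter = 100L, tol = 1e-6,
                   var_floor = NULL) {
  vol <- as_volume(vol)
  require_brain(vol)
  if (is.null(init)) init <- init_mixture_fcm(vol)
  model <- init
  trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    post <- e_step(vol, model)
    trace <- c(trace, post$loglik)
    if (it > 1L) {
      rel <- abs(trace[it] - trace[it - 1L]) /
        (abs(trace[it - 1L]) + .Machine$double.eps)
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
    model <- m_step(vol, post, var_floor = var_floor)
  }
  o <- order(model$means)
  model <- sort_mixture(model)
  post$values <- post$values[, o, drop = FALSE]
  post$alpha <- post$alpha[o]
  list(model = model, posterior = post, loglik = trace, converged = converged)
}

#' MAP classification from a posterior field
#'
#' Assigns every masked voxel to the class with the largest posterior
#' (ties broken toward the lower class index); background voxels keep
#' label 0.
#'
#' @param post a [posterior_field()] with K = 3 columns ordered
#'   CSF, GM, WM (or any K, in which case labels are 1..K).
#' @return A [label_map()].
#' @export
classify <- function(post) {
  lab <- array(0L, post$dim)
  k <- max.col(post$values, ties.method = "first")
  lab[post$idx] <- k
  label_map(lab)
}

#' FCM-based mixture initialization
#'
#' Runs fuzzy c-means ([fcm_fit()]) on the masked intensities and converts
#' the result into an initial mixture: means = FCM centers, variances =
#' within-cluster variances of the hard assignment, weights = cluster
#' fractions.
#'
#' @param vol a [volume()].
#' @param K number of classes (3 tissue classes by default).
#' @param max_n cap on the number of intensities passed to FCM; larger
#'   inputs are strided deterministically.
#' @return A [mixture_model()] sorted by ascending mean.
#' @export
init_mixture_fcm <- function(vol, K = 3L, max_n = 50000L) {
  vol <- as_volume(vol)
  require_brain(vol)
  y <- vol$data[vol$mask]
  if (length(y) > max_n) {
    y <- y[round(seq(1L, length(y), length.out = max_n))]
  }
  fc <- fcm_fit(y, K)
  mixture_from_centers(y, fc$centers)
}

# Hard-assign intensities to their nearest center and summarize as a
# mixture model; shared by the global and the per-patch initializers.
mixture_from_centers <- function(y, centers) {
  K <- length(centers)
  d2 <- outer(y, centers, function(a, b) (a - b)^2)
  grp <- max.col(-d2, ties.method = "first")
  gvar <- stats::var(y)
  if (!is.finite(gvar) || gvar <= 0) gvar <- max(1e-6, mean(abs(y)) * 1e-3)
  weights <- numeric(K)
  vars <- numeric(K)
  for (k in seq_len(K)) {
    nk <- sum(grp == k)
    weights[k] <- max(nk, 1) / length(y)
    vk <- if (nk > 1) stats::var(y[grp == k]) else NA_real_
    vars[k] <- if (is.finite(vk) && vk > 0) vk else 1e-2 * gvar
  }
  weights <- weights / sum(weights)
  sort_mixture(mixture_model(weights, centers, pmax(vars, 1e-6 * gvar)))
}
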