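#' Fuzzy c-means clustering of intensities
#'
#' Standard FCM on a 1D intensity sample: memberships
#' \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{ij})^{2/(m-1)}} and centers
#' \eqn{c_k = \sum_i u_{ik}^m y_i / \sum_i u_{ik}^m}, iterated until the
#' largest center movement falls below `tol`. Initial centers are the
#' K interior quantiles of the data, which makes the fit fully
#' deterministic. Used both to initialize EM and to score grid cells via
#' the inner distance.
#'
#' @param x numeric vector of intensities.
#' @param K number of clusters.
#' @param m fuzzifier (> 1); the usual default 2.
#' @param max_iter maximum iterations.
#' @param tol absolute center-change threshold for convergence.
#' @return A list with `centers` (ascending), `memberships` (n x K, rows
#'   sum to 1, columns matching the sorted centers), `objective`
#'   (per-iteration trace of \eqn{\sum u^m d^2}, non-increasing),
#'   `degenerate` (TRUE when fewer than K distinct values forced a center
#'   jitter) and `iterations`.
#' @examples
#' fcm_fit(c(10, 11, 12, 100, 101, 102), K = 2)$centers
#' @export
fcm_fit <- function(x, K, m = 2, max_iter = 200L, tol = 1e-6) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("fcm_fit needs at least one value")
  if (K < 1L) stop("K must be >= 1")
  if (m <= 1) stop("fuzzifier m must be > 1")
  n <- length(x)
  degenerate <- length(unique(x)) < K
  centers <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K,
                             names = FALSE, type = 7)
  if (anyDuplicated(centers)) {
    # deterministic jitter keeps duplicated centers distinct
    eps <- max(1e-8, 1e-8 * max(abs(x), 1))
    centers <- centers + (seq_len(K) - 1) * eps
  }
  if (K == 1L) {
    centers <- mean(x)
    u <- matrix(1, n, 1)
    obj <- sum((x - centers)^2)
    return(list(centers = centers, memberships = u, objective = obj,
                degenerate = degenerate, iterations = 1L))
  }
  ex <- 1 / (m - 1)
  obj <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    zero <- d2 < .Machine$double.eps
    inv <- d2^(-ex)
    u <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      # a point sitting exactly on >=1 center splits its membership there
      u[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    um <- u^m
    obj <- c(obj, sum(um * d2))
    mass <- colSums(um)
    new_centers <- colSums(um * x) / mass
    # a cluster with no membership mass keeps its previous center
    dead <- mass <= 0 | !is.finite(new_centers)
    new_centers[dead] <- centers[dead]
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  o <- order(centers)
  list(centers = centers[o], memberships = u[, o, drop = FALSE],
       objective = obj, degenerate = degenerate, iterations = it)
}
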