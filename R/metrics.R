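#' Jaccard similarity of one tissue class
#'
#' \eqn{JS = |A \cap B| / |A \cup B|} between the predicted and true voxel
#' sets of a class; 1 means a perfect match. An empty union (the class is
#' absent from both maps) is defined as 1.
#'
#' @param pred,truth label maps ([label_map()], segmentation results, or
#'   integer arrays) of identical shape.
#' @param cls class id in `{1 = CSF, 2 = GM, 3 = WM}`.
#' @return Jaccard value in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 2, 2), 2)
#' jaccard(a, a, 1)
#' @export
jaccard <- function(pred, truth, cls) {
  p <- as_label_array(pred)
  t_ <- as_label_array(truth)
  if (!identical(dim(p), dim(t_))) {
    stop("prediction and truth shapes differ")
  }
  if (!(cls %in% 1:3)) stop("cls must be 1 (CSF), 2 (GM) or 3 (WM)")
  a <- p == cls
  b <- t_ == cls
  uni <- sum(a | b)
  if (uni == 0L) {
    return(1)
  }
  sum(a & b) / uni
}

#' Evaluate a segmentation against ground truth
#'
#' Per-class Jaccard values, their mean, and a 4 x 4 label confusion
#' matrix. Evaluation is restricted to voxels where the truth is a brain
#' tissue (truth > 0); background is never scored.
#'
#' @param pred,truth label maps of identical shape.
#' @return An object of class `mngmm_eval` with fields `js_per_class`
#'   (named CSF/GM/WM), `mean_js`, `confusion` (rows = truth, cols =
#'   prediction, labels 0..3) and `n_evaluated`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  p <- as_label_array(pred)
  t_ <- as_label_array(truth)
  if (!identical(dim(p), dim(t_))) {
    stop("prediction and truth shapes differ")
  }
  keep <- t_ > 0L
  pv <- p[keep]
  tv <- t_[keep]
  js <- vapply(1:3, function(cls) {
    uni <- sum(pv == cls | tv == cls)
    if (uni == 0L) 1 else sum(pv == cls & tv == cls) / uni
  }, numeric(1))
  names(js) <- tissue_classes()
  conf <- table(factor(tv, levels = 0:3), factor(pv, levels = 0:3))
  structure(list(js_per_class = js, mean_js = mean(js),
                 confusion = unclass(conf), n_evaluated = sum(keep)),
            class = "mngmm_eval")
}

#' @export
print.mngmm_eval <- function(x, ...) {
  cat("<mngmm_eval> JS  CSF:", sprintf("%.4f", x$js_per_class["CSF"]),
      " GM:", sprintf("%.4f", x$js_per_class["GM"]),
      " WM:", sprintf("%.4f", x$js_per_class["WM"]),
      " mean:", sprintf("%.4f", x$mean_js), "\n")
  invisible(x)
}

#' Tabulate Jaccard values over a batch of evaluations
#'
#' Builds the per-image, per-class table with mean and standard deviation
#' rows, the reporting format used for noise and inhomogeneity sweeps.
#'
#' @param reports list of [evaluate_segmentation()] results.
#' @param ids optional image identifiers.
#' @return A data.frame with one row per image and columns
#'   `id`, `CSF`, `GM`, `WM`, `mean`; the mean and sd across images are
#'   attached as attribute `summary`.
#' @export
js_table <- function(reports, ids = seq_along(reports)) {
  m <- t(vapply(reports, function(r) r$js_per_class, numeric(3)))
  df <- data.frame(id = ids, m, mean = rowMeans(m))
  colnames(df)[2:4] <- tissue_classes()
  attr(df, "summary") <- rbind(mean = colMeans(df[, 2:5]),
                               sd = apply(df[, 2:5], 2, stats::sd))
  df
}
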