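#' Intensity volume with an optional brain mask
#'
#' The central data container: a 2D or 3D scalar intensity array together
#' with the physical voxel spacing and a logical brain mask. All model
#' fitting in this package is restricted to masked voxels. Inputs are
#' assumed skull-stripped, with zero intensity outside the brain, so when
#' no mask is supplied the default mask is `data > 0`.
#'
#' @param data numeric matrix (2D) or 3D array of intensities. Values must
#'   be finite at every masked voxel.
#' @param spacing numeric vector of per-axis voxel sizes in mm; defaults to
#'   1 on every axis.
#' @param mask optional logical array of the same shape as `data`;
#'   `TRUE` marks brain tissue. Defaults to `data > 0`.
#' @return An object of class `mngmm_volume` with fields `data`, `spacing`
#'   and `mask`.
#' @examples
#' v <- volume(matrix(c(0, 0, 10, 12), 2, 2))
#' sum(v$mask)
#' @export
volume <- function(data, spacing = NULL, mask = NULL) {
  if (is.null(dim(data))) {
    data <- matrix(data, nrow = length(data))
  }
  data <- as.array(data)
  storage.mode(data) <- "double"
  nd <- length(dim(data))
  if (nd < 2L || nd > 3L) {
    stop("volume data must be a 2D matrix or a 3D array")
  }
  if (is.null(spacing)) {
    spacing <- rep(1, nd)
  }
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must give one positive voxel size per axis")
  }
  if (is.null(mask)) {
    mask <- !is.na(data) & data > 0
  } else {
    if (!identical(dim(data), dim(mask))) {
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match data shape ", paste(dim(data), collapse = "x"))
    }
    mask <- array(as.logical(mask), dim(data))
    mask[is.na(mask)] <- FALSE
  }
  if (any(!is.finite(data[mask]))) {
    stop("intensities must be finite at every masked voxel")
  }
  structure(list(data = data, spacing = as.numeric(spacing), mask = mask),
            class = "mngmm_volume")
}

#' @export
print.mngmm_volume <- function(x, ...) {
  cat("<mngmm_volume> ", paste(dim(x$data), collapse = " x "),
      " | brain voxels: ", sum(x$mask),
      " | spacing: ", paste(signif(x$spacing, 3), collapse = ", "), " mm\n",
      sep = "")
  invisible(x)
}

as_volume <- function(x) {
  if (inherits(x, "mngmm_volume")) x else volume(x)
}

#' Number of masked (brain) voxels
#' @param vol an [volume()] object.
#' @return Integer count of `TRUE` mask entries.
#' @export
n_brain <- function(vol) {
  sum(as_volume(vol)$mask)
}

require_brain <- function(vol) {
  if (n_brain(vol) < 1L) {
    stop("volume contains no voxels inside the brain mask")
  }
  invisible(vol)
}

#' Tissue label map
#'
#' Integer labels with the fixed coding 0 = background, 1 = CSF, 2 = GM,
#' 3 = WM (ordered by expected T1 intensity, so the mixture component with
#' the lowest mean always maps to CSF).
#'
#' @param labels integer matrix/array with values in `{0, 1, 2, 3}`.
#' @param mask optional logical array; when given, labels must be 0 exactly
#'   where the mask is `FALSE`.
#' @return An object of class `mngmm_label_map` with field `labels`.
#' @export
label_map <- function(labels, mask = NULL) {
  if (inherits(labels, "mngmm_label_map")) {
    labels <- labels$labels
  }
  if (is.null(dim(labels))) {
    stop("labels must be a matrix or array")
  }
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:3)) {
    stop("labels must take values only in {0 = background, 1 = CSF, 2 = GM, 3 = WM}")
  }
  if (!is.null(mask)) {
    if (!identical(dim(labels), dim(mask))) {
      stop("mask shape does not match label shape")
    }
    if (any(labels[!mask] != 0L)) {
      stop("labels must be 0 wherever the mask is FALSE")
    }
  }
  structure(list(labels = labels), class = "mngmm_label_map")
}

#' @export
print.mngmm_label_map <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 4L)
  cat("<mngmm_label_map> ", paste(dim(x$labels), collapse = " x "),
      " | bg/CSF/GM/WM: ", paste(tab, collapse = "/"), "\n", sep = "")
  invisible(x)
}

as_label_array <- function(x) {
  if (inherits(x, "mngmm_label_map")) {
    x$labels
  } else if (inherits(x, "mngmm_segmentation")) {
    x$labels$labels
  } else {
    y <- as.array(x)
    storage.mode(y) <- "integer"
    y
  }
}

#' Tissue class names used throughout the package
#' @return `c("CSF", "GM", "WM")`.
#' @export
tissue_classes <- function() c("CSF", "GM", "WM")
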