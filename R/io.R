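# Readers and writers for the formats the package supports: NIfTI-1 /
# ANALYZE-7.5 volumes through RNifti, plus single-channel PNG and TIFF for
# 2D slices. Label images are written as unsigned 8-bit integers.

file_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.(hdr|img)(\\.gz)?$", p)) return("analyze")
  if (grepl("\\.png$", p)) return("png")
  if (grepl("\\.tiff?$", p)) return("tiff")
  stop("unrecognized image format for '", path,
       "' (supported: .nii/.nii.gz, .hdr/.img, .png, .tif/.tiff)")
}

read_image_array <- function(path) {
  fmt <- file_format(path)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  arr <- switch(fmt,
    nifti = ,
    analyze = {
      img <- tryCatch(RNifti::readNifti(path),
                      error = function(e) stop("unreadable NIfTI/ANALYZE file '",
                                               path, "': ", conditionMessage(e)))
      a <- as.array(img)
      sp <- abs(RNifti::pixdim(img))
      attributes(a) <- list(dim = dim(a))
      attr(a, "spacing") <- sp
      a
    },
    png = {
      a <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable PNG file '", path,
                                             "': ", conditionMessage(e)))
      if (length(dim(a)) == 3L) {
        if (dim(a)[3] > 1L && !all(a[, , 1] == a[, , 2])) {
          stop("PNG input must be single-channel grayscale: ", path)
        }
        a <- a[, , 1]
      }
      a
    },
    tiff = {
      a <- tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("unreadable TIFF file '", path,
                                             "': ", conditionMessage(e)))
      if (length(dim(a)) == 3L) {
        if (dim(a)[3] > 1L && !all(a[, , 1] == a[, , 2])) {
          stop("TIFF input must be single-channel grayscale: ", path)
        }
        a <- a[, , 1]
      }
      a
    }
  )
  # volumes stored as W x H x 1 are really 2D slices
  d <- dim(arr)
  sp <- attr(arr, "spacing")
  if (length(d) > 2L && any(d == 1L)) {
    keep <- d > 1L
    arr <- array(arr, d[keep])
    if (!is.null(sp)) attr(arr, "spacing") <- sp[keep]
  }
  arr
}

#' Read an intensity volume from disk
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`), ANALYZE-7.5 (`.hdr`/`.img`) or
#' single-channel PNG/TIFF images into a [volume()]. Inputs are expected to
#' be skull-stripped; when no mask image is given the brain mask defaults
#' to `data > 0`.
#'
#' @param path path to the intensity image.
#' @param mask_path optional path to a binary mask image of the same shape
#'   (non-zero = brain).
#' @return A [volume()].
#' @export
read_volume <- function(path, mask_path = NULL) {
  arr <- read_image_array(path)
  spacing <- attr(arr, "spacing")
  attr(arr, "spacing") <- NULL
  if (!is.null(spacing)) {
    spacing <- spacing[seq_along(dim(arr))]
    if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- NULL
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_image_array(mask_path)
    attr(m, "spacing") <- NULL
    if (!identical(dim(m), dim(arr))) {
      stop("mask shape ", paste(dim(m), collapse = "x"),
           " does not match image shape ", paste(dim(arr), collapse = "x"))
    }
    mask <- m != 0
  }
  volume(arr, spacing = spacing, mask = mask)
}

#' Write an intensity volume to disk
#'
#' NIfTI output preserves intensities exactly (64-bit float); TIFF output
#' uses 32-bit float samples and requires values in `[0, 1]`; PNG output is
#' 8-bit and also requires values in `[0, 1]`.
#'
#' @param vol a [volume()] or bare array.
#' @param path output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  fmt <- file_format(path)
  arr <- vol$data
  switch(fmt,
    nifti = {
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- vol$spacing
      RNifti::writeNifti(img, path, datatype = "double")
    },
    analyze = stop("writing ANALYZE pairs is not supported; use .nii/.nii.gz"),
    png = {
      if (min(arr) < 0 || max(arr) > 1) {
        stop("PNG intensity output requires values in [0, 1]; rescale first")
      }
      png::writePNG(arr, target = path)
    },
    tiff = {
      if (min(arr) < 0 || max(arr) > 1) {
        stop("TIFF intensity output requires values in [0, 1]; rescale first")
      }
      tiff::writeTIFF(arr, where = path, bits.per.sample = 32L)
    }
  )
  invisible(path)
}

#' Write a label map to disk
#'
#' Label codes (0 = background, 1 = CSF, 2 = GM, 3 = WM) survive a
#' write/read round-trip exactly in every supported format.
#'
#' @param x a [label_map()], a segmentation result, or an integer array
#'   with values in 0..3.
#' @param path output path (`.nii`/`.nii.gz`, `.png` or `.tif`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path) {
  lab <- label_map(as_label_array(x))$labels
  fmt <- file_format(path)
  switch(fmt,
    nifti = {
      RNifti::writeNifti(RNifti::asNifti(lab), path, datatype = "uint8")
    },
    analyze = stop("writing ANALYZE pairs is not supported; use .nii/.nii.gz"),
    png = png::writePNG(lab / 255, target = path),
    tiff = tiff::writeTIFF(lab / 255, where = path, bits.per.sample = 8L)
  )
  invisible(path)
}

#' Read a label map from disk
#'
#' Inverse of [write_labels()]: 8-bit PNG/TIFF label images are mapped back
#' from `value/255` to integer codes.
#'
#' @param path label image path.
#' @return A [label_map()].
#' @export
read_labels <- function(path) {
  arr <- read_image_array(path)
  attr(arr, "spacing") <- NULL
  fmt <- file_format(path)
  if (fmt %in% c("png", "tiff")) {
    arr <- arr * 255
  }
  lab <- round(arr)
  if (max(abs(arr - lab)) > 1e-6) {
    stop("image at '", path, "' does not contain integer label codes")
  }
  label_map(array(as.integer(lab), dim(arr)))
}
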