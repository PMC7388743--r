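#' Read a 2-D grayscale image
#'
#' Reads PNG and TIFF (8- or 16-bit, rescaled to the `[0, 255]` float
#' scale) and single slices of NIfTI volumes (`.nii` / `.nii.gz`, requires
#' the RNifti package; intensities are min-max rescaled to `[0, 255]`).
#' Color inputs are converted to single-channel luminance
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel is dropped.
#'
#' For PNG/TIFF the stored `[0, 1]` sample `u` is mapped to
#' `u * slope + offset`; the defaults (`slope = 255`, `offset = 0`)
#' recover plain `[0, 255]` images, while fixtures written with an affine
#' compression (see [make_test_suite()]) are restored by passing the
#' manifest's recorded `offset` and `slope`.
#'
#' @param path File path; format chosen by extension.
#' @param slice For NIfTI volumes, the axial slice index (default: middle
#'   slice).
#' @param offset,slope Affine decoding parameters for PNG/TIFF samples.
#' @return Numeric matrix on the `[0, 255]` scale (or the affine-decoded
#'   scale when `offset`/`slope` are given).
#' @export
read_image <- function(path, slice = NULL, offset = 0, slope = 255) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (grepl("\\.nii(\\.gz)?$", tolower(path))) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package", call. = FALSE)
    vol <- as.array(RNifti::readNifti(path))
    if (length(dim(vol)) == 3L) {
      if (is.null(slice)) slice <- ceiling(dim(vol)[3] / 2)
      if (slice < 1 || slice > dim(vol)[3])
        stop("slice ", slice, " out of range 1..", dim(vol)[3], call. = FALSE)
      vol <- vol[, , slice]
    } else if (length(dim(vol)) != 2L) {
      stop("unsupported NIfTI dimensionality", call. = FALSE)
    }
    rng <- range(vol)
    if (diff(rng) == 0) return(matrix(0, nrow(vol), ncol(vol)))
    return((vol - rng[1]) / diff(rng) * 255)
  }
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext,
         "' (use PNG, TIFF or NIfTI)", call. = FALSE)
  )
  to_gray(raw) * slope + offset
}

to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    ch <- dim(a)[3]
    if (ch >= 3L)
      return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
    return(a[, , 1])
  }
  stop("unsupported image array shape", call. = FALSE)
}

#' Write a 2-D grayscale image
#'
#' Writes a `[0, 255]`-scale matrix as 8-bit PNG or 16-bit grayscale TIFF,
#' chosen by extension. Values are clipped to `[0, 255]` before
#' quantization.
#'
#' @param img Numeric matrix on the `[0, 255]` scale.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("'img' must be a numeric matrix", call. = FALSE)
  u <- pmin(pmax(img, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(u, path),
    tif  = ,
    tiff = tiff::writeTIFF(u, path, bits.per.sample = 16L),
    stop("unsupported output format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}
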