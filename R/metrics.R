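#' Mean squared error between two images
#'
#' \deqn{MSE = \frac{1}{MN} \sum_i \sum_j \left[d(i,j) - \hat d(i,j)\right]^2}
#' in squared intensity units on the `[0, 255]` scale. Symmetric in its
#' arguments.
#'
#' @param ref Reference image (numeric matrix).
#' @param test Test image, same shape as `ref`.
#' @return Single non-negative number.
#' @export
#' @examples
#' img_mse(matrix(0, 2, 1), matrix(c(3, 4), 2, 1))  # 12.5
img_mse <- function(ref, test) {
  check_image_pair(ref, test)
  mean((ref - test)^2)
}

#' Peak signal-to-noise ratio
#'
#' \deqn{PSNR = 10 \log_{10}\!\left(\frac{255^2}{MSE}\right)} in decibels,
#' with the peak fixed at 255 regardless of the actual image maximum
#' (inputs on other scales should be rescaled first). Identical images
#' (MSE = 0) return `Inf`.
#'
#' @inheritParams img_mse
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
#' @examples
#' img_psnr(matrix(0, 4, 4), matrix(5, 4, 4))  # 20*log10(255/5) = 34.15 dB
img_psnr <- function(ref, test) {
  m <- img_mse(ref, test)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

check_image_pair <- function(ref, test) {
  if (!is.numeric(ref) || !is.numeric(test))
    stop("images must be numeric", call. = FALSE)
  dr <- dim(ref) %||% length(ref)
  dt <- dim(test) %||% length(test)
  if (length(dr) != length(dt) || any(dr != dt))
    stop("image shapes differ: ", paste(dr, collapse = "x"), " vs ",
         paste(dt, collapse = "x"), call. = FALSE)
  if (any(!is.finite(ref)) || any(!is.finite(test)))
    stop("images must be finite", call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
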