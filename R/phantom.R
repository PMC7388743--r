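# Synthetic brain-like phantoms and AWGN corruption. All generation is
# seed-deterministic (Mersenne-Twister + inversion sampling, pinned
# explicitly so results are stable across R configurations) and leaves the
# caller's RNG state untouched.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

# Separable circular Gaussian blur (kernel truncated at 4 sd).
gauss_blur <- function(m, sigma) {
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  out <- stats::filter(m, k, method = "convolution", sides = 2,
                       circular = TRUE)
  out <- t(stats::filter(t(out), k, method = "convolution", sides = 2,
                         circular = TRUE))
  matrix(as.numeric(out), nrow(m), ncol(m))
}

# Fixed anatomy table: centre (cx, cy), semi-axes (a, b) in units of the
# half-image, rotation (degrees), mean intensity. Rows 1-2 are the
# skull-like outer ellipse and the brain interior; the rest are inner
# tissue structures (ventricle-like dark regions and brighter matter).
phantom_anatomy <- function() {
  m <- rbind(
    c( 0.00,  0.00, 0.92, 0.95,   0, 230),  # skull rim
    c( 0.00,  0.00, 0.84, 0.87,   0, 120),  # brain tissue
    c( 0.00, -0.12, 0.16, 0.34,  10,  60),  # ventricle
    c( 0.18,  0.20, 0.28, 0.22, -20, 165),
    c(-0.30,  0.15, 0.20, 0.30,  25,  90),
    c( 0.05,  0.45, 0.30, 0.14,   0, 180),
    c(-0.10, -0.50, 0.22, 0.12,   0, 145),
    c( 0.35, -0.30, 0.12, 0.20,  40,  75)
  )
  colnames(m) <- c("cx", "cy", "a", "b", "angle", "value")
  m
}

#' Phantom specification
#'
#' Parameters of the brain-like synthetic test image generator (a stand-in
#' for real MRI brain slices; see [make_phantom()]).
#'
#' @param size Image dimensions `(rows, cols)`, each >= 32 (default
#'   `c(256, 256)`).
#' @param n_ellipses Number of nested intensity ellipses drawn (default 8:
#'   skull rim, brain interior and six inner structures; values beyond the
#'   built-in anatomy table are drawn at random from the seed).
#' @param texture_amp Amplitude (intensity units) of the smooth
#'   low-frequency sinusoidal texture inside the brain (default 12).
#' @param detail_amp Amplitude (intensity units) of the fine-scale
#'   band-pass tissue texture inside the brain (default 25). Real brain MRI
#'   carries substantial energy in the finest wavelet subbands; without
#'   this component a phantom is piecewise-smooth and unrepresentatively
#'   easy for aggressive thresholding.
#' @param seed RNG seed controlling texture phases and any extra ellipses.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256, 256), n_ellipses = 8,
                         texture_amp = 12, detail_amp = 25, seed = 0) {
  size <- as.integer(size)
  if (length(size) == 1L) size <- c(size, size)
  if (length(size) != 2L || anyNA(size) || any(size < 32L))
    stop("'size' must be two integers >= 32", call. = FALSE)
  if (!is.numeric(n_ellipses) || n_ellipses < 0)
    stop("'n_ellipses' must be >= 0", call. = FALSE)
  check_scalar_nonneg(texture_amp, "texture_amp")
  check_scalar_nonneg(detail_amp, "detail_amp")
  structure(list(size = size, n_ellipses = as.integer(n_ellipses),
                 texture_amp = texture_amp, detail_amp = detail_amp,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a brain-like phantom image
#'
#' Deterministic (given the seed) synthetic 2-D image on the `[0, 255]`
#' intensity scale: a skull-like bright outer ellipse, brain interior,
#' nested tissue ellipses with distinct mean intensities, a smooth
#' low-frequency sinusoidal texture, and fine-scale band-pass texture
#' (white noise band-passed between Gaussian blurs of 0.5 px and 2 px,
#' confined to the brain region) emulating tissue heterogeneity. The output
#' is clipped to `[0, 255]`.
#'
#' @param spec A [phantom_spec()] (default spec if missing).
#' @return Numeric matrix of dimension `spec$size` with values in
#'   `[0, 255]`.
#' @export
#' @examples
#' img <- make_phantom(phantom_spec(size = c(64, 64)))
#' range(img)
make_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    stop("'spec' must be a phantom_spec", call. = FALSE)
  nr <- spec$size[1]; nc <- spec$size[2]
  y <- matrix(rep((seq_len(nr) - (nr + 1) / 2) / (nr / 2), nc), nr, nc)
  x <- matrix(rep((seq_len(nc) - (nc + 1) / 2) / (nc / 2), each = nr), nr, nc)

  with_seed(spec$seed, {
    img <- matrix(20, nr, nc)                      # background
    tab <- phantom_anatomy()
    n <- spec$n_ellipses
    if (n > nrow(tab)) {
      extra <- cbind(cx = stats::runif(n - nrow(tab), -0.4, 0.4),
                     cy = stats::runif(n - nrow(tab), -0.4, 0.4),
                     a = stats::runif(n - nrow(tab), 0.05, 0.2),
                     b = stats::runif(n - nrow(tab), 0.05, 0.2),
                     angle = stats::runif(n - nrow(tab), 0, 180),
                     value = stats::runif(n - nrow(tab), 40, 220))
      tab <- rbind(tab, extra)
    }
    inside <- function(row) {
      th <- row["angle"] * pi / 180
      xr <- (x - row["cx"]) * cos(th) + (y - row["cy"]) * sin(th)
      yr <- -(x - row["cx"]) * sin(th) + (y - row["cy"]) * cos(th)
      (xr / row["a"])^2 + (yr / row["b"])^2 <= 1
    }
    brain <- NULL
    for (i in seq_len(min(n, nrow(tab)))) {
      m <- inside(tab[i, ])
      img[m] <- tab[i, "value"]
      if (i <= 2L) brain <- m                      # innermost of rim/interior
    }
    if (is.null(brain)) brain <- matrix(TRUE, nr, nc)

    if (spec$texture_amp > 0) {
      ph <- stats::runif(3, 0, 2 * pi)
      tex <- sin(2 * pi * x * 1.5 + ph[1]) * sin(2 * pi * y * 1.1 + ph[2]) +
        0.6 * sin(2 * pi * (x + y) * 0.8 + ph[3])
      img <- img + spec$texture_amp * tex * brain
    }
    if (spec$detail_amp > 0) {
      w <- matrix(stats::rnorm(nr * nc), nr, nc)
      z <- gauss_blur(w, 0.5) - gauss_blur(w, 2.0)
      z <- z / stats::sd(z)
      img <- img + spec$detail_amp * z * brain
    }
    pmin(pmax(img, 0), 255)
  })
}

#' Additive white Gaussian noise model
#'
#' Zero-mean i.i.d. Gaussian noise with variance `variance` on the unit
#' intensity scale: on the `[0, 255]` working scale the added noise has
#' standard deviation `255 * sqrt(variance)` (so `variance = 0.01` means a
#' noise sd of 25.5 intensity units and an unclipped noisy-image PSNR of
#' exactly `10 * log10(1 / variance) = 20` dB).
#'
#' @param variance Unit-scale noise variance, in `(0, 1)`.
#' @param seed RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(variance, seed = 1) {
  if (!is.numeric(variance) || length(variance) != 1L ||
      !is.finite(variance) || variance <= 0 || variance >= 1)
    stop("'variance' must lie strictly in (0, 1)", call. = FALSE)
  structure(list(variance = variance, mean = 0, seed = as.integer(seed)),
            class = "noise_model")
}

#' Corrupt an image with AWGN
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation
#' `255 * sqrt(variance)` to an image on the `[0, 255]` scale. The result
#' is deliberately NOT clipped: the de-noising pipeline sees the raw noisy
#' signal, and clipping is an output-stage concern. Deterministic given the
#' model's seed; the caller's RNG state is preserved.
#'
#' @param img Numeric matrix on the `[0, 255]` scale.
#' @param noise A [noise_model()].
#' @return Numeric matrix, same shape as `img`.
#' @export
#' @examples
#' clean <- make_phantom(phantom_spec(size = c(64, 64)))
#' noisy <- add_awgn(clean, noise_model(0.01, seed = 1))
#' sd(noisy - clean)  # ~25.5
add_awgn <- function(img, noise) {
  if (!inherits(noise, "noise_model"))
    stop("'noise' must be a noise_model", call. = FALSE)
  if (!is.matrix(img) || !is.numeric(img) || any(!is.finite(img)))
    stop("'img' must be a finite numeric matrix", call. = FALSE)
  sd_255 <- 255 * sqrt(noise$variance)
  with_seed(noise$seed,
            img + matrix(stats::rnorm(length(img), 0, sd_255),
                         nrow(img), ncol(img)))
}

#' Write a grid of phantom fixtures to disk
#'
#' Generates `n_phantoms` clean phantoms (seeds `1..n_phantoms`) and, for
#' every combination of phantom, noise variance and noise seed, an
#' AWGN-corrupted copy. Images are written as 16-bit grayscale TIFF; noisy
#' images (which exceed `[0, 255]`) are stored with an affine scale so the
#' excursions survive the round trip: the pixel value on disk is
#' `(value - offset) / slope` in `[0, 1]`, and the manifest records
#' `offset` and `slope` per file (clean files have `offset = 0`,
#' `slope = 255`).
#'
#' @param out_dir Output directory (created if needed).
#' @param variances Numeric vector of unit-scale noise variances (may be
#'   empty, in which case only clean phantoms are written).
#' @param seeds Integer vector of noise seeds.
#' @param n_phantoms Number of distinct phantoms (default 1).
#' @param size Phantom size passed to [phantom_spec()].
#' @return Invisibly, the manifest data frame (columns `file`, `role`,
#'   `phantom_seed`, `variance`, `noise_seed`, `offset`, `slope`), which is
#'   also written to `manifest.csv` in `out_dir`.
#' @export
make_test_suite <- function(out_dir, variances = c(0.01, 0.03, 0.05),
                            seeds = 1L, n_phantoms = 1L,
                            size = c(256, 256)) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  rows <- list()
  for (p in seq_len(n_phantoms)) {
    clean <- make_phantom(phantom_spec(size = size, seed = p))
    fc <- sprintf("phantom%02d_clean.tiff", p)
    write_image(clean, file.path(out_dir, fc))
    rows[[length(rows) + 1L]] <- data.frame(
      file = fc, role = "clean", phantom_seed = p, variance = NA_real_,
      noise_seed = NA_integer_, offset = 0, slope = 255)
    for (v in variances) {
      for (s in seeds) {
        noisy <- add_awgn(clean, noise_model(v, seed = s))
        off <- min(noisy); slope <- max(noisy) - off
        fn <- sprintf("phantom%02d_v%03d_s%02d_noisy.tiff",
                      p, round(1000 * v), s)
        tiff::writeTIFF((noisy - off) / slope, file.path(out_dir, fn),
                        bits.per.sample = 16L)
        rows[[length(rows) + 1L]] <- data.frame(
          file = fn, role = "noisy", phantom_seed = p, variance = v,
          noise_seed = s, offset = off, slope = slope)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
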