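#' AGGD core function s(x)
#'
#' Evaluates the adaptive generalized Gaussian distribution (AGGD) core
#' \deqn{s(x) = \sigma_n \left(e^{x^2 / (2\sigma_n^2)} - \tfrac12\right)}
#' used by the adaptive and AGGD shrinkage families to "tune" wavelet
#' coefficients inside the threshold interval instead of zeroing them.
#' The function is even in `x`, with `s(0) = sigma_n / 2`.
#'
#' @param x Numeric vector of wavelet coefficients (finite).
#' @param sigma_n Noise standard deviation in coefficient units (single
#'   positive number).
#' @return Numeric vector, `sigma_n * (exp(x^2 / (2 * sigma_n^2)) - 0.5)`.
#' @seealso [shrink_adaptive_hard()], [shrink_aggd()], [solve_aggd_threshold()]
#' @export
#' @examples
#' aggd_core(0, 1)   # 0.5
#' aggd_core(1, 1)   # exp(0.5) - 0.5
aggd_core <- function(x, sigma_n) {
  check_scalar_pos(sigma_n, "sigma_n")
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  sigma_n * (exp(x^2 / (2 * sigma_n^2)) - 0.5)
}

# Odd-symmetric middle branch shared by the adaptive/AGGD families:
# sign(x) * (s(|x|) - s(0)). Assumes |x| <= t so the exponent is small.
aggd_middle <- function(x, sigma_n) {
  sign(x) * sigma_n * (exp(x^2 / (2 * sigma_n^2)) - 1)
}

#' Hard threshold
#'
#' Keep-or-kill rule: coefficients with `|x| > t` pass unchanged, the rest
#' are set to zero.
#'
#' @param x Numeric vector of coefficients.
#' @param t Threshold (> 0).
#' @return Thresholded coefficients, same length as `x`.
#' @export
shrink_hard <- function(x, t) {
  check_scalar_pos(t, "t")
  ifelse(abs(x) > t, x, 0)
}

#' Soft threshold
#'
#' Shrinks every coefficient toward zero by `t`:
#' `sign(x) * max(|x| - t, 0)`.
#'
#' @inheritParams shrink_hard
#' @return Thresholded coefficients.
#' @export
shrink_soft <- function(x, t) {
  check_scalar_pos(t, "t")
  sign(x) * pmax(abs(x) - t, 0)
}

#' Zhang's smooth soft threshold
#'
#' Differentiable relaxation of the soft threshold,
#' \deqn{\eta(x) = x + \tfrac12\left(\sqrt{(x-t)^2+\lambda} -
#'   \sqrt{(x+t)^2+\lambda}\right),}
#' which collapses exactly to [shrink_soft()] at `lam = 0` and smooths the
#' corners at `|x| = t` as `lam` grows.
#'
#' @inheritParams shrink_hard
#' @param lam Shape parameter \eqn{\lambda \ge 0} (dimensionless; larger
#'   values give a smoother transition).
#' @return Thresholded coefficients.
#' @export
shrink_zhang_soft <- function(x, t, lam) {
  check_scalar_pos(t, "t")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("'lam' must be a finite number >= 0", call. = FALSE)
  x + 0.5 * (sqrt((x - t)^2 + lam) - sqrt((x + t)^2 + lam))
}

#' Zhang's smooth hard threshold
#'
#' Sigmoid-gated relaxation of the hard threshold,
#' \deqn{\eta(x) = \left(\frac{1}{1+e^{(-x+t)/\mu}} -
#'   \frac{1}{1+e^{(-x-t)/\mu}} + 1\right) x,}
#' converging pointwise to [shrink_hard()] as `mu -> 0` (except at
#' `|x| = t`). Sigmoids are evaluated through [stats::plogis()] so large
#' `|x - t| / mu` never overflows.
#'
#' @inheritParams shrink_hard
#' @param mu Shape parameter \eqn{\mu > 0} (dimensionless).
#' @return Thresholded coefficients.
#' @export
shrink_zhang_hard <- function(x, t, mu) {
  check_scalar_pos(t, "t")
  check_scalar_pos(mu, "mu")
  (stats::plogis((x - t) / mu) - stats::plogis((x + t) / mu) + 1) * x
}

#' Adaptive hard threshold ("tune and keep")
#'
#' Identity outside `[-sigma_n, sigma_n]`; inside the interval, coefficients
#' are tuned through the AGGD core rather than zeroed:
#' `sign(x) * (s(|x|) - s(0))`. Discontinuous at `|x| = sigma_n`; the
#' threshold is tied to the noise level (`t = sigma_n`).
#'
#' @param x Numeric vector of coefficients.
#' @param sigma_n Noise standard deviation (> 0), which is also the
#'   threshold.
#' @return Thresholded coefficients.
#' @export
shrink_adaptive_hard <- function(x, sigma_n) {
  check_scalar_pos(sigma_n, "sigma_n")
  ifelse(abs(x) > sigma_n, x, aggd_middle(x, sigma_n))
}

#' Adaptive soft threshold ("tune and shrink")
#'
#' Same AGGD-tuned middle branch as [shrink_adaptive_hard()], but
#' coefficients beyond the interval are shifted toward zero by
#' `t - (s(t) - s(0))` with `t = sigma_n`, which makes the function
#' continuous everywhere.
#'
#' @inheritParams shrink_adaptive_hard
#' @return Thresholded coefficients.
#' @export
shrink_adaptive_soft <- function(x, sigma_n) {
  check_scalar_pos(sigma_n, "sigma_n")
  offset <- sigma_n - sigma_n * (exp(0.5) - 1)   # t - (s(t) - s(0)), t = sigma_n
  ifelse(abs(x) > sigma_n,
         sign(x) * (abs(x) - offset),
         aggd_middle(x, sigma_n))
}

#' AGGD threshold function
#'
#' Identity outside `[-t, t]`; AGGD-tuned middle branch inside. Continuous
#' at `|x| = t` exactly when `t` is the intersection of the shifted AGGD
#' core with the identity line (see [solve_aggd_threshold()]).
#'
#' @param x Numeric vector of coefficients.
#' @param sigma_n Noise standard deviation (> 0).
#' @param t Threshold, `t >= sigma_n`.
#' @return Thresholded coefficients.
#' @export
shrink_aggd <- function(x, sigma_n, t) {
  check_scalar_pos(sigma_n, "sigma_n")
  check_scalar_pos(t, "t")
  if (t < sigma_n)
    stop("'t' must be >= 'sigma_n' for the AGGD families", call. = FALSE)
  ifelse(abs(x) > t, x, aggd_middle(x, sigma_n))
}

#' Improved AGGD threshold function
#'
#' Fully non-linear variant of [shrink_aggd()]: the outer branches are
#' sigmoid-weighted,
#' \deqn{\eta(x) = \frac{x}{1+e^{-x+t}} + \frac{t}{2} \quad (x > t),}
#' with the mirrored form for `x < -t`, and the AGGD-tuned middle branch
#' inside `[-t, t]`. At `x = t` the outer branch equals `t/2 + t/2 = t`, so
#' the function is continuous at the solver's threshold `t*`. Note the
#' outer branch approaches `x + t/2` (not the identity) for large `x`; the
#' formulation is inherently tied to unit-scale coefficients, which is why
#' [denoise()] operates on the `[0, 1]` working scale.
#'
#' @inheritParams shrink_aggd
#' @return Thresholded coefficients.
#' @export
shrink_improved_aggd <- function(x, sigma_n, t) {
  check_scalar_pos(sigma_n, "sigma_n")
  check_scalar_pos(t, "t")
  if (t < sigma_n)
    stop("'t' must be >= 'sigma_n' for the AGGD families", call. = FALSE)
  a <- abs(x)
  outer <- sign(x) * (stats::plogis(a - t) * a + t / 2)
  ifelse(a > t, outer, aggd_middle(x, sigma_n))
}

#' Shrinkage specification
#'
#' Bundles a threshold-function family with its parameters, validated
#' against the family's requirements. Used by [apply_shrinkage()] and
#' produced by [select_threshold()].
#'
#' A degenerate spec with `t = 0` (and, for the adaptive/AGGD families,
#' `sigma_n = 0`) is allowed and denotes the identity map: it arises
#' naturally when the noise estimate of a noise-free image is zero.
#'
#' @param family One of `"hard"`, `"soft"`, `"zhang_soft"`, `"zhang_hard"`,
#'   `"adaptive_hard"`, `"adaptive_soft"`, `"aggd"`, `"improved_aggd"`.
#' @param t Threshold value in coefficient units (>= 0; for the adaptive
#'   families it must equal `sigma_n` and defaults to it, for the AGGD
#'   families it must be `>= sigma_n`).
#' @param sigma_n Noise standard deviation in coefficient units (required
#'   by the adaptive and AGGD families; >= 0).
#' @param lam Shape parameter for `zhang_soft` (>= 0, default 0.1).
#' @param mu Shape parameter for `zhang_hard` (> 0, default 0.05).
#' @return An object of class `shrinkage_spec`.
#' @export
#' @examples
#' shrinkage_spec("soft", t = 1)
#' shrinkage_spec("improved_aggd", sigma_n = 1, t = solve_aggd_threshold(1))
shrinkage_spec <- function(family, t = NULL, sigma_n = NULL,
                           lam = NULL, mu = NULL) {
  family <- match.arg(family, shrinkage_families())
  needs_sigma <- family %in% c("adaptive_hard", "adaptive_soft",
                               "aggd", "improved_aggd")
  if (needs_sigma) {
    check_scalar_nonneg(sigma_n, "sigma_n")
    if (family %in% c("adaptive_hard", "adaptive_soft")) {
      if (is.null(t)) t <- sigma_n
      if (abs(t - sigma_n) > 1e-12 * max(sigma_n, 1))
        stop("adaptive families require t == sigma_n", call. = FALSE)
    } else {
      if (is.null(t))
        stop("'t' is required for the AGGD families", call. = FALSE)
      check_scalar_nonneg(t, "t")
      if (t < sigma_n)
        stop("AGGD families require t >= sigma_n", call. = FALSE)
    }
  } else {
    check_scalar_nonneg(t, "t")
  }
  if (family == "zhang_soft") {
    if (is.null(lam)) lam <- 0.1
    check_scalar_nonneg(lam, "lam")
  } else if (!is.null(lam)) {
    stop("'lam' is only meaningful for family 'zhang_soft'", call. = FALSE)
  }
  if (family == "zhang_hard") {
    if (is.null(mu)) mu <- 0.05
    check_scalar_pos(mu, "mu")
  } else if (!is.null(mu)) {
    stop("'mu' is only meaningful for family 'zhang_hard'", call. = FALSE)
  }
  structure(list(family = family, t = t, sigma_n = sigma_n,
                 lam = lam, mu = mu),
            class = "shrinkage_spec")
}

#' @export
print.shrinkage_spec <- function(x, ...) {
  cat("Shrinkage spec:", x$family, "\n")
  cat("  t =", format(x$t), "\n")
  if (!is.null(x$sigma_n)) cat("  sigma_n =", format(x$sigma_n), "\n")
  if (!is.null(x$lam)) cat("  lambda =", format(x$lam), "\n")
  if (!is.null(x$mu)) cat("  mu =", format(x$mu), "\n")
  invisible(x)
}

#' Supported shrinkage families
#'
#' @return Character vector of family names accepted by [shrinkage_spec()].
#' @export
shrinkage_families <- function() {
  c("hard", "soft", "zhang_soft", "zhang_hard",
    "adaptive_hard", "adaptive_soft", "aggd", "improved_aggd")
}

#' Apply a shrinkage function elementwise
#'
#' Dispatches on `spec$family` and applies the corresponding threshold
#' function to every element of `coeffs`, preserving shape (vector or
#' matrix). The input is not mutated. A degenerate spec (`t = 0`) is the
#' identity map for every family.
#'
#' @param coeffs Numeric vector or matrix of wavelet coefficients (finite).
#' @param spec A [shrinkage_spec()].
#' @return Object of the same shape as `coeffs`.
#' @export
apply_shrinkage <- function(coeffs, spec) {
  if (!inherits(spec, "shrinkage_spec"))
    stop("'spec' must be a shrinkage_spec", call. = FALSE)
  if (!is.numeric(coeffs))
    stop("'coeffs' must be numeric", call. = FALSE)
  if (length(coeffs) == 0L) return(coeffs)
  if (any(!is.finite(coeffs)))
    stop("'coeffs' must be finite", call. = FALSE)
  if (spec$t == 0) return(coeffs)
  out <- switch(spec$family,
    hard          = shrink_hard(coeffs, spec$t),
    soft          = shrink_soft(coeffs, spec$t),
    zhang_soft    = shrink_zhang_soft(coeffs, spec$t, spec$lam),
    zhang_hard    = shrink_zhang_hard(coeffs, spec$t, spec$mu),
    adaptive_hard = shrink_adaptive_hard(coeffs, spec$sigma_n),
    adaptive_soft = shrink_adaptive_soft(coeffs, spec$sigma_n),
    aggd          = shrink_aggd(coeffs, spec$sigma_n, spec$t),
    improved_aggd = shrink_improved_aggd(coeffs, spec$sigma_n, spec$t),
    stop("unsupported shrinkage family: ", spec$family, call. = FALSE)
  )
  if (!is.null(dim(coeffs))) dim(out) <- dim(coeffs)
  out
}

check_scalar_pos <- function(v, name) {
  if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop(sprintf("'%s' must be a finite number > 0", name), call. = FALSE)
  invisible(v)
}

check_scalar_nonneg <- function(v, name) {
  if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
    stop(sprintf("'%s' must be a finite number >= 0", name), call. = FALSE)
  invisible(v)
}
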