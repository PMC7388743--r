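#' Robust noise estimate from the finest diagonal subband
#'
#' Median-absolute-deviation estimator of the noise standard deviation:
#' \deqn{\hat\sigma = \mathrm{Median}(|G_{i,j}|) / 0.6745,}
#' where `G` is the finest-level HH (diagonal detail) subband and 0.6745 is
#' the third quartile of the standard normal. Deterministic; invariant to
#' sign flips and permutations of the subband.
#'
#' @param hh_subband Numeric vector or matrix of finest-level HH
#'   coefficients (non-empty, finite).
#' @param source_subband Label recorded in the result (default `"HH1"`).
#' @return An object of class `noise_estimate`: list with `sigma_hat`,
#'   `source_subband`, `n_coeffs`.
#' @export
#' @examples
#' estimate_sigma(c(0.6745, 0.6745, 0.6745))$sigma_hat  # 1
estimate_sigma <- function(hh_subband, source_subband = "HH1") {
  if (!is.numeric(hh_subband) || length(hh_subband) == 0L)
    stop("'hh_subband' must be a non-empty numeric array", call. = FALSE)
  if (any(!is.finite(hh_subband)))
    stop("'hh_subband' must be finite", call. = FALSE)
  structure(list(
    sigma_hat      = stats::median(abs(hh_subband)) / 0.6745,
    source_subband = source_subband,
    n_coeffs       = length(hh_subband)
  ), class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat("Noise estimate: sigma_hat =", format(x$sigma_hat),
      "from", x$source_subband, sprintf("(%d coefficients)\n", x$n_coeffs))
  invisible(x)
}

#' VisuShrink universal threshold
#'
#' \deqn{t_{uni} = \sigma \sqrt{2 \ln n}.} Returns 0 when `n = 1` or
#' `sigma = 0`. `n` is taken as the total pixel count of the image (the
#' scope used throughout this package).
#'
#' @param sigma Noise standard deviation (>= 0).
#' @param n Sample size (>= 1).
#' @return The universal threshold.
#' @export
universal_threshold <- function(sigma, n) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("'sigma' must be a finite number >= 0", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a number >= 1", call. = FALSE)
  sigma * sqrt(2 * log(n))
}

#' AGGD intersection threshold
#'
#' Solves for the unique `t* > 0` at which the shifted AGGD core meets the
#' identity line, \eqn{s(t) - s(0) = t}, i.e.
#' \eqn{\sigma_n (e^{t^2/(2\sigma_n^2)} - 1) = t}. This is the threshold
#' that makes [shrink_aggd()] and [shrink_improved_aggd()] continuous at
#' `|x| = t`. The equation is scale equivariant, so it is solved once in
#' normalized units `u = t / sigma_n` (Brent's method on `[1, 3]`, where a
#' unique sign change exists) and rescaled, giving
#' `t*(sigma_n) = sigma_n * t*(1)` exactly. `t*(1) = 1.2858887...`, always
#' `> sigma_n`.
#'
#' @param sigma_n Noise standard deviation (> 0).
#' @return The threshold `t*`.
#' @export
#' @examples
#' solve_aggd_threshold(1)   # 1.28589...
solve_aggd_threshold <- function(sigma_n) {
  check_scalar_pos(sigma_n, "sigma_n")
  sigma_n * aggd_tstar_unit()
}

# Normalized root of e^{u^2/2} - 1 - u = 0 on (0, Inf); cached after the
# first call (the equation has no parameters).
aggd_tstar_unit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- function(u) exp(u^2 / 2) - 1 - u
      cache <<- stats::uniroot(f, c(1, 3), tol = .Machine$double.eps)$root
    }
    cache
  }
})

#' Select the threshold for a shrinkage family
#'
#' Consolidates the threshold rules into a single dispatch:
#' * `hard`, `soft`, `zhang_soft`, `zhang_hard` use the VisuShrink
#'   [universal_threshold()] `sigma_hat * sqrt(2 ln n)`;
#' * `adaptive_hard`, `adaptive_soft` use `t = sigma_hat`;
#' * `aggd`, `improved_aggd` use the intersection threshold
#'   [solve_aggd_threshold()].
#'
#' When `sigma_hat = 0` (noise-free input) every rule yields `t = 0`, a
#' degenerate spec under which [apply_shrinkage()] is the identity map.
#'
#' @param family Shrinkage family name (see [shrinkage_families()]).
#' @param sigma_hat Estimated noise standard deviation (>= 0).
#' @param n Sample size for the universal threshold (>= 1), normally the
#'   pixel count of the image.
#' @param lam,mu Shape parameters forwarded to [shrinkage_spec()] for the
#'   Zhang families.
#' @return A [shrinkage_spec()].
#' @export
select_threshold <- function(family, sigma_hat, n, lam = 0.1, mu = 0.05) {
  family <- match.arg(family, shrinkage_families())
  check_scalar_nonneg(sigma_hat, "sigma_hat")
  aggd_t <- if (sigma_hat > 0) solve_aggd_threshold(sigma_hat) else 0
  switch(family,
    hard       = shrinkage_spec("hard", t = universal_threshold(sigma_hat, n)),
    soft       = shrinkage_spec("soft", t = universal_threshold(sigma_hat, n)),
    zhang_soft = shrinkage_spec("zhang_soft",
                                t = universal_threshold(sigma_hat, n), lam = lam),
    zhang_hard = shrinkage_spec("zhang_hard",
                                t = universal_threshold(sigma_hat, n), mu = mu),
    adaptive_hard = shrinkage_spec("adaptive_hard", sigma_n = sigma_hat),
    adaptive_soft = shrinkage_spec("adaptive_soft", sigma_n = sigma_hat),
    aggd          = shrinkage_spec("aggd", sigma_n = sigma_hat, t = aggd_t),
    improved_aggd = shrinkage_spec("improved_aggd", sigma_n = sigma_hat,
                                   t = aggd_t)
  )
}
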