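# Frozen high-precision reference values (computed once with
# arbitrary-precision arithmetic from the closed-form expressions).
S_CORE_1_1       <- 1.14872127070012814685   # exp(0.5) - 0.5
ADAPT_1_1        <- 0.64872127070012814685   # exp(0.5) - 1
ADAPT_SOFT_3_1   <- 2.64872127070012814685   # 3 - (2 - exp(0.5))
ZHANG_SOFT_1_1_1 <- 0.38196601125010515180   # 1 + (1 - sqrt(5))/2
UNI_2_4          <- 3.33021844463079102541   # 2 * sqrt(2 * log(4))
TSTAR_1          <- 1.28588870250989357039   # root of exp(u^2/2) - 1 - u
IMPAGGD_10_1     <- 10.64130210522326483     # plogis(10 - t*) * 10 + t*/2
PSNR_MSE_25      <- 34.15140352195872732     # 20 * log10(255 / 5)

# Independent grid-scan + bisection oracle for the AGGD intersection
# threshold (never calls solve_aggd_threshold).
tstar_oracle <- function(sigma) {
  f <- function(u) sigma * (exp(u^2 / (2 * sigma^2)) - 1) - u
  grid <- seq(sigma * 1e-3, 3 * sigma, length.out = 2000)
  fg <- f(grid)
  i <- which(fg[-1] > 0 & fg[-length(fg)] <= 0)
  i <- i[length(i)]            # positive root (u = 0 is also a root)
  lo <- grid[i]; hi <- grid[i + 1]
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Small deterministic phantom for fast pipeline tests.
tiny_phantom <- function(size = 64, seed = 0)
  make_phantom(phantom_spec(size = c(size, size), seed = seed))

clip255 <- function(x) pmin(pmax(x, 0), 255)

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_script <- function() system.file("cli", "aggdenoise.R",
                                     package = "aggdenoise")

run_cli <- function(...) {
  suppressWarnings(system2(rscript_bin(), c(cli_script(), ...),
                           stdout = TRUE, stderr = TRUE))
}

make_tempdir <- function() {
  d <- tempfile("fixtures")
  dir.create(d)
  d
}
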