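test_that("AGGD core matches its closed form", {
  expect_equal(aggd_core(0, 1), 0.5)
  expect_equal(aggd_core(0, 2), 1.0)
  expect_equal(aggd_core(1, 1), S_CORE_1_1, tolerance = 1e-14)
  # even in x
  x <- seq(-3, 3, length.out = 41)
  expect_equal(aggd_core(x, 1.3), aggd_core(-x, 1.3))
  expect_error(aggd_core(1, 0), "sigma_n")
  expect_error(aggd_core(NaN, 1), "finite")
})

test_that("hard and soft thresholds follow the keep-or-kill / shift rules", {
  expect_equal(shrink_hard(3, 1), 3)
  expect_equal(shrink_hard(0.5, 1), 0)
  expect_equal(shrink_hard(-3, 1), -3)
  expect_equal(shrink_soft(3, 1), 2)
  expect_equal(shrink_soft(-0.5, 1), 0)
  expect_equal(shrink_soft(-3, 1), -2)
})

test_that("Zhang soft function matches the closed form and its soft limit", {
  expect_equal(shrink_zhang_soft(3, 1, 0), 2)
  expect_equal(shrink_zhang_soft(0, 1, 0.5), 0)
  expect_equal(shrink_zhang_soft(1, 1, 1), ZHANG_SOFT_1_1_1, tolerance = 1e-14)
  # lambda = 0 collapses exactly to the soft threshold
  x <- seq(-10, 10, length.out = 20001)
  expect_lt(max(abs(shrink_zhang_soft(x, 1.7, 0) - shrink_soft(x, 1.7))),
            1e-12)
  expect_error(shrink_zhang_soft(1, 1, -0.1), "lam")
})

test_that("Zhang hard function is overflow-safe and converges to hard", {
  expect_equal(shrink_zhang_hard(0, 1, 0.1), 0)
  expect_equal(shrink_zhang_hard(100, 1, 0.1), 100, tolerance = 1e-9)
  expect_equal(shrink_zhang_hard(0.5, 1, 0.01), 0, tolerance = 1e-9)
  # no overflow for extreme arguments
  expect_true(is.finite(shrink_zhang_hard(1e6, 1, 1e-3)))
  # mu -> 0 pointwise convergence away from |x| = t
  x <- seq(-10, 10, length.out = 4001)
  x <- x[abs(abs(x) - 2) > 0.05]
  expect_lt(max(abs(shrink_zhang_hard(x, 2, 1e-4) - shrink_hard(x, 2))), 1e-9)
  expect_error(shrink_zhang_hard(1, 1, 0), "mu")
})

test_that("adaptive hard tunes inside [-sigma, sigma] and keeps outside", {
  expect_equal(shrink_adaptive_hard(0, 1), 0)
  expect_equal(shrink_adaptive_hard(2, 1), 2)
  expect_equal(shrink_adaptive_hard(1, 1), ADAPT_1_1, tolerance = 1e-14)
  # middle branch is s(|x|) - s(0), odd-extended
  expect_equal(shrink_adaptive_hard(-1, 1), -ADAPT_1_1, tolerance = 1e-14)
})

test_that("adaptive soft is continuous and matches its closed form", {
  expect_equal(shrink_adaptive_soft(0, 1), 0)
  expect_equal(shrink_adaptive_soft(1, 1), ADAPT_1_1, tolerance = 1e-14)
  expect_equal(shrink_adaptive_soft(3, 1), ADAPT_SOFT_3_1, tolerance = 1e-14)
  # boundary value from both branches agrees (continuity at |x| = sigma)
  eps <- 1e-9
  expect_equal(shrink_adaptive_soft(1 + eps, 1),
               shrink_adaptive_soft(1 - eps, 1), tolerance = 1e-7)
})

test_that("AGGD and improved AGGD match the printed branches", {
  t1 <- TSTAR_1
  expect_equal(shrink_aggd(0, 1, t1), 0)
  expect_equal(shrink_aggd(5, 1, t1), 5)
  expect_equal(shrink_aggd(1, 1, t1), ADAPT_1_1, tolerance = 1e-14)
  expect_equal(shrink_improved_aggd(0, 1, t1), 0)
  # at x = t the right branch gives x/2 + t/2 = t
  expect_equal(shrink_improved_aggd(t1 + 1e-12, 1, t1), t1, tolerance = 1e-9)
  expect_equal(shrink_improved_aggd(10, 1, t1), IMPAGGD_10_1,
               tolerance = 1e-12)
  expect_error(shrink_aggd(1, 2, 1), "t.*sigma_n|sigma_n.*t")
  expect_error(shrink_improved_aggd(1, 2, 1), "t.*sigma_n|sigma_n.*t")
})

test_that("all families are odd functions", {
  t <- 1.3; s <- 1
  x <- seq(0, 10 * t, length.out = 5001)
  fns <- list(
    function(z) shrink_hard(z, t),
    function(z) shrink_soft(z, t),
    function(z) shrink_zhang_soft(z, t, 0.1),
    function(z) shrink_zhang_hard(z, t, 0.05),
    function(z) shrink_adaptive_hard(z, s),
    function(z) shrink_adaptive_soft(z, s),
    function(z) shrink_aggd(z, s, t),
    function(z) shrink_improved_aggd(z, s, t)
  )
  for (f in fns)
    expect_lt(max(abs(f(-x) + f(x))), 1e-12)
})

test_that("soft-type families are continuous, hard-type families jump", {
  s <- 1; t <- TSTAR_1
  grid <- seq(-4, 4, by = 1e-4)
  jump <- function(f) max(abs(diff(f(grid))))
  # continuous families: max adjacent jump bounded by spacing * slope bound
  expect_lt(jump(function(z) shrink_adaptive_soft(z, s)), 1e-4 * 20)
  expect_lt(jump(function(z) shrink_aggd(z, s, t)), 1e-4 * 30)
  expect_lt(jump(function(z) shrink_improved_aggd(z, s, t)), 1e-4 * 30)
  expect_lt(jump(function(z) shrink_zhang_soft(z, 1.5, 0.1)), 1e-4 * 20)
  expect_lt(jump(function(z) shrink_zhang_hard(z, 1.5, 0.05)), 1e-4 * 300)
  # hard-type: jump of size t - eta(t-) > 0 at |x| = t
  eps <- 1e-9
  expect_equal(shrink_hard(1.5 + eps, 1.5) - shrink_hard(1.5 - eps, 1.5),
               1.5, tolerance = 1e-6)
  gap <- shrink_adaptive_hard(s + eps, s) - shrink_adaptive_hard(s - eps, s)
  expect_equal(gap, s * (2 - exp(0.5)), tolerance = 1e-6)
})

test_that("adaptive kill zone tunes instead of zeroing", {
  s <- 0.7
  x <- seq(-s, s, length.out = 201)
  bound <- aggd_core(s, s) - aggd_core(0, s)
  for (f in list(function(z) shrink_adaptive_hard(z, s),
                 function(z) shrink_adaptive_soft(z, s))) {
    y <- f(x)
    expect_true(all(abs(y) <= bound + 1e-12))
    expect_true(all(y[x != 0] != 0))
    expect_true(all(sign(y[x != 0]) == sign(x[x != 0])))
  }
  # standard functions return exactly zero there
  expect_true(all(shrink_hard(x, s) == 0))
  expect_true(all(shrink_soft(x, s) == 0))
})

test_that("identity tails are exact for hard-type and AGGD families", {
  s <- 1; t <- TSTAR_1
  x <- c(seq(1.01, 20, length.out = 100), -seq(1.01, 20, length.out = 100))
  expect_identical(shrink_hard(x, 1), x)
  expect_identical(shrink_adaptive_hard(x, s), x)
  xt <- x * t
  expect_identical(shrink_aggd(xt, s, t), xt)
})

test_that("shrinkage_spec validates family-parameter combinations", {
  expect_s3_class(shrinkage_spec("soft", t = 1), "shrinkage_spec")
  expect_error(shrinkage_spec("nonsense", t = 1))
  expect_error(shrinkage_spec("soft", t = -1), "t")
  expect_error(shrinkage_spec("adaptive_hard", sigma_n = 1, t = 2),
               "t == sigma_n")
  expect_error(shrinkage_spec("aggd", sigma_n = 1, t = 0.5), ">= sigma_n")
  expect_error(shrinkage_spec("soft", t = 1, lam = 0.1), "zhang_soft")
  expect_error(shrinkage_spec("soft", t = 1, mu = 0.1), "zhang_hard")
  # adaptive threshold defaults to sigma_n
  expect_equal(shrinkage_spec("adaptive_soft", sigma_n = 0.8)$t, 0.8)
  # degenerate zero-threshold spec allowed (noise-free input)
  expect_equal(shrinkage_spec("improved_aggd", sigma_n = 0, t = 0)$t, 0)
  # Zhang shape defaults
  expect_equal(shrinkage_spec("zhang_soft", t = 1)$lam, 0.1)
  expect_equal(shrinkage_spec("zhang_hard", t = 1)$mu, 0.05)
})

test_that("apply_shrinkage is elementwise, shape-preserving, non-mutating", {
  expect_equal(apply_shrinkage(c(3, 0.5, -3), shrinkage_spec("soft", t = 1)),
               c(2, 0, -2))
  expect_equal(apply_shrinkage(numeric(0), shrinkage_spec("soft", t = 1)),
               numeric(0))
  expect_equal(apply_shrinkage(c(1, 2),
                               shrinkage_spec("adaptive_hard", sigma_n = 1)),
               c(ADAPT_1_1, 2), tolerance = 1e-14)
  m <- matrix(c(3, 0.5, -3, 0), 2, 2)
  out <- apply_shrinkage(m, shrinkage_spec("hard", t = 1))
  expect_identical(dim(out), dim(m))
  expect_identical(m, matrix(c(3, 0.5, -3, 0), 2, 2))  # input untouched
  # degenerate spec is the identity for every family
  z <- seq(-2, 2, length.out = 11)
  expect_identical(apply_shrinkage(z, shrinkage_spec("aggd", sigma_n = 0,
                                                     t = 0)), z)
  bogus <- structure(list(family = "nope", t = 1), class = "shrinkage_spec")
  expect_error(apply_shrinkage(1, bogus), "unsupported")
  expect_error(apply_shrinkage(c(1, Inf), shrinkage_spec("soft", t = 1)),
               "finite")
})
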