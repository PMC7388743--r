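test_that("phantom generation is seed-deterministic and leaves the RNG
           state alone", {
  spec <- phantom_spec(size = c(64, 64), seed = 7)
  expect_identical(make_phantom(spec), make_phantom(spec))
  expect_false(identical(make_phantom(spec),
                         make_phantom(phantom_spec(size = c(64, 64),
                                                   seed = 8))))
  set.seed(123)
  before <- .Random.seed
  invisible(make_phantom(spec))
  expect_identical(.Random.seed, before)
})

test_that("phantom intensities stay in [0, 255] and contain edges", {
  img <- make_phantom()
  expect_gte(min(img), 0); expect_lte(max(img), 255)
  grad <- max(abs(diff(img)), abs(t(diff(t(img)))))
  expect_gt(grad, 10)
})

test_that("a textureless single-ellipse phantom has exactly two intensities", {
  img <- make_phantom(phantom_spec(size = c(64, 64), n_ellipses = 1,
                                   texture_amp = 0, detail_amp = 0))
  expect_identical(sort(unique(as.numeric(img))), c(20, 230))
})

test_that("degenerate phantom sizes are rejected", {
  expect_error(phantom_spec(size = c(16, 64)), "32")
  expect_error(phantom_spec(size = c(256, 256), texture_amp = -1))
})

test_that("AWGN has the advertised scale, zero mean and determinism", {
  clean <- make_phantom()
  noisy <- add_awgn(clean, noise_model(0.01, seed = 5))
  d <- noisy - clean
  expect_gt(sd(d), 24.0); expect_lt(sd(d), 27.0)    # true value 25.5
  expect_gt(mean(d), -0.5); expect_lt(mean(d), 0.5)
  expect_identical(noisy, add_awgn(clean, noise_model(0.01, seed = 5)))
  expect_false(identical(noisy, add_awgn(clean, noise_model(0.01, seed = 6))))
  expect_error(noise_model(0), "variance")
  expect_error(noise_model(1), "variance")
})

test_that("noise injection and PSNR are mutually consistent", {
  clean <- make_phantom()
  noisy <- add_awgn(clean, noise_model(0.01, seed = 2))   # unclipped pair
  expect_equal(img_psnr(clean, noisy), 20, tolerance = 0.1)
})

test_that("make_test_suite writes the fixture grid and a faithful manifest", {
  dir <- make_tempdir()
  man <- make_test_suite(dir, variances = c(0.01, 0.03), seeds = 1,
                         n_phantoms = 2, size = c(64, 64))
  expect_equal(nrow(man), 6)                       # 2 clean + 4 noisy
  expect_equal(sum(man$role == "clean"), 2)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  # noisy image round-trips through the recorded affine scale to within
  # 16-bit quantization
  row <- man[man$role == "noisy", ][1, ]
  raw <- tiff::readTIFF(file.path(dir, row$file))
  restored <- raw * row$slope + row$offset
  clean <- make_phantom(phantom_spec(size = c(64, 64),
                                     seed = row$phantom_seed))
  regen <- add_awgn(clean, noise_model(row$variance, seed = row$noise_seed))
  expect_lt(max(abs(restored - regen)), row$slope / 65535)

  # empty variance list: clean phantoms only
  dir2 <- make_tempdir()
  man2 <- make_test_suite(dir2, variances = numeric(0), seeds = 1,
                          n_phantoms = 1, size = c(64, 64))
  expect_identical(unique(man2$role), "clean")
})
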