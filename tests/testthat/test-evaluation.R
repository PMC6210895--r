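test_that("PSNR matches its closed form and the triple-loop oracle", {
  cube <- random_cube(6, 7, 3, seed = 71)
  cube$data[cube$data == 4095] <- 4094
  plus1 <- hyperspectral_cube(cube$data + 1, 12L)
  expect_equal(psnr(cube, plus1), 10 * log10(4095^2), tolerance = 1e-12)

  for (s in 1:5) {
    o <- random_cube(5, 6, 2, seed = 100 + s)
    r <- random_cube(5, 6, 2, seed = 200 + s)
    expect_equal(psnr(o, r), psnr_oracle(o$data, r$data, 12L), tolerance = 1e-9)
  }
  expect_error(psnr(cube, random_cube(2, 2, 1)), "shapes")
})

test_that("identical cubes yield the identical sentinel, and noise lowers PSNR", {
  cube <- random_cube(8, 8, 2, seed = 72)
  p <- psnr(cube, cube)
  expect_true(isTRUE(attr(p, "identical")))
  set.seed(1)
  n1 <- hyperspectral_cube(pmin(pmax(cube$data +
          array(sample(c(-1, 1), 128, TRUE), c(8, 8, 2)), 0), 4095))
  set.seed(1)
  n2 <- hyperspectral_cube(pmin(pmax(cube$data +
          array(sample(c(-3, 3), 128, TRUE), c(8, 8, 2)), 0), 4095))
  expect_gt(psnr(cube, n1), psnr(cube, n2))
  # invariance under a shared voxel permutation
  set.seed(2)
  perm <- sample(128)
  po <- hyperspectral_cube(array(cube$data[perm], c(8, 8, 2)))
  pr <- hyperspectral_cube(array(n1$data[perm], c(8, 8, 2)))
  expect_equal(psnr(po, pr), psnr(cube, n1), tolerance = 1e-12)
})

test_that("spectral correlation is symmetric, affine-invariant and matches the oracle", {
  gen <- generate_cube(tea_like_spec(seed = 4, a = 32L, b = 32L, c = 8L))
  expect_identical(spectral_correlation(gen$cube, 3, 3), 1)
  expect_equal(spectral_correlation(gen$cube, 2, 7),
               spectral_correlation(gen$cube, 7, 2), tolerance = 1e-12)

  f <- matrix(round(runif(64, 0, 2000)), 8, 8)
  aff <- array(0, c(8, 8, 2)); aff[, , 1] <- f; aff[, , 2] <- 2 * f + 11
  expect_equal(spectral_correlation(hyperspectral_cube(aff), 1, 2), 1,
               tolerance = 1e-9)

  for (s in 1:5) {
    o <- random_cube(7, 9, 2, seed = 300 + s)
    expect_equal(spectral_correlation(o, 1, 2),
                 zeta_oracle(matrix(o$data[, , 1], 7, 9),
                             matrix(o$data[, , 2], 7, 9)),
                 tolerance = 1e-9)
  }
  expect_error(spectral_correlation(hyperspectral_cube(array(c(1, 1, 1, 1, 0, 1, 2, 3),
                                                             c(2, 2, 2))), 1, 2),
               "constant")
})

test_that("independent noise bands are nearly uncorrelated", {
  zetas <- sapply(1:5, function(s) {
    set.seed(400 + s)
    arr <- array(sample(0:4095, 128 * 256 * 2, TRUE), c(128, 256, 2))
    spectral_correlation(hyperspectral_cube(arr), 1, 2)
  })
  expect_true(all(abs(zetas) < 0.02))
})

test_that("correlation curves track the AR(1) decay and transpose swaps them", {
  f <- ar1_field(512, 512, 0.95, seed = 81)
  cb <- hyperspectral_cube(array(pmax(pmin(round(2048 + 400 * f), 4095), 0),
                                 c(512, 512, 1)))
  cur <- correlation_curves(cb, 1, lag_max = 10)
  expect_true(all(abs(cur$row_corr - 0.95^(1:10)) < 0.03))
  expect_true(all(abs(cur$col_corr - 0.95^(1:10)) < 0.03))

  tcb <- hyperspectral_cube(array(t(matrix(cb$data[, , 1], 512, 512)), c(512, 512, 1)))
  tcur <- correlation_curves(tcb, 1, lag_max = 10)
  expect_equal(tcur$row_corr, cur$col_corr, tolerance = 1e-12)
  expect_equal(tcur$col_corr, cur$row_corr, tolerance = 1e-12)
})

test_that("evaluation reports aggregate correctly and survive JSON round-trips", {
  gen <- generate_cube(tea_like_spec(seed = 6, a = 24L, b = 24L, c = 6L))
  set.seed(5)
  noisy <- hyperspectral_cube(pmin(pmax(gen$cube$data +
             array(round(rnorm(prod(dim(gen$cube$data)), sd = 30)),
                   dim(gen$cube$data)), 0), 4095), 12L, gen$cube$wavelengths)
  rep <- evaluate(gen$cube, noisy, lag_max = 5)
  expect_length(rep$per_band_psnr, 6)
  # the aggregate is the 3-D MSE, not the mean of per-band PSNRs
  expect_equal(rep$psnr_db, as.numeric(psnr(gen$cube, noisy)), tolerance = 1e-12)
  mse_band <- sapply(1:6, function(z) mean((gen$cube$data[, , z] - noisy$data[, , z])^2))
  expect_equal(rep$psnr_db, 10 * log10(4095^2 / mean(mse_band)), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(rep$psnr_db, mean(rep$per_band_psnr))))

  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$psnr_db, rep$psnr_db, tolerance = 1e-9)
  expect_equal(back$per_band_psnr, rep$per_band_psnr, tolerance = 1e-9)
  expect_equal(back$spectral_corr$original, rep$spectral_corr$original,
               tolerance = 1e-9)
})

test_that("showcase bands follow the wavelength axis when present", {
  gen <- generate_cube(tea_like_spec(seed = 6, a = 16L, b = 16L, c = 40L))
  rep <- evaluate(gen$cube, gen$cube, lag_max = 2)
  wl <- gen$cube$wavelengths
  expect_identical(rep$showcase_bands,
                   vapply(c(440, 620, 980), function(w) which.min(abs(wl - w)),
                          integer(1)))
  expect_true(rep$identical)
})
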