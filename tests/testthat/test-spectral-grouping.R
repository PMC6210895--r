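test_that("band distance matches its closed form and the loop oracle", {
  arr <- array(0, c(128, 256, 2))
  arr[, , 2] <- 1
  cube <- hyperspectral_cube(arr)
  expect_identical(band_distance(cube, 1, matrix(cube$data[, , 1], 128, 256)), 0)
  expect_equal(band_distance(cube, 2, matrix(cube$data[, , 1], 128, 256)),
               sqrt(128 * 256), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:5) {
    A <- matrix(runif(12 * 9, 0, 4095), 12, 9)
    cb <- hyperspectral_cube(array(round(A), c(12, 9, 1)))
    B <- matrix(runif(12 * 9, 0, 4095), 12, 9)
    expect_equal(band_distance(cb, 1, B),
                 band_dist_oracle(matrix(cb$data[, , 1], 12, 9), B),
                 tolerance = 1e-9)
  }
  expect_error(band_distance(cube, 1, matrix(0, 2, 2)), "shape")
})

test_that("k-means recovers duplicate-template bands exactly and k = c isolates bands", {
  set.seed(5)
  t1 <- matrix(sample(0:4095, 64, TRUE), 8, 8)
  t2 <- matrix(sample(0:4095, 64, TRUE), 8, 8)
  arr <- array(0, c(8, 8, 6))
  for (z in 1:3) arr[, , z] <- t1
  for (z in 4:6) arr[, , z] <- t2
  cube <- hyperspectral_cube(arr)
  g <- group_bands_kmeans(cube, k = 2, seed = 1)
  expect_setequal(lapply(g$groups, as.integer), list(1:3, 4:6))

  g1 <- group_bands_kmeans(cube, k = 6, seed = 1)
  expect_identical(lapply(g1$groups, as.integer), as.list(1:6))
  expect_error(group_bands_kmeans(cube, k = 7, seed = 1), "1..bands")
})

test_that("planted contiguous groups are recovered with k known and k auto", {
  for (s in 1:4) {
    gen <- generate_cube(tea_like_spec(seed = 500 + s, a = 64L, b = 64L, c = 24L))
    planted <- gen$grouping$groups
    for (kk in list(3, "auto")) {
      g <- group_bands_kmeans(gen$cube, k = kk, seed = s)
      expect_identical(lapply(g$groups, as.integer), lapply(planted, as.integer))
    }
  }
})

test_that("grouping agrees with the reference k-means on planted data", {
  gen <- generate_cube(tea_like_spec(seed = 99, a = 48L, b = 48L, c = 18L))
  d <- dim(gen$cube$data)
  X <- t(matrix(gen$cube$data, d[1] * d[2], d[3]))
  ref <- stats::kmeans(X, centers = 3, nstart = 5)
  ref_groups <- unname(split(seq_len(d[3]), ref$cluster))
  ref_groups <- ref_groups[order(vapply(ref_groups, min, integer(1)))]
  ours <- group_bands_kmeans(gen$cube, k = 3, seed = 7)
  expect_identical(lapply(ours$groups, as.integer), lapply(ref_groups, as.integer))
})

test_that("grouping is always a partition of the band axis", {
  for (s in 1:3) {
    cube <- random_cube(10, 10, 11, seed = 600 + s)
    g <- group_bands_kmeans(cube, k = 4, seed = s)
    got <- sort(unlist(g$groups))
    expect_identical(as.integer(got), 1:11)
  }
})

test_that("LMLSD matches the loop oracle, including single-interval degeneracy", {
  plan <- block_plan(8, 16, 16)
  set.seed(41)
  for (i in 1:5) {
    img <- matrix(runif(256, 100, 4000), 16, 16)
    cube <- hyperspectral_cube(array(round(img), c(16, 16, 1)))
    for (ni in c(1L, 10L)) {
      sc <- lmlsd_score(cube, 1, plan, n_intervals = ni)
      expect_equal(sc$R, lmlsd_oracle(matrix(cube$data[, , 1], 16, 16), 8, ni),
                   tolerance = 1e-9)
    }
  }
  # n_intervals = 1 reduces to all-block means over all-block stds
  img <- matrix(round(runif(256, 100, 4000)), 16, 16)
  cube <- hyperspectral_cube(array(img, c(16, 16, 1)))
  sc <- lmlsd_score(cube, 1, plan, n_intervals = 1L)
  X <- pssahcs:::band_to_blocks(img, plan)
  expect_equal(sc$R, 20 * log10(mean(colMeans(X)) / mean(apply(X, 2, sd))),
               tolerance = 1e-10)
  expect_error(lmlsd_score(hyperspectral_cube(array(5, c(16, 16, 1))), 1, plan),
               "constant")
})

test_that("LMLSD ranks a band lower as additive noise grows", {
  plan <- block_plan(8, 64, 64)
  for (s in 1:5) {
    base <- 2000 + 10 * ar1_field(64, 64, 0.995, seed = 700 + s)
    Rs <- sapply(c(0, 5, 20, 50), function(sd_n) {
      set.seed(800 + s + round(sd_n))
      img <- pmin(pmax(round(base + rnorm(64 * 64, sd = sd_n)), 0), 4095)
      lmlsd_score(hyperspectral_cube(array(img, c(64, 64, 1))), 1, plan)$R
    })
    expect_true(all(diff(Rs) < 0))
  }
})

test_that("key-band selection favours the clean band and breaks ties low", {
  plan <- block_plan(8, 64, 64)
  for (s in 1:5) {
    gen <- generate_cube(one_clean_band_spec(seed = 900 + s, noise_sd = 60))
    g <- select_key_bands(gen$cube, gen$grouping, plan)
    expect_identical(g$key_band, c(2L, 5L, 8L))
  }
  # identical bands: lowest index wins; singleton group keeps its band
  arr <- array(rep(matrix(round(runif(64, 0, 4095)), 8, 8), 3), c(8, 8, 3))
  cube <- hyperspectral_cube(arr)
  plan2 <- block_plan(4, 8, 8)
  g2 <- new_grouping_for_test(list(1:2, 3L))
  got <- select_key_bands(cube, g2, plan2)
  expect_identical(got$key_band, c(1L, 3L))
})
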