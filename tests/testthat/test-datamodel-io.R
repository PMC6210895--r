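test_that("cube construction validates range, shape and wavelengths", {
  expect_s3_class(hyperspectral_cube(array(0:7, c(2, 2, 2)), 12L), "hyperspectral_cube")
  expect_error(hyperspectral_cube(array(-1, c(2, 2, 1))), "lie in")
  expect_error(hyperspectral_cube(array(4096, c(2, 2, 1)), 12L), "lie in")
  expect_error(hyperspectral_cube(array(0, c(2, 2, 2)), wavelengths = c(500, 400)),
               "strictly increasing")
  expect_error(hyperspectral_cube(array(0, c(2, 2, 2)), wavelengths = 500),
               "one entry per band")
})

test_that("ENVI round-trip is the identity, including 12-bit extremes", {
  dir <- withr::local_tempdir()
  cube <- random_cube(6, 5, 3, seed = 11, wavelengths = c(400, 550, 700))
  cube$data[1, 1, 1] <- 4095  # full-scale value must survive
  hdr <- file.path(dir, "cube.hdr")
  write_envi(cube, hdr)
  back <- read_envi(hdr)
  expect_identical(back$data, cube$data)
  expect_identical(back$bit_depth, cube$bit_depth)
  expect_equal(back$wavelengths, cube$wavelengths)

  tiny <- hyperspectral_cube(array(c(0, 1, 2, 3), c(2, 2, 1)), 12L)
  hdr2 <- file.path(dir, "tiny.hdr")
  write_envi(tiny, hdr2)
  expect_identical(read_envi(hdr2)$data, tiny$data)
})

test_that("cube without wavelengths writes a readable header without them", {
  dir <- withr::local_tempdir()
  cube <- random_cube(4, 4, 2, seed = 3)
  hdr <- file.path(dir, "nw.hdr")
  write_envi(cube, hdr)
  expect_false(any(grepl("wavelength =", readLines(hdr))))
  expect_null(read_envi(hdr)$wavelengths)
})

test_that("declared dimensions are honoured and mismatches are errors", {
  dir <- withr::local_tempdir()
  cube <- random_cube(128, 256, 2, seed = 5)
  hdr <- file.path(dir, "big.hdr")
  write_envi(cube, hdr)
  got <- read_envi(hdr)
  expect_identical(dim(got$data)[1:2], c(128L, 256L))

  # truncate the raw file: fewer samples than the header implies
  raw <- file.path(dir, "big.raw")
  sz <- file.info(raw)$size
  con <- file(raw, "r+b"); seek(con, sz - 100, rw = "write"); truncate(con); close(con)
  expect_error(read_envi(hdr), "bytes")
})

test_that("header parsing tolerates whitespace, ordering and multi-line blocks", {
  dir <- withr::local_tempdir()
  vals <- as.integer(c(10, 20, 30, 40, 50, 60))
  raw <- file.path(dir, "x.raw")
  writeBin(vals, raw, size = 2L, endian = "little")
  writeLines(c("ENVI",
               "interleave =  bsq  ",
               "bands =   3",
               "data type = 12",
               "wavelength = {400.0,",
               "  500.0, 600.0}",
               "lines = 1",
               "  samples =  2 ",
               "byte order = 0"),
             file.path(dir, "x.hdr"))
  cube <- read_envi(file.path(dir, "x.hdr"))
  expect_equal(dim(cube$data), c(1L, 2L, 3L))
  expect_equal(cube$wavelengths, c(400, 500, 600))
  expect_equal(as.vector(cube$data), c(10, 20, 30, 40, 50, 60))
})

test_that("BIL and BIP interleaves are converted to band-sequential on read", {
  dir <- withr::local_tempdir()
  a <- 2L; b <- 3L; c_ <- 2L
  arr <- array(seq_len(a * b * c_) * 10, c(a, b, c_))
  for (il in c("bil", "bip")) {
    vals <- if (il == "bil") {
      as.integer(aperm(arr, c(2, 3, 1)))   # cols, bands, rows
    } else {
      as.integer(aperm(arr, c(3, 2, 1)))   # bands, cols, rows
    }
    raw <- file.path(dir, paste0(il, ".raw"))
    writeBin(vals, raw, size = 2L, endian = "little")
    writeLines(c("ENVI", sprintf("samples = %d", b), sprintf("lines = %d", a),
                 sprintf("bands = %d", c_), "data type = 12",
                 sprintf("interleave = %s", il)),
               file.path(dir, paste0(il, ".hdr")))
    cube <- read_envi(file.path(dir, paste0(il, ".hdr")))
    expect_equal(cube$data, arr, ignore_attr = TRUE, info = il)
  }
})

test_that("compressed-package container round-trips bit-exactly and detects damage", {
  dir <- withr::local_tempdir()
  gen <- generate_cube(tea_like_spec(seed = 2, a = 32L, b = 32L, c = 8L))
  cfg <- pssahcs_config(bpp = 0.25, kmeans_seed = 9, matrix_seed = 42)
  pkg <- compress(gen$cube, cfg)
  path <- file.path(dir, "x.pssahcs")
  save_package(pkg, path)
  back <- load_package(path)

  expect_identical(back$grouping$groups, pkg$grouping$groups)
  expect_identical(back$grouping$key_band, pkg$grouping$key_band)
  expect_identical(back$config$matrix_seed, 42L)
  expect_identical(back$config$kmeans_seed, 9L)
  expect_identical(back$predictors, pkg$predictors)
  expect_identical(back$measurements, pkg$measurements)
  expect_identical(back$plan$M, pkg$plan$M)

  # truncation is flagged
  sz <- file.info(path)$size
  con <- file(path, "r+b"); seek(con, sz - 10, rw = "write"); truncate(con); close(con)
  expect_error(load_package(path), "truncated|corrupt")

  # wrong magic is flagged
  bad <- file.path(dir, "bad.pssahcs")
  writeBin(charToRaw("NOTAPKG1whatever"), bad)
  expect_error(load_package(bad), "magic")
})
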