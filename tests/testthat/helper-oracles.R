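# Literal double-loop transcriptions of the evaluation formulas, kept naive on
# purpose: they are the independent oracles the vectorized implementations are
# checked against.

eta_oracle <- function(img, dx, dy) {
  a <- nrow(img); b <- ncol(img)
  fbar <- mean(img)
  num <- 0; den <- 0
  for (x in seq_len(a - dx)) {
    for (y in seq_len(b - dy)) {
      num <- num + (img[x, y] - fbar) * (img[x + dx, y + dy] - fbar)
      den <- den + (img[x, y] - fbar)^2
    }
  }
  min(max(num / den, -1), 1)
}

band_dist_oracle <- function(A, B) {
  s <- 0
  for (x in seq_len(nrow(A))) for (y in seq_len(ncol(A))) {
    s <- s + (A[x, y] - B[x, y])^2
  }
  sqrt(s)
}

# sub-block local means / local standard deviations score; shares the
# bin-edge convention (equal-width, right-closed except the first) since the
# formulas do not define it
lmlsd_oracle <- function(img, M, n_intervals) {
  a <- nrow(img); b <- ncol(img)
  stopifnot(a %% M == 0, b %% M == 0)
  Ms <- c(); Ds <- c()
  for (r0 in seq(1, a, by = M)) for (c0 in seq(1, b, by = M)) {
    blk <- img[r0:(r0 + M - 1), c0:(c0 + M - 1)]
    n <- M * M
    mu <- sum(blk) / n
    Ms <- c(Ms, mu)
    Ds <- c(Ds, sqrt(sum((blk - mu)^2) / (n - 1)))
  }
  lo <- min(Ds); hi <- max(Ds)
  if (lo == hi) {
    sel <- rep(TRUE, length(Ds))
  } else {
    breaks <- seq(lo, hi, length.out = n_intervals + 1)
    bin <- integer(length(Ds))
    for (i in seq_along(Ds)) {
      bin[i] <- 1L
      for (j in seq_len(n_intervals)) {
        if (Ds[i] > breaks[j] && Ds[i] <= breaks[j + 1]) bin[i] <- j
      }
    }
    counts <- sapply(seq_len(n_intervals), function(j) sum(bin == j))
    sel <- bin == which.max(counts)
  }
  20 * log10(mean(Ms[sel]) / mean(Ds[sel]))
}

psnr_oracle <- function(orig, recon, n_bits) {
  d <- dim(orig)
  s <- 0
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    s <- s + abs(orig[x, y, z] - recon[x, y, z])^2
  }
  mse <- s / prod(d)
  10 * log10((2^n_bits - 1)^2 / mse)
}

zeta_oracle <- function(f1, f2) {
  m1 <- mean(f1); m2 <- mean(f2)
  num <- 0; d1 <- 0; d2 <- 0
  for (x in seq_len(nrow(f1))) for (y in seq_len(ncol(f1))) {
    num <- num + (f1[x, y] - m1) * (f2[x, y] - m2)
    d1 <- d1 + (f1[x, y] - m1)^2
    d2 <- d2 + (f2[x, y] - m2)^2
  }
  num / sqrt(d1 * d2)
}

new_grouping_for_test <- function(groups) {
  pssahcs:::new_grouping(groups, length(groups), 1L)
}

# small random integer cube for I/O and metric tests
random_cube <- function(a, b, c, n_bits = 12L, seed = 1L, wavelengths = NULL) {
  set.seed(seed)
  arr <- array(sample.int(2^n_bits, a * b * c, replace = TRUE) - 1L, c(a, b, c))
  hyperspectral_cube(arr, n_bits, wavelengths)
}

# synthetic spec for key-band selection checks: every band in a group shares
# the same affine map, all bands but one carry extra noise. The scene is
# smooth and low-contrast (gentle texture over a uniform level), the regime
# the local-statistics noise score is designed for.
one_clean_band_spec <- function(seed, noise_sd, a = 64L, b = 64L, c = 9L) {
  ranges <- list(1:3, 4:6, 7:9)
  clean <- c(2L, 5L, 8L)
  groups <- lapply(seq_along(ranges), function(g) {
    nb <- length(ranges[[g]])
    list(bands = ranges[[g]], level = 2000, slopes = rep(0.1, nb),
         intercepts = rep(0, nb))
  })
  noisy <- setdiff(1:9, clean)
  synth_spec(a, b, c, n_bits = 12L, rho = 0.99, groups = groups,
             noisy_bands = data.frame(band = noisy,
                                      sd = rep(noise_sd, length(noisy))),
             seed = seed)
}
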