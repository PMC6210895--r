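#' Discrete spatial autocorrelation of one band
#'
#' Normalized spatial autocorrelation between a band image and its shift by
#' `(dx, dy)` pixels (rows, columns). Both sums run over the pixel pairs where
#' both the pixel and its shifted partner lie inside the image; the
#' normalization is the sum of squared deviations of the unshifted samples
#' over those same pairs, using the full-band mean. The result is clipped to
#' `[-1, 1]`.
#'
#' @param cube A [hyperspectral_cube()].
#' @param band Band index (1-based).
#' @param dx Row lag, `0 <= dx < rows`.
#' @param dy Column lag, `0 <= dy < cols`.
#' @return Correlation in `[-1, 1]`.
#' @export
spatial_autocorrelation <- function(cube, band, dx, dy) {
  img <- cube_band(cube, band)
  spatial_autocorrelation_img(img, dx, dy)
}

# matrix version used internally (avoids re-slicing the cube in lag loops)
spatial_autocorrelation_img <- function(img, dx, dy) {
  a <- nrow(img); b <- ncol(img)
  dx <- as.integer(dx); dy <- as.integer(dy)
  if (dx < 0L || dx >= a || dy < 0L || dy >= b) {
    stop("lags must satisfy 0 <= dx < rows, 0 <= dy < cols", call. = FALSE)
  }
  fbar <- mean(img)
  base <- img[seq_len(a - dx), seq_len(b - dy), drop = FALSE] - fbar
  shft <- img[(1L + dx):a, (1L + dy):b, drop = FALSE] - fbar
  den <- sum(base^2)
  if (den == 0) stop("constant band: spatial autocorrelation undefined", call. = FALSE)
  min(max(sum(base * shft) / den, -1), 1)
}

#' Adaptively select the spatial block size
#'
#' For each candidate lag `1..lag_max`, computes the mean over a sample of
#' bands of the average of the row correlation (lag along rows) and column
#' correlation (lag along columns). The block size `M` is the smallest lag
#' whose mean correlation falls in `[lo, hi]` — blocks just large enough that
#' pixels a block apart are still strongly but not maximally correlated. If
#' every lag correlates above `hi` the image is smooth at all examined scales
#' and `M = lag_max`; if even lag 1 falls below `lo` the image carries no
#' usable spatial correlation and `M = block_min`.
#'
#' @param cube A [hyperspectral_cube()].
#' @param band_sample Band indices over which lag correlations are averaged.
#'   Default: 8 bands evenly spaced across the spectrum.
#' @param lag_max Largest lag examined (default 32).
#' @param lo,hi Admissible correlation band for the crossing (defaults 0.9 and
#'   0.95).
#' @param block_min,block_max Clamps on the returned block size. `block_min`
#'   (default 1) only engages on the no-correlation fallback; the codec
#'   front-end raises it to 8 so compressive sampling always has enough
#'   coefficients per block. `block_max` defaults to 64.
#' @return A `block_plan`: list with `M`, `pad_rows`, `pad_cols`, `a`, `b`,
#'   `a_pad`, `b_pad` and `blocks`, a data frame of 1-based `(row_start,
#'   col_start)` tile origins covering the padded grid.
#' @export
select_block_size <- function(cube, band_sample = NULL, lag_max = 32L,
                              lo = 0.9, hi = 0.95,
                              block_min = 1L, block_max = 64L) {
  d <- dim(cube$data)
  if (is.null(band_sample)) {
    band_sample <- unique(round(seq(1L, d[3L], length.out = min(8L, d[3L]))))
  }
  if (!length(band_sample)) stop("`band_sample` must be non-empty", call. = FALSE)
  lag_max <- as.integer(lag_max)
  if (lag_max < 1L) stop("`lag_max` must be >= 1", call. = FALSE)
  lag_max <- min(lag_max, d[1L] - 1L, d[2L] - 1L)

  mean_corr <- vapply(seq_len(lag_max), function(lag) {
    per_band <- vapply(band_sample, function(z) {
      img <- cube_band(cube, z)
      (spatial_autocorrelation_img(img, lag, 0L) +
         spatial_autocorrelation_img(img, 0L, lag)) / 2
    }, numeric(1L))
    mean(per_band)
  }, numeric(1L))

  ok <- which(mean_corr >= lo & mean_corr <= hi)
  M <- if (length(ok)) {
    ok[1L]
  } else if (mean_corr[1L] < lo) {
    block_min            # no spatial correlation to exploit
  } else {
    lag_max              # smooth beyond every examined lag
  }
  M <- max(M, block_min)
  M <- min(M, block_max, d[1L], d[2L])
  block_plan(M, d[1L], d[2L])
}

#' Build a block tiling plan for an `a x b` grid
#'
#' The grid is reflect-padded on the right/bottom edges so both dimensions
#' become multiples of `M`; tiles are disjoint `M x M` squares covering the
#' padded grid exactly.
#'
#' @param M Block size in pixels.
#' @param a,b Image rows and columns.
#' @return A `block_plan` list.
#' @export
block_plan <- function(M, a, b) {
  M <- as.integer(M); a <- as.integer(a); b <- as.integer(b)
  if (M < 1L) stop("block size must be >= 1", call. = FALSE)
  if (M > a || M > b) stop("block size exceeds image dimensions", call. = FALSE)
  pad_rows <- (M - a %% M) %% M
  pad_cols <- (M - b %% M) %% M
  a_pad <- a + pad_rows; b_pad <- b + pad_cols
  origins <- expand.grid(row_start = seq(1L, a_pad, by = M),
                         col_start = seq(1L, b_pad, by = M))
  structure(list(M = M, a = a, b = b, pad_rows = pad_rows, pad_cols = pad_cols,
                 a_pad = a_pad, b_pad = b_pad,
                 blocks = origins[order(origins$row_start, origins$col_start), ,
                                  drop = FALSE]),
            class = "block_plan")
}

#' @export
print.block_plan <- function(x, ...) {
  cat(sprintf("<block_plan> M = %d, grid %dx%d (+%d,+%d pad), %d blocks\n",
              x$M, x$a, x$b, x$pad_rows, x$pad_cols, nrow(x$blocks)))
  invisible(x)
}

# Reflect-pad a band image to the plan's padded dimensions.
pad_band <- function(img, plan) {
  a <- nrow(img); b <- ncol(img)
  if (plan$pad_rows > 0L) {
    ref <- img[a:(a - plan$pad_rows + 1L), , drop = FALSE]
    img <- rbind(img, ref)
  }
  if (plan$pad_cols > 0L) {
    ref <- img[, ncol(img):(ncol(img) - plan$pad_cols + 1L), drop = FALSE]
    img <- cbind(img, ref)
  }
  img
}

unpad_band <- function(img, plan) img[seq_len(plan$a), seq_len(plan$b), drop = FALSE]

# Extract all blocks of a padded band as an N x n_blocks matrix of row-major
# vectorized pixels (N = M^2), block order matching plan$blocks.
band_to_blocks <- function(img_pad, plan) {
  M <- plan$M
  nb <- nrow(plan$blocks)
  out <- matrix(0, M * M, nb)
  for (i in seq_len(nb)) {
    r0 <- plan$blocks$row_start[i]; c0 <- plan$blocks$col_start[i]
    blk <- img_pad[r0:(r0 + M - 1L), c0:(c0 + M - 1L)]
    out[, i] <- as.vector(t(blk))    # row-major raster order
  }
  out
}

blocks_to_band <- function(X, plan) {
  M <- plan$M
  img <- matrix(0, plan$a_pad, plan$b_pad)
  for (i in seq_len(ncol(X))) {
    r0 <- plan$blocks$row_start[i]; c0 <- plan$blocks$col_start[i]
    img[r0:(r0 + M - 1L), c0:(c0 + M - 1L)] <- t(matrix(X[, i], M, M))
  }
  img
}
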