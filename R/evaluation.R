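#' Peak signal-to-noise ratio between two cubes
#'
#' Mean squared error over all `rows x cols x bands` voxels;
#' `PSNR = 10 log10((2^n - 1)^2 / MSE)` with `n` the bit depth. Identical
#' cubes return `Inf` carrying attribute `identical = TRUE`.
#'
#' @param orig,recon Cubes of identical shape and bit depth.
#' @param bands Optional band subset over which the MSE is taken.
#' @return PSNR in dB.
#' @export
psnr <- function(orig, recon, bands = NULL) {
  stopifnot(inherits(orig, "hyperspectral_cube"), inherits(recon, "hyperspectral_cube"))
  if (!identical(dim(orig$data), dim(recon$data))) stop("cube shapes differ", call. = FALSE)
  if (orig$bit_depth != recon$bit_depth) stop("cube bit depths differ", call. = FALSE)
  x <- orig$data; y <- recon$data
  if (!is.null(bands)) {
    x <- x[, , bands, drop = FALSE]; y <- y[, , bands, drop = FALSE]
  }
  mse <- mean((x - y)^2)
  if (mse == 0) return(structure(Inf, identical = TRUE))
  10 * log10(dn_max(orig)^2 / mse)
}

#' Spectral correlation coefficient between two bands
#'
#' Pearson-form correlation over pixels of the two band images. High between
#' adjacent bands of a well-behaved spectrum; drops sharply at noisy
#' atmospheric-absorption bands.
#'
#' @param cube A [hyperspectral_cube()].
#' @param z1,z2 Band indices.
#' @return Correlation in `[-1, 1]`.
#' @export
spectral_correlation <- function(cube, z1, z2) {
  f1 <- cube_band(cube, z1); f2 <- cube_band(cube, z2)
  d1 <- f1 - mean(f1); d2 <- f2 - mean(f2)
  den <- sqrt(sum(d1^2) * sum(d2^2))
  if (den == 0) stop("constant band: spectral correlation undefined", call. = FALSE)
  min(max(sum(d1 * d2) / den, -1), 1)
}

#' Row and column spatial-correlation curves for one band
#'
#' @param cube A [hyperspectral_cube()].
#' @param band Band index.
#' @param lag_max Largest lag.
#' @return List with `lag` (`1..lag_max`), `row_corr` (lag along rows),
#'   `col_corr` (lag along columns).
#' @export
correlation_curves <- function(cube, band, lag_max) {
  img <- cube_band(cube, band)
  lag <- seq_len(lag_max)
  list(lag = lag,
       row_corr = vapply(lag, function(d) spatial_autocorrelation_img(img, d, 0L), numeric(1L)),
       col_corr = vapply(lag, function(d) spatial_autocorrelation_img(img, 0L, d), numeric(1L)))
}

#' Full spatial/spectral evaluation of a reconstruction
#'
#' Aggregates PSNR (3-D MSE over all voxels, plus per-band PSNR), spatial
#' row/column correlation curves on showcase bands, the adjacent-band
#' spectral-correlation curve, and the mean spectral profiles of both cubes.
#' Showcase bands default to the nearest wavelengths to 440, 620 and 980 nm
#' when a wavelength axis is present, else first/middle/last band.
#'
#' @param orig,recon Cubes of identical shape.
#' @param bands Showcase band indices (optional).
#' @param lag_max Largest lag for the correlation curves (default 20).
#' @return An `evaluation_report` list.
#' @export
evaluate <- function(orig, recon, bands = NULL, lag_max = 20L) {
  d <- dim(orig$data)
  if (is.null(bands)) {
    bands <- if (!is.null(orig$wavelengths)) {
      vapply(c(440, 620, 980), function(w) which.min(abs(orig$wavelengths - w)), integer(1L))
    } else {
      unique(c(1L, max(1L, round(d[3L] / 2)), d[3L]))
    }
    bands <- unique(pmin(pmax(bands, 1L), d[3L]))
  }
  p <- psnr(orig, recon)
  per_band <- vapply(seq_len(d[3L]), function(z) as.numeric(psnr(orig, recon, bands = z)),
                     numeric(1L))
  curves <- lapply(bands, function(z) {
    list(band = z,
         original = correlation_curves(orig, z, lag_max),
         reconstructed = correlation_curves(recon, z, lag_max))
  })
  zeta <- function(cb) vapply(seq_len(d[3L] - 1L), function(z)
    spectral_correlation(cb, z, z + 1L), numeric(1L))
  structure(list(
    psnr_db = as.numeric(p),
    identical = isTRUE(attr(p, "identical")),
    per_band_psnr = per_band,
    showcase_bands = bands,
    spatial_curves = curves,
    spectral_corr = list(original = zeta(orig), reconstructed = zeta(recon)),
    spectral_profiles = list(original = apply(orig$data, 3L, mean),
                             reconstructed = apply(recon$data, 3L, mean)),
    wavelengths = orig$wavelengths
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  PSNR: %s dB\n", if (x$identical) "identical cubes" else sprintf("%.4f", x$psnr_db)))
  cat(sprintf("  per-band PSNR: %.2f - %.2f dB over %d bands\n",
              min(x$per_band_psnr), max(x$per_band_psnr), length(x$per_band_psnr)))
  cat(sprintf("  showcase bands: %s\n", paste(x$showcase_bands, collapse = ", ")))
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An `evaluation_report` from [evaluate()].
#' @param path Destination JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an evaluation report from JSON
#'
#' @param path JSON path written by [write_report()].
#' @return An `evaluation_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "evaluation_report")
}
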