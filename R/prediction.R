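#' Fit the affine interband predictor
#'
#' Least-squares fit of `target ~ m * ref + n` over all pixels, in the moment
#' form: `m = (E[ref*target] - E[ref]E[target]) / (E[ref^2] - E[ref]^2)` and
#' `n = E[target] - m * E[ref]`. Within a spectral group the non-key bands are
#' near-affine functions of the key band, so two coefficients per band capture
#' most of the interband redundancy.
#'
#' @param ref_image 2-D reference (key-band) image.
#' @param target_image 2-D image to be predicted; same shape.
#' @return A `predictor_pair` list: `m` (slope), `n` (intercept, DN).
#' @export
fit_predictor <- function(ref_image, target_image) {
  ref_image <- as.matrix(ref_image); target_image <- as.matrix(target_image)
  if (!identical(dim(ref_image), dim(target_image))) {
    stop("reference and target images must have the same shape", call. = FALSE)
  }
  N <- length(ref_image)
  u_r <- sum(ref_image) / N
  u_g <- sum(target_image) / N
  R_rg <- sum(ref_image * target_image) / N
  R_rr <- sum(ref_image * ref_image) / N
  den <- R_rr - u_r^2
  if (den <= 0 || !is.finite(den)) {
    stop("constant reference image: predictor slope undefined", call. = FALSE)
  }
  m <- (R_rg - u_r * u_g) / den
  n <- u_g - m * u_r
  structure(list(m = m, n = n), class = "predictor_pair")
}

#' Apply an affine predictor to a reference image
#'
#' @param ref_image 2-D reference image.
#' @param pair A `predictor_pair` from [fit_predictor()].
#' @return Elementwise `m * ref + n`, unrounded.
#' @export
predict_band <- function(ref_image, pair) {
  pair$m * ref_image + pair$n
}

#' Prediction residual
#'
#' @param target_image Actual band image.
#' @param predicted_image Prediction from the key band.
#' @return Signed real residual `target - predicted`.
#' @export
residual_image <- function(target_image, predicted_image) {
  if (!identical(dim(as.matrix(target_image)), dim(as.matrix(predicted_image)))) {
    stop("shapes differ", call. = FALSE)
  }
  target_image - predicted_image
}

#' Rebuild a band from its prediction and a reconstructed residual
#'
#' @param predicted_image Prediction from the (reconstructed) key band.
#' @param recon_residual Reconstructed residual image.
#' @param bit_depth If given, the sum is clipped to `[0, 2^bit_depth - 1]` and
#'   rounded — final-output quantization, applied exactly once per band.
#' @return Reconstructed band image.
#' @export
reconstruct_band <- function(predicted_image, recon_residual, bit_depth = NULL) {
  out <- predicted_image + recon_residual
  if (!is.null(bit_depth)) out <- clip_round_dn(out, bit_depth)
  out
}
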