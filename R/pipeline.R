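#' Codec configuration
#'
#' All tunables of the compressor in one record. The rate knob `bpp` follows
#' the block-CS convention in which the nominal rate equals the sampling
#' fraction at native bit depth: each band receives
#' `round(bpp * n_pixels * bit_depth / quant_bits)` quantized measurements, so
#' with `quant_bits` equal to the cube's depth, `bpp = 0.25` means 25% of the
#' pixel count in measurements.
#'
#' @param bpp Rate target (default 0.25); the four customary operating points
#'   are 0.10, 0.15, 0.20, 0.25.
#' @param quant_bits Measurement quantizer depth in bits (default 12).
#' @param k Number of spectral groups, or `"auto"` (default).
#' @param kmeans_seed Seed for the grouping k-means (default 1).
#' @param contiguity Keep groups contiguous in wavelength (default TRUE).
#' @param adjacent_corr_threshold Boundary threshold for `k = "auto"`.
#' @param lmlsd_intervals Histogram intervals for the LMLSD key-band score.
#' @param lag_max,corr_lo,corr_hi Block-size selection parameters.
#' @param band_sample_count Bands averaged for block-size selection.
#' @param block_min,block_max Block-size clamps for the codec (8 and 64: CS on
#'   blocks below 8x8 has too few transform coefficients; beyond 64x64 the
#'   per-block solve dominates runtime).
#' @param stomp_t,stomp_max_stages,stomp_tol StOMP parameters.
#' @param matrix_seed Seed of the shared Gaussian measurement matrix.
#' @param budget_split Ratio of the key-band to residual-band per-band
#'   measurement budget (default 1 = equal; `Inf` sends the whole pair budget
#'   to key bands and codes residuals with zero measurements).
#' @return A `pssahcs_config` list.
#' @export
pssahcs_config <- function(bpp = 0.25, quant_bits = 12L, k = "auto",
                           kmeans_seed = 1L, contiguity = TRUE,
                           adjacent_corr_threshold = 0.9,
                           lmlsd_intervals = 10L,
                           lag_max = 32L, corr_lo = 0.9, corr_hi = 0.95,
                           band_sample_count = 8L,
                           block_min = 8L, block_max = 64L,
                           stomp_t = 2.5, stomp_max_stages = 10L,
                           stomp_tol = 1e-6, matrix_seed = 1L,
                           budget_split = 1.0) {
  bpp <- as.numeric(bpp)
  budget_split <- as.numeric(budget_split)  # "Inf" survives JSON as a string
  if (bpp <= 0) stop("`bpp` must be positive", call. = FALSE)
  structure(list(bpp = bpp, quant_bits = as.integer(quant_bits), k = k,
                 kmeans_seed = as.integer(kmeans_seed), contiguity = contiguity,
                 adjacent_corr_threshold = adjacent_corr_threshold,
                 lmlsd_intervals = as.integer(lmlsd_intervals),
                 lag_max = as.integer(lag_max), corr_lo = corr_lo,
                 corr_hi = corr_hi,
                 band_sample_count = as.integer(band_sample_count),
                 block_min = as.integer(block_min),
                 block_max = as.integer(block_max),
                 stomp_t = stomp_t,
                 stomp_max_stages = as.integer(stomp_max_stages),
                 stomp_tol = stomp_tol, matrix_seed = as.integer(matrix_seed),
                 budget_split = budget_split),
            class = "pssahcs_config")
}

# Per-band measurement budgets. T is the per-band pair budget; the split s
# (key : residual) allocates 2T/(1+s) to residual bands and 2Ts/(1+s) to keys.
band_budgets <- function(cfg, plan, n_bits) {
  npix <- plan$a_pad * plan$b_pad
  T_pair <- round(cfg$bpp * npix * n_bits / cfg$quant_bits)
  s <- cfg$budget_split
  if (is.infinite(s)) {
    T_key <- 2L * T_pair; T_res <- 0L
  } else {
    T_key <- round(2 * T_pair * s / (1 + s))
    T_res <- round(2 * T_pair / (1 + s))
  }
  nb <- nrow(plan$blocks); N <- plan$M^2
  list(key = min(T_key, nb * N), res = min(T_res, nb * N))
}

# Spread T measurements over nb blocks: floor(T/nb) each, first blocks get one
# extra. T = 0 is the degenerate zero-budget path; 0 < T < nb is infeasible.
distribute_measurements <- function(T_band, plan, cfg, n_bits) {
  nb <- nrow(plan$blocks)
  if (T_band == 0L) return(rep(0L, nb))
  if (T_band < nb) {
    min_bpp <- nb * cfg$quant_bits / (plan$a_pad * plan$b_pad * n_bits)
    stop(sprintf(paste0("infeasible rate: %.4g bpp gives fewer than one ",
                        "measurement per block; minimum achievable bpp is %.4g"),
                 cfg$bpp, min_bpp), call. = FALSE)
  }
  m_lo <- T_band %/% nb
  extra <- T_band - m_lo * nb
  m <- rep(m_lo, nb)
  if (extra > 0L) m[seq_len(extra)] <- m_lo + 1L
  as.integer(m)
}

# Sense one band image: subtract the band mean (stored as side information,
# so blocks are AC-scale and the quantizer range is not wasted on the DC
# pedestal), pad, tile, project, keep the per-block measurement counts,
# quantize. Returns the stored-form measurement record.
encode_band <- function(img, plan, op, m_per_block, q_bits) {
  mu <- mean(img)
  if (all(m_per_block == 0L)) {
    return(list(codes = integer(0), lo = 0, hi = 0, mean = mu,
                m_per_block = m_per_block))
  }
  X <- band_to_blocks(pad_band(img - mu, plan), plan)
  Y <- op$Phi %*% X
  keep <- sequence(m_per_block)  # row indices, block-major
  y_all <- Y[cbind(keep, rep(seq_along(m_per_block), m_per_block))]
  qm <- quantize_measurements(y_all, q_bits)
  list(codes = qm$codes, lo = qm$lo, hi = qm$hi, mean = mu,
       m_per_block = m_per_block)
}

# Inverse of encode_band up to CS recovery: dequantize, StOMP, synthesize,
# untile, unpad. Returns the real-valued band image.
decode_band <- function(meas, plan, op, cfg, q_bits) {
  nb <- nrow(plan$blocks)
  if (all(meas$m_per_block == 0L)) {
    return(matrix(meas$mean, plan$a, plan$b))
  }
  y_all <- dequantize_measurements(list(codes = meas$codes, lo = meas$lo,
                                        hi = meas$hi, q_bits = q_bits))
  Y <- matrix(0, max(meas$m_per_block), nb)
  Y[cbind(sequence(meas$m_per_block), rep(seq_len(nb), meas$m_per_block))] <- y_all
  X <- reconstruct_blocks(Y, meas$m_per_block, op, t = cfg$stomp_t,
                          max_stages = cfg$stomp_max_stages, tol = cfg$stomp_tol)
  meas$mean + unpad_band(blocks_to_band(X, plan), plan)
}

#' Compress a hyperspectral cube
#'
#' Runs the full encoder: adaptive block-size selection, k-means spectral
#' grouping, LMLSD key-band selection, compressive sampling of each key band,
#' closed-loop affine prediction of the non-key bands from the *reconstructed*
#' key band (so the encoder's reference is exactly what the decoder will
#' have), compressive sampling of the prediction residuals, and uniform scalar
#' quantization of all measurements. The measurement matrix is regenerated
#' from its seed at decode time; only seeds, side information and quantized
#' measurements enter the package.
#'
#' @param cube A [hyperspectral_cube()].
#' @param cfg A [pssahcs_config()].
#' @return A `compressed_package`; see [save_package()] for the on-disk form.
#' @export
compress <- function(cube, cfg = pssahcs_config()) {
  stopifnot(inherits(cube, "hyperspectral_cube"), inherits(cfg, "pssahcs_config"))
  d <- dim(cube$data)
  band_sample <- unique(round(seq(1L, d[3L],
                                  length.out = min(cfg$band_sample_count, d[3L]))))
  plan <- select_block_size(cube, band_sample = band_sample,
                            lag_max = cfg$lag_max, lo = cfg$corr_lo,
                            hi = cfg$corr_hi, block_min = cfg$block_min,
                            block_max = cfg$block_max)
  grouping <- if (d[3L] == 1L) {
    g <- new_grouping(list(1L), 1L, cfg$kmeans_seed); g$key_band <- 1L; g
  } else {
    g <- group_bands_kmeans(cube, k = cfg$k, seed = cfg$kmeans_seed,
                            contiguity = cfg$contiguity,
                            adjacent_corr_threshold = cfg$adjacent_corr_threshold)
    select_key_bands(cube, g, plan, cfg$lmlsd_intervals)
  }

  budgets <- band_budgets(cfg, plan, cube$bit_depth)
  m_key <- distribute_measurements(budgets$key, plan, cfg, cube$bit_depth)
  m_res <- distribute_measurements(budgets$res, plan, cfg, cube$bit_depth)
  m_hi <- max(m_key, m_res, 1L)
  # residual bands get their own matrix (seed + 1): a residual is precisely
  # the component the key-band solve could not explain under the key matrix,
  # so re-projecting it with the same rows would carry no new information
  op_key <- make_operator(plan$M, m_hi, cfg$matrix_seed)
  op_res <- make_operator(plan$M, m_hi, cfg$matrix_seed + 1L)

  meas <- vector("list", d[3L])
  predictors <- data.frame(band = seq_len(d[3L]), key_band = NA_integer_,
                           m = NA_real_, n = NA_real_)
  for (g in seq_along(grouping$groups)) {
    kb <- grouping$key_band[g]
    key_img <- cube_band(cube, kb)
    meas[[kb]] <- encode_band(key_img, plan, op_key, m_key, cfg$quant_bits)
    key_rec <- decode_band(meas[[kb]], plan, op_key, cfg, cfg$quant_bits)
    for (z in setdiff(grouping$groups[[g]], kb)) {
      target <- cube_band(cube, z)
      pair <- tryCatch(fit_predictor(key_rec, target),
                       error = function(e) list(m = 0, n = mean(target)))
      predictors$key_band[z] <- kb
      predictors$m[z] <- pair$m
      predictors$n[z] <- pair$n
      resid <- residual_image(target, predict_band(key_rec, pair))
      meas[[z]] <- encode_band(resid, plan, op_res, m_res, cfg$quant_bits)
    }
  }

  meas_bits <- sum(vapply(meas, function(m) length(m$codes), integer(1L))) *
    cfg$quant_bits
  side_bits <- 2L * 64L * sum(!is.na(predictors$key_band))
  structure(list(
    version = 1L, config = cfg, plan = plan, grouping = grouping,
    predictors = predictors, measurements = meas, m_hi = m_hi,
    original_dims = d, bit_depth = cube$bit_depth,
    wavelengths = cube$wavelengths,
    bits = list(measurement_bits = meas_bits, side_bits = side_bits,
                realized_rate = meas_bits / (plan$a_pad * plan$b_pad * d[3L] *
                                               cube$bit_depth),
                bits_per_pixel = meas_bits / prod(d))
  ), class = "compressed_package")
}

#' @export
print.compressed_package <- function(x, ...) {
  d <- x$original_dims
  cat(sprintf("<compressed_package> %dx%dx%d, %d-bit, M = %d, %d group(s)\n",
              d[1L], d[2L], d[3L], x$bit_depth, x$plan$M,
              length(x$grouping$groups)))
  cat(sprintf("  rate: %.4f (nominal %.4f), %.3f bits/pixel stored\n",
              x$bits$realized_rate, x$config$bpp, x$bits$bits_per_pixel))
  invisible(x)
}

#' Decompress a package back to a cube
#'
#' Regenerates the sensing operator from the recorded seed, StOMP-reconstructs
#' every key band, then every residual band, applies the stored affine
#' predictors to the reconstructed key bands, and rounds/clips once to the DN
#' range. Needs nothing beyond the package itself.
#'
#' @param pkg A `compressed_package` from [compress()] or [load_package()].
#' @return A [hyperspectral_cube()] with the original shape and bit depth.
#' @export
decompress <- function(pkg) {
  stopifnot(inherits(pkg, "compressed_package"))
  cfg <- pkg$config; plan <- pkg$plan
  d <- pkg$original_dims
  op_key <- make_operator(plan$M, pkg$m_hi, cfg$matrix_seed)
  op_res <- make_operator(plan$M, pkg$m_hi, cfg$matrix_seed + 1L)
  out <- array(0, dim = d)
  for (g in seq_along(pkg$grouping$groups)) {
    kb <- pkg$grouping$key_band[g]
    key_rec <- decode_band(pkg$measurements[[kb]], plan, op_key, cfg, cfg$quant_bits)
    out[, , kb] <- clip_round_dn(key_rec, pkg$bit_depth)
    for (z in setdiff(pkg$grouping$groups[[g]], kb)) {
      resid_rec <- decode_band(pkg$measurements[[z]], plan, op_res, cfg, cfg$quant_bits)
      pair <- list(m = pkg$predictors$m[z], n = pkg$predictors$n[z])
      out[, , z] <- reconstruct_band(predict_band(key_rec, pair), resid_rec,
                                     bit_depth = pkg$bit_depth)
    }
  }
  hyperspectral_cube(out, pkg$bit_depth, pkg$wavelengths)
}

#' Per-band blocked compressive sensing baseline
#'
#' The comparison codec: identical block plan, sensing operator, rate mapping
#' and quantizer, but every band is sampled and reconstructed independently —
#' no grouping, no key bands, no prediction.
#'
#' @param cube A [hyperspectral_cube()].
#' @param cfg A [pssahcs_config()] (grouping fields are ignored).
#' @return List with `recon` (the reconstructed cube) and `bits` (accounting
#'   as in [compress()]).
#' @export
baseline_blocked_cs <- function(cube, cfg = pssahcs_config()) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  d <- dim(cube$data)
  band_sample <- unique(round(seq(1L, d[3L],
                                  length.out = min(cfg$band_sample_count, d[3L]))))
  plan <- select_block_size(cube, band_sample = band_sample,
                            lag_max = cfg$lag_max, lo = cfg$corr_lo,
                            hi = cfg$corr_hi, block_min = cfg$block_min,
                            block_max = cfg$block_max)
  npix <- plan$a_pad * plan$b_pad
  T_band <- min(round(cfg$bpp * npix * cube$bit_depth / cfg$quant_bits),
                nrow(plan$blocks) * plan$M^2)
  m_per_block <- distribute_measurements(T_band, plan, cfg, cube$bit_depth)
  op <- make_operator(plan$M, max(m_per_block), cfg$matrix_seed)
  out <- array(0, dim = d)
  total_codes <- 0L
  for (z in seq_len(d[3L])) {
    meas <- encode_band(cube_band(cube, z), plan, op, m_per_block, cfg$quant_bits)
    total_codes <- total_codes + length(meas$codes)
    out[, , z] <- clip_round_dn(decode_band(meas, plan, op, cfg, cfg$quant_bits),
                                cube$bit_depth)
  }
  bits <- total_codes * cfg$quant_bits
  list(recon = hyperspectral_cube(out, cube$bit_depth, cube$wavelengths),
       bits = list(measurement_bits = bits, side_bits = 0L,
                   realized_rate = bits / (npix * d[3L] * cube$bit_depth),
                   bits_per_pixel = bits / prod(d)))
}
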