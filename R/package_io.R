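#' Save a compressed package to a single `.pssahcs` file
#'
#' Container layout (version 1, little-endian throughout):
#'
#' 1. magic bytes `"PSSAHCS1"` (8 bytes);
#' 2. `int32` length of the JSON metadata block;
#' 3. JSON metadata: codec config, block plan, grouping, per-band measurement
#'    layout (`m_per_block`, code counts) and array directory;
#' 4. `double` array (8 bytes each): per band `lo, hi` quantizer range and
#'    `mean` (the band-mean offset removed before sensing), then per non-key
#'    band `m, n` predictor coefficients (bands ascending) — binary so the
#'    decode is bit-exact;
#' 5. per band (ascending), the quantized measurement codes as `uint16`
#'    (`quant_bits <= 16`) or `int32`.
#'
#' A trailing `int32` holds the total code count as a truncation check.
#'
#' @param pkg A `compressed_package` from [compress()].
#' @param path Destination path (conventionally `.pssahcs`).
#' @export
save_package <- function(pkg, path) {
  stopifnot(inherits(pkg, "compressed_package"))
  cfg <- pkg$config
  code_size <- if (cfg$quant_bits <= 16L) 2L else 4L
  c_ <- pkg$original_dims[3L]

  meta <- list(
    format = "pssahcs", version = pkg$version,
    config = unclass(cfg),
    plan = list(M = pkg$plan$M, a = pkg$plan$a, b = pkg$plan$b),
    grouping = list(groups = pkg$grouping$groups,
                    key_band = pkg$grouping$key_band,
                    k = pkg$grouping$k, seed = pkg$grouping$seed),
    predictor_bands = pkg$predictors$band[!is.na(pkg$predictors$key_band)],
    predictor_keys = pkg$predictors$key_band[!is.na(pkg$predictors$key_band)],
    m_hi = pkg$m_hi,
    original_dims = pkg$original_dims,
    bit_depth = pkg$bit_depth,
    wavelengths = pkg$wavelengths,
    bits = pkg$bits,
    m_per_block = lapply(pkg$measurements, `[[`, "m_per_block"),
    n_codes = vapply(pkg$measurements, function(m) length(m$codes), integer(1L)),
    code_size = code_size
  )
  meta_json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null")
  meta_raw <- charToRaw(as.character(meta_json))

  pred_idx <- which(!is.na(pkg$predictors$key_band))
  dbl <- c(rbind(vapply(pkg$measurements, `[[`, numeric(1L), "lo"),
                 vapply(pkg$measurements, `[[`, numeric(1L), "hi"),
                 vapply(pkg$measurements, `[[`, numeric(1L), "mean")),
           as.vector(rbind(pkg$predictors$m[pred_idx],
                           pkg$predictors$n[pred_idx])))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("PSSAHCS1"), con)
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  writeBin(dbl, con, size = 8L, endian = "little")
  total <- 0L
  for (z in seq_len(c_)) {
    codes <- pkg$measurements[[z]]$codes
    total <- total + length(codes)
    if (length(codes)) {
      if (code_size == 2L) codes <- ifelse(codes > 32767L, codes - 65536L, codes)
      writeBin(as.integer(codes), con, size = code_size, endian = "little")
    }
  }
  writeBin(total, con, size = 4L, endian = "little")
  invisible(path)
}

#' Load a compressed package from disk
#'
#' @param path A file written by [save_package()].
#' @return A `compressed_package`, bit-identical to the one saved.
#' @export
load_package <- function(path) {
  if (!file.exists(path)) stop("package file not found: ", path, call. = FALSE)
  fsize <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- rawToChar(readBin(con, "raw", n = 8L))
  if (!identical(magic, "PSSAHCS1")) {
    stop("not a pssahcs package (bad magic / unsupported version): ", path,
         call. = FALSE)
  }
  meta_len <- readBin(con, integer(), size = 4L, endian = "little")
  if (!length(meta_len) || meta_len <= 0L || meta_len > fsize) {
    stop("corrupted package: bad metadata length", call. = FALSE)
  }
  meta_raw <- readBin(con, "raw", n = meta_len)
  if (length(meta_raw) < meta_len) stop("corrupted package: truncated metadata", call. = FALSE)
  meta <- jsonlite::fromJSON(rawToChar(meta_raw), simplifyVector = TRUE)
  if (!identical(meta$format, "pssahcs") || meta$version != 1L) {
    stop("unsupported package version", call. = FALSE)
  }

  c_ <- meta$original_dims[3L]
  n_pred <- length(meta$predictor_bands)
  n_dbl <- 3L * c_ + 2L * n_pred
  dbl <- readBin(con, numeric(), n = n_dbl, size = 8L, endian = "little")
  if (length(dbl) < n_dbl) stop("corrupted package: truncated coefficient block", call. = FALSE)

  cfg <- do.call(pssahcs_config, meta$config)
  plan <- block_plan(meta$plan$M, meta$plan$a, meta$plan$b)
  groups <- meta$grouping$groups
  if (!is.list(groups)) groups <- lapply(seq_len(nrow(groups)), function(i) groups[i, ])
  grouping <- new_grouping(lapply(groups, as.integer),
                           meta$grouping$k, meta$grouping$seed)
  grouping$key_band <- as.integer(meta$grouping$key_band)

  predictors <- data.frame(band = seq_len(c_), key_band = NA_integer_,
                           m = NA_real_, n = NA_real_)
  los <- dbl[seq(1L, 3L * c_, by = 3L)]
  his <- dbl[seq(2L, 3L * c_, by = 3L)]
  means <- dbl[seq(3L, 3L * c_, by = 3L)]
  if (n_pred) {
    pred_dbl <- dbl[(3L * c_ + 1L):n_dbl]
    pb <- as.integer(meta$predictor_bands)
    predictors$key_band[pb] <- as.integer(meta$predictor_keys)
    predictors$m[pb] <- pred_dbl[seq(1L, 2L * n_pred, by = 2L)]
    predictors$n[pb] <- pred_dbl[seq(2L, 2L * n_pred, by = 2L)]
  }

  code_size <- meta$code_size
  mpb <- meta$m_per_block
  if (!is.list(mpb)) mpb <- lapply(seq_len(nrow(mpb)), function(i) mpb[i, ])
  meas <- vector("list", c_)
  for (z in seq_len(c_)) {
    n_codes <- meta$n_codes[z]
    codes <- if (n_codes > 0L) {
      got <- if (code_size == 2L) {
        readBin(con, integer(), n = n_codes, size = 2L, signed = FALSE,
                endian = "little")
      } else {
        readBin(con, integer(), n = n_codes, size = 4L, endian = "little")
      }
      if (length(got) < n_codes) stop("corrupted package: truncated measurements", call. = FALSE)
      got
    } else integer(0)
    meas[[z]] <- list(codes = codes, lo = los[z], hi = his[z], mean = means[z],
                      m_per_block = as.integer(mpb[[z]]))
  }
  total <- readBin(con, integer(), size = 4L, endian = "little")
  if (!length(total) || total != sum(meta$n_codes)) {
    stop("corrupted package: truncated file", call. = FALSE)
  }

  structure(list(
    version = 1L, config = cfg, plan = plan, grouping = grouping,
    predictors = predictors, measurements = meas, m_hi = as.integer(meta$m_hi),
    original_dims = as.integer(meta$original_dims),
    bit_depth = as.integer(meta$bit_depth),
    wavelengths = if (is.null(meta$wavelengths) || !length(meta$wavelengths)) NULL
                  else as.numeric(meta$wavelengths),
    bits = meta$bits
  ), class = "compressed_package")
}
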