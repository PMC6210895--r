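#' Construct a hyperspectral cube
#'
#' A hyperspectral cube is a 3-D array of non-negative integer digital numbers
#' (DN) indexed `(row, col, band)`, together with its bit depth and an optional
#' wavelength axis. All codec stages in this package operate on this container.
#'
#' @param data 3-D numeric array, dimensions `rows x cols x bands`, all values
#'   integers in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Bits per pixel (default 12, the usual depth of scientific
#'   visible/NIR line-scan cameras).
#' @param wavelengths Optional numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per band.
#' @return An object of class `hyperspectral_cube`: a list with elements
#'   `data`, `bit_depth`, `wavelengths`.
#' @export
hyperspectral_cube <- function(data, bit_depth = 12L, wavelengths = NULL) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (rows x cols x bands)", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L || bit_depth > 32L) stop("`bit_depth` must be in 1..32", call. = FALSE)
  if (anyNA(data)) stop("cube contains NA values", call. = FALSE)
  dn_max <- 2^bit_depth - 1
  if (min(data) < 0 || max(data) > dn_max) {
    stop(sprintf("cube values must lie in [0, %d]", dn_max), call. = FALSE)
  }
  if (!is.null(wavelengths)) {
    wavelengths <- as.numeric(wavelengths)
    if (length(wavelengths) != dim(data)[3L]) {
      stop("`wavelengths` must have one entry per band", call. = FALSE)
    }
    if (any(diff(wavelengths) <= 0)) {
      stop("`wavelengths` must be strictly increasing", call. = FALSE)
    }
  }
  storage.mode(data) <- "double"
  structure(
    list(data = data, bit_depth = bit_depth, wavelengths = wavelengths),
    class = "hyperspectral_cube"
  )
}

#' @export
dim.hyperspectral_cube <- function(x) dim(x$data)

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyperspectral_cube> %d x %d pixels, %d bands, %d-bit\n",
              d[1L], d[2L], d[3L], x$bit_depth))
  if (!is.null(x$wavelengths)) {
    cat(sprintf("  wavelengths: %.1f - %.1f nm\n",
                x$wavelengths[1L], x$wavelengths[length(x$wavelengths)]))
  }
  rng <- range(x$data)
  cat(sprintf("  DN range: [%g, %g]\n", rng[1L], rng[2L]))
  invisible(x)
}

# Extract one band as a 2-D matrix.
cube_band <- function(cube, band) {
  d <- dim(cube$data)
  if (band < 1L || band > d[3L]) stop("band index out of range", call. = FALSE)
  matrix(cube$data[, , band], d[1L], d[2L])
}

#' Number of rows, columns and bands of a cube
#' @param cube A `hyperspectral_cube`.
#' @return Integer vector `c(rows, cols, bands)`.
#' @export
cube_dims <- function(cube) dim(cube$data)

#' @keywords internal
dn_max <- function(cube_or_bits) {
  bits <- if (inherits(cube_or_bits, "hyperspectral_cube")) cube_or_bits$bit_depth else cube_or_bits
  2^bits - 1
}

# Clip to the DN range and round to integers; used once, at final codec output.
clip_round_dn <- function(x, bit_depth) {
  pmin(pmax(round(x), 0), 2^bit_depth - 1)
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
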