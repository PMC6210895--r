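#' Separable AR(1) Gaussian random field
#'
#' White noise filtered by a first-order autoregression along rows and then
#' along columns, giving expected lag-1 autocorrelation `rho` in both
#' directions (and `rho^d` at lag `d`). The recursion is warmed up over a
#' cropped margin so the field is stationary, and the output is standardized
#' to mean 0, variance 1.
#'
#' @param a,b Field dimensions (rows, cols).
#' @param rho Per-step correlation, `0 <= rho < 1`.
#' @param seed Integer seed.
#' @return `a x b` matrix.
#' @export
ar1_field <- function(a, b, rho, seed) {
  if (rho < 0 || rho >= 1) stop("`rho` must be in [0, 1)", call. = FALSE)
  warm <- if (rho > 0) max(32L, ceiling(log(1e-6) / log(rho))) else 0L
  aw <- a + warm; bw <- b + warm
  z <- with_seed(seed, matrix(stats::rnorm(aw * bw), aw, bw))
  if (rho > 0) {
    s <- sqrt(1 - rho^2)
    # innovations scaled so the stationary variance is 1; the zero-init
    # transient decays inside the cropped warm-up margin
    z <- apply(z * s, 2L, function(col) {
      as.numeric(stats::filter(col, rho, method = "recursive"))
    })
    z <- t(apply(z, 1L, function(row) {
      as.numeric(stats::filter(row * s, rho, method = "recursive"))
    }))
  }
  z <- z[(warm + 1L):aw, (warm + 1L):bw, drop = FALSE]
  (z - mean(z)) / stats::sd(z)
}

#' Synthetic-cube specification
#'
#' Describes a cube with the statistical structure a spatial-spectral codec
#' exploits: one spatially autocorrelated latent scene per spectral group,
#' bands within a group that are affine transforms of their group scene, and
#' designated noisy bands with extra additive Gaussian noise (emulating
#' atmospheric-absorption bands at the ends of a visible/NIR spectrum).
#'
#' @param a,b,c Rows, columns, bands.
#' @param n_bits Bit depth (default 12).
#' @param rho Spatial AR(1) correlation per pixel step (default 0.97).
#' @param groups List of group descriptors, each a list with `bands` (index
#'   range), `level` (base DN level), `slopes` and `intercepts` (per-band
#'   affine coefficients relative to the group scene).
#' @param noisy_bands Data frame with columns `band`, `sd` (additive noise
#'   std in DN).
#' @param seed Integer seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(a, b, c, n_bits = 12L, rho = 0.97, groups,
                       noisy_bands = data.frame(band = integer(), sd = numeric()),
                       seed = 1L) {
  covered <- sort(unlist(lapply(groups, `[[`, "bands")))
  if (!identical(as.integer(covered), seq_len(c))) {
    stop("group band ranges must partition 1..c", call. = FALSE)
  }
  if (any(noisy_bands$sd < 0)) stop("noise std must be >= 0", call. = FALSE)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 n_bits = as.integer(n_bits), rho = rho, groups = groups,
                 noisy_bands = noisy_bands, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Tea-like synthetic cube preset
#'
#' The default study preset: a 128 x 256 x 40 cube of 12-bit DN emulating a
#' visible/NIR leaf scene — three contiguous spectral groups (a chlorophyll-
#' absorption-like visible regime, a red-edge transition and a NIR plateau,
#' each its own latent scene at a distinct base level), strong spatial
#' autocorrelation (`rho = 0.97`), and noisy bands (std 60 DN) at both
#' spectral ends where atmospheric absorption degrades real sensors.
#'
#' @param seed Integer seed.
#' @param a,b,c Optional overrides of the preset dimensions.
#' @param noise_sd Noise std (DN) for the end bands (default 60).
#' @return A `synth_spec`.
#' @export
tea_like_spec <- function(seed = 1L, a = 128L, b = 256L, c = 40L, noise_sd = 60) {
  stopifnot(c >= 6L)
  cuts <- round(c(c / 3, 2 * c / 3))
  ranges <- list(1:cuts[1L], (cuts[1L] + 1L):cuts[2L], (cuts[2L] + 1L):c)
  levels <- c(1600, 2050, 2500)
  groups <- lapply(seq_along(ranges), function(g) {
    nb <- length(ranges[[g]])
    # slopes swing +/-10% within the group but return to 1 at the group ends,
    # so the noisy end bands are not also the extreme-slope bands
    j <- seq_len(nb)
    list(bands = ranges[[g]],
         level = levels[g],
         slopes = 1 + 0.1 * sin(2 * pi * (j - 1) / max(nb - 1, 1)),
         intercepts = seq(-80, 80, length.out = nb))
  })
  noisy <- data.frame(band = c(1L, 2L, c - 1L, c),
                      sd = rep(noise_sd, 4L))
  synth_spec(a, b, c, n_bits = 12L, rho = 0.97, groups = groups,
             noisy_bands = noisy, seed = seed)
}

#' Generate a synthetic hyperspectral cube
#'
#' Draws one AR(1) scene per group, maps each band through its affine
#' coefficients onto the DN scale (scene std 400 DN, keeping the signal in
#' roughly the central 80% of the 12-bit range so clipping is rare and the
#' planted affine relations survive rounding), adds i.i.d. Gaussian noise to
#' the designated noisy bands, and rounds/clips to the DN range.
#'
#' @param spec A [synth_spec()].
#' @return List with `cube` (the noisy integer cube), `clean` (the noise-free
#'   integer cube), `grouping` (the planted `spectral_grouping`), and
#'   `clean_real` (the unrounded noise-free bands, for affine-recovery
#'   checks).
#' @export
generate_cube <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  a <- spec$a; b <- spec$b; c_ <- spec$c
  scene_sd <- 400
  arr <- array(0, dim = c(a, b, c_))
  clean <- array(0, dim = c(a, b, c_))
  clean_real <- array(0, dim = c(a, b, c_))
  noise_seed_base <- spec$seed + 10000L

  for (g in seq_along(spec$groups)) {
    grp <- spec$groups[[g]]
    scene <- ar1_field(a, b, spec$rho, seed = spec$seed + g)
    for (j in seq_along(grp$bands)) {
      z <- grp$bands[j]
      band_real <- grp$level + grp$intercepts[j] +
        grp$slopes[j] * scene_sd * scene
      clean_real[, , z] <- band_real
      clean[, , z] <- clip_round_dn(band_real, spec$n_bits)
      hit <- match(z, spec$noisy_bands$band)
      noisy <- if (!is.na(hit) && spec$noisy_bands$sd[hit] > 0) {
        band_real + with_seed(noise_seed_base + z, {
          matrix(stats::rnorm(a * b, sd = spec$noisy_bands$sd[hit]), a, b)
        })
      } else {
        band_real
      }
      arr[, , z] <- clip_round_dn(noisy, spec$n_bits)
    }
  }

  wl <- seq(380, 1030, length.out = c_)
  grouping <- new_grouping(lapply(spec$groups, `[[`, "bands"),
                           length(spec$groups), spec$seed)
  list(cube = hyperspectral_cube(arr, spec$n_bits, wl),
       clean = hyperspectral_cube(clean, spec$n_bits, wl),
       grouping = grouping,
       clean_real = clean_real)
}
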