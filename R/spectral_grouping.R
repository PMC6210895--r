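#' Euclidean distance between a band and a centroid image
#'
#' Square root of the sum of squared pixel differences — the distance used by
#' the band-grouping k-means.
#'
#' @param cube A [hyperspectral_cube()].
#' @param zi Band index.
#' @param zc_image 2-D centroid image with the cube's spatial dimensions.
#' @return Non-negative distance.
#' @export
band_distance <- function(cube, zi, zc_image) {
  img <- cube_band(cube, zi)
  if (!identical(dim(img), dim(as.matrix(zc_image)))) {
    stop("centroid image shape does not match band shape", call. = FALSE)
  }
  sqrt(sum((img - zc_image)^2))
}

#' Group bands by k-means clustering
#'
#' Lloyd-style k-means over vectorized band images with Euclidean distance,
#' seeded k-means++ initialization, deterministic tie-breaks toward the lower
#' index, and re-seeding of empty clusters from the farthest band. With
#' `contiguity = TRUE` (default) labels are smoothed with a width-3 majority
#' filter until stable, so groups form contiguous wavelength runs — the regime
#' in which predicting a band from its group's key band is physically
#' meaningful.
#'
#' With `k = "auto"` the number of groups is chosen from the adjacent-band
#' spectral correlation: every drop of the correlation between neighbouring
#' bands below `adjacent_corr_threshold` marks a group boundary (noisy
#' atmospheric-absorption bands and reflectance regime changes produce such
#' drops), and the resulting contiguous runs seed the k-means.
#'
#' @param cube A [hyperspectral_cube()].
#' @param k Number of groups, or `"auto"`.
#' @param seed Integer RNG seed recorded in the result.
#' @param contiguity Enforce contiguous-in-wavelength groups (default TRUE).
#' @param adjacent_corr_threshold Boundary threshold for `k = "auto"`
#'   (default 0.9).
#' @param max_iter Lloyd iteration cap (default 300).
#' @return A `spectral_grouping`: list with `groups` (list of band-index
#'   vectors), `key_band` (NA until [select_key_bands()]), `k`, `seed`.
#' @export
group_bands_kmeans <- function(cube, k = "auto", seed = 1L, contiguity = TRUE,
                               adjacent_corr_threshold = 0.9, max_iter = 300L) {
  d <- dim(cube$data)
  c_ <- d[3L]
  X <- matrix(cube$data, d[1L] * d[2L], c_)   # pixels x bands

  init_centroids <- NULL
  if (identical(k, "auto")) {
    zeta <- vapply(seq_len(c_ - 1L), function(z) {
      spectral_correlation(cube, z, z + 1L)
    }, numeric(1L))
    boundaries <- which(zeta < adjacent_corr_threshold)
    runs <- split(seq_len(c_), findInterval(seq_len(c_), boundaries + 1L))
    k <- length(runs)
    init_centroids <- vapply(runs, function(idx) {
      rowMeans(X[, idx, drop = FALSE])
    }, numeric(nrow(X)))
  } else {
    k <- as.integer(k)
    if (k < 1L || k > c_) stop("`k` must be in 1..bands", call. = FALSE)
  }
  if (k >= c_) {
    grouping <- new_grouping(as.list(seq_len(c_)), c_, seed)
    return(grouping)
  }

  labels <- with_seed(seed, {
    cent <- if (is.null(init_centroids)) kmeanspp_init(X, k) else init_centroids
    lloyd(X, cent, k, max_iter)
  })

  if (contiguity) {
    labels <- smooth_labels(labels)
    groups <- label_runs(labels)
  } else {
    groups <- unname(split(seq_along(labels), labels))
    groups <- groups[order(vapply(groups, min, integer(1L)))]
  }
  new_grouping(groups, length(groups), seed)
}

new_grouping <- function(groups, k, seed) {
  structure(list(groups = groups, key_band = rep(NA_integer_, length(groups)),
                 k = k, seed = as.integer(seed)),
            class = "spectral_grouping")
}

#' @export
print.spectral_grouping <- function(x, ...) {
  cat(sprintf("<spectral_grouping> %d group(s)\n", length(x$groups)))
  for (g in seq_along(x$groups)) {
    idx <- x$groups[[g]]
    kb <- x$key_band[g]
    cat(sprintf("  group %d: bands %d..%d (%d)%s\n", g, min(idx), max(idx),
                length(idx),
                if (is.na(kb)) "" else sprintf(", key band %d", kb)))
  }
  invisible(x)
}

# k-means++ seeding over columns of X (bands); uses the current RNG stream.
kmeanspp_init <- function(X, k) {
  c_ <- ncol(X)
  centers <- integer(k)
  centers[1L] <- sample.int(c_, 1L)
  d2 <- colSums((X - X[, centers[1L]])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(c_, 1L)
    } else {
      centers[j + 1L] <- sample.int(c_, 1L, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, colSums((X - X[, centers[j + 1L]])^2))
  }
  X[, centers, drop = FALSE]
}

lloyd <- function(X, cent, k, max_iter) {
  c_ <- ncol(X)
  labels <- integer(c_)
  for (it in seq_len(max_iter)) {
    # squared distances bands x k; ties break toward the lower cluster index
    d2 <- outer(colSums(X^2), colSums(cent^2), "+") - 2 * crossprod(X, cent)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty clusters: re-seed from the band farthest from its centroid
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        resid <- d2[cbind(seq_len(c_), new_labels)]
        far <- which.max(resid)
        new_labels[far] <- j
        d2[far, ] <- Inf  # pin it
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      cent[, j] <- rowMeans(X[, labels == j, drop = FALSE])
    }
  }
  labels
}

# Width-3 majority relabeling along the band axis, iterated to stability.
smooth_labels <- function(labels) {
  c_ <- length(labels)
  if (c_ < 3L) return(labels)
  for (pass in seq_len(c_)) {
    new <- labels
    for (i in 2L:(c_ - 1L)) {
      win <- labels[(i - 1L):(i + 1L)]
      tab <- table(win)
      if (max(tab) >= 2L) {
        new[i] <- as.integer(names(tab)[which.max(tab)])
      }
    }
    if (identical(new, labels)) break
    labels <- new
  }
  labels
}

# maximal runs of equal labels, in band order
label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(seq_along(ends), function(i) starts[i]:ends[i])
}

#' Score a band's noise level by local means / local standard deviations
#'
#' Each sub-block of the band (per the block plan) contributes its mean DN and
#' its sample standard deviation. The range of sub-block standard deviations
#' is divided into `n_intervals` equal-width intervals; within the interval
#' holding the most sub-blocks (the modal interval — the band's "typical"
#' local texture), the mean of the block means and the mean of the block
#' standard deviations give the score `R = 20 log10(M_mean / D_mean)` in dB.
#' Noisier bands have inflated local standard deviations and hence lower `R`.
#'
#' @param cube A [hyperspectral_cube()].
#' @param band Band index.
#' @param plan A [block_plan()].
#' @param n_intervals Number of equal-width histogram intervals (default 10).
#' @return An `lmlsd_score` list: `band`, `R` (dB), `modal_interval` (lo, hi),
#'   `M_mean`, `D_mean`.
#' @export
lmlsd_score <- function(cube, band, plan, n_intervals = 10L) {
  img <- pad_band(cube_band(cube, band), plan)
  X <- band_to_blocks(img, plan)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L) stop("`n_intervals` must be >= 1", call. = FALSE)
  M_num <- colMeans(X)
  D_num <- sqrt(colSums((X - rep(M_num, each = nrow(X)))^2) / (nrow(X) - 1L))
  if (all(D_num == 0)) stop("all sub-blocks constant: LMLSD undefined", call. = FALSE)

  lo <- min(D_num); hi <- max(D_num)
  if (lo == hi) {
    sel <- rep(TRUE, length(D_num))
    modal <- c(lo, hi)
  } else {
    breaks <- seq(lo, hi, length.out = n_intervals + 1L)
    # right-closed bins except the first; modal ties break toward lower interval
    bin <- pmin(pmax(findInterval(D_num, breaks, left.open = TRUE), 1L), n_intervals)
    counts <- tabulate(bin, nbins = n_intervals)
    m <- which.max(counts)
    sel <- bin == m
    modal <- c(breaks[m], breaks[m + 1L])
  }
  M_mean <- mean(M_num[sel])
  D_mean <- mean(D_num[sel])
  if (D_mean == 0) stop("modal interval has zero standard deviation: LMLSD undefined", call. = FALSE)
  structure(list(band = band, R = 20 * log10(M_mean / D_mean),
                 modal_interval = modal, M_mean = M_mean, D_mean = D_mean),
            class = "lmlsd_score")
}

#' Select each group's key band by the LMLSD criterion
#'
#' The key band of a group is the band with the largest LMLSD score `R` — the
#' least-noisy band, which is compressed directly and serves as the prediction
#' reference for the rest of the group. Ties break toward the smaller band
#' index; singleton groups keep their only band.
#'
#' @param cube A [hyperspectral_cube()].
#' @param grouping A `spectral_grouping` from [group_bands_kmeans()].
#' @param plan A [block_plan()].
#' @param n_intervals Passed to [lmlsd_score()].
#' @return The grouping with `key_band` filled in.
#' @export
select_key_bands <- function(cube, grouping, plan, n_intervals = 10L) {
  stopifnot(inherits(grouping, "spectral_grouping"))
  grouping$key_band <- vapply(grouping$groups, function(idx) {
    if (length(idx) == 1L) return(as.integer(idx))
    R <- vapply(idx, function(z) lmlsd_score(cube, z, plan, n_intervals)$R,
                numeric(1L))
    as.integer(idx[which.max(R)])   # which.max breaks ties toward lower index
  }, integer(1L))
  grouping
}
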