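#' Orthonormal DCT-II matrix
#'
#' Rows are the type-II discrete cosine basis functions, scaled so the matrix
#' is orthonormal (`C %*% t(C) = I`).
#'
#' @param M Transform size.
#' @return `M x M` matrix.
#' @export
dct_matrix <- function(M) {
  M <- as.integer(M)
  i <- 0:(M - 1L)
  C <- sqrt(2 / M) * cos(pi * outer(i, 2L * i + 1L) / (2 * M))
  C[1L, ] <- sqrt(1 / M)
  C
}

#' Build the sensing operator for one block geometry
#'
#' The measurement matrix `Phi` has i.i.d. Gaussian entries with mean 0 and
#' variance `1/m_meas` (so its columns have expected unit norm), drawn from
#' the recorded seed — the decoder regenerates it from the seed rather than
#' transmitting it. The sparse basis `Psi` is the separable orthonormal
#' inverse 2-D DCT acting on row-major vectorized `M x M` blocks, and
#' `A = Phi %*% Psi` is the combined sensing matrix StOMP works against.
#'
#' @param M Block size in pixels.
#' @param m_meas Number of measurements per block, `1 <= m_meas <= M^2`.
#' @param seed Integer seed for `Phi`.
#' @return A `sensing_operator` list: `Phi`, `Psi`, `A`, `M`, `m_meas`, `seed`.
#' @export
make_operator <- function(M, m_meas, seed) {
  M <- as.integer(M); m_meas <- as.integer(m_meas)
  N <- M * M
  if (m_meas < 1L || m_meas > N) {
    stop(sprintf("`m_meas` must be in 1..%d", N), call. = FALSE)
  }
  # rows are filled from the seed stream row-by-row, so operators with larger
  # m_meas extend smaller ones: raising the rate adds measurements instead of
  # redrawing the whole matrix, and a per-block budget of m or m+1 rows reuses
  # the same projections
  Phi <- with_seed(seed, {
    matrix(stats::rnorm(m_meas * N), m_meas, N, byrow = TRUE) / sqrt(m_meas)
  })
  C <- dct_matrix(M)
  # row-major vec: vec_r(C' Theta C) = (C' %x% C') vec_r(Theta)
  Psi <- kronecker(t(C), t(C))
  structure(list(Phi = Phi, Psi = Psi, A = Phi %*% Psi,
                 M = M, m_meas = m_meas, seed = as.integer(seed)),
            class = "sensing_operator")
}

#' Compressively sample one block
#'
#' @param block_pixels Numeric vector of length `M^2` (row-major vectorized
#'   block) or an `M x M` matrix.
#' @param op A [make_operator()] result.
#' @return Measurement vector `y = Phi %*% x` of length `m_meas`.
#' @export
sense <- function(block_pixels, op) {
  if (is.matrix(block_pixels)) block_pixels <- as.vector(t(block_pixels))
  if (length(block_pixels) != ncol(op$Phi)) {
    stop("block length does not match the operator's M^2", call. = FALSE)
  }
  drop(op$Phi %*% block_pixels)
}

#' Stagewise orthogonal matching pursuit
#'
#' Greedy sparse recovery of `x` from `y = A %*% x`. Each stage matched-filters
#' the residual (`c = t(A) %*% r`, normalized by the column norms), estimates
#' the formal noise level `sigma = ||r|| / sqrt(m)`, admits every atom with
#' `|c_j| / ||a_j|| > t * sigma` into the running support (strongest first;
#' the support is capped at `m/2` atoms, past which the refit would start
#' interpolating measurement noise), and least-squares refits `y` on the
#' support. If no atom clears the threshold while the support is still empty
#' — unavoidable when `m <= t^2`, since the normalized correlation cannot
#' exceed `sqrt(m) * sigma` — a single matching-pursuit step admits the
#' strongest atom. Stops when the residual falls below `tol * ||y||`, no new
#' atoms qualify, or `max_stages` is reached.
#'
#' @param y Measurement vector (length `m`).
#' @param A `m x N` sensing matrix.
#' @param t Threshold multiplier (default 2.5; the customary range is 2–3).
#' @param max_stages Stage cap (default 10).
#' @param tol Relative residual stopping tolerance (default 1e-6).
#' @return Length-`N` coefficient vector, zero off-support.
#' @export
stomp <- function(y, A, t = 2.5, max_stages = 10L, tol = 1e-6) {
  if (t <= 0) stop("`t` must be positive", call. = FALSE)
  if (length(y) != nrow(A)) stop("length(y) must equal nrow(A)", call. = FALSE)
  drop(stomp_cpp(A, as.numeric(y), t, as.integer(max_stages), tol))
}

#' Reconstruct one block from its measurements
#'
#' Runs [stomp()] on the combined matrix `A = Phi %*% Psi` and synthesizes
#' pixels through the inverse DCT.
#'
#' @param y Measurement vector.
#' @param op A [make_operator()] result.
#' @inheritParams stomp
#' @return `M x M` matrix of reconstructed pixel values (unrounded).
#' @export
reconstruct_block <- function(y, op, t = 2.5, max_stages = 10L, tol = 1e-6) {
  coef <- stomp(y, op$A, t = t, max_stages = max_stages, tol = tol)
  x <- drop(op$Psi %*% coef)
  t(matrix(x, op$M, op$M))   # undo row-major vectorization
}

# Batch reconstruction of many blocks sharing the operator geometry; column i
# of Y carries m_per_col[i] valid measurements against the first m_per_col[i]
# rows of op$A.
reconstruct_blocks <- function(Y, m_per_col, op, t = 2.5, max_stages = 10L,
                               tol = 1e-6) {
  coefs <- stomp_batch_cpp(op$A, Y, as.integer(m_per_col), t,
                           as.integer(max_stages), tol)
  op$Psi %*% coefs
}

# Uniform scalar quantizer for measurement values: q bits, shared [lo, hi]
# range per band. Returns integer codes plus the range needed to dequantize.
quantize_measurements <- function(y, q_bits) {
  lo <- min(y); hi <- max(y)
  levels <- 2^q_bits - 1
  codes <- if (hi == lo) {
    rep(0L, length(y))
  } else {
    as.integer(round((y - lo) / (hi - lo) * levels))
  }
  list(codes = codes, lo = lo, hi = hi, q_bits = as.integer(q_bits))
}

dequantize_measurements <- function(qm) {
  if (qm$hi == qm$lo) return(rep(qm$lo, length(qm$codes)))
  qm$lo + qm$codes / (2^qm$q_bits - 1) * (qm$hi - qm$lo)
}
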