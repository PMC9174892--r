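#' Temporal phase unwrapping along the cardiac cycle
#'
#' Unwraps each voxel's phase time series independently. The series is
#' anchored at the frame of minimum absolute phase for that voxel (the frame
#' most likely to be alias-free: diastolic velocities are lowest) and the
#' remaining frames are visited cyclically forward from the anchor, forcing
#' every successive difference into `(-pi, pi]` by adding integer multiples
#' of `2*pi` cumulatively. The output differs from the input by voxelwise
#' integer multiples of `2*pi`.
#'
#' @param phase a wrapped `phase_map`.
#' @return a `phase_map` with `wrapped = FALSE`.
#' @export
unwrap_temporal <- function(phase) {
  stopifnot(inherits(phase, "phase_map"))
  phi <- lapply(phase$phi, unwrap_temporal_array)
  structure(list(phi = phi, wrapped = FALSE, mask = phase$mask,
                 venc = phase$venc),
            class = "phase_map")
}

# Core of the temporal unwrap on one (nx, ny, nz, nt) array; voxels with any
# non-finite frame are passed through untouched.
unwrap_temporal_array <- function(phi4) {
  d <- dim(phi4)
  nt <- d[4]
  if (nt < 2L) return(phi4)
  nvox <- prod(d[1:3])
  M <- matrix(phi4, nvox, nt)
  ok <- rowSums(!is.finite(M)) == 0L
  if (!any(ok)) return(phi4)
  M <- M[ok, , drop = FALSE]
  nr <- nrow(M)

  a <- max.col(-abs(M), ties.method = "first")      # anchor frame per voxel
  O <- (outer(a - 1L, 0:(nt - 1L), "+") %% nt) + 1L # cyclic visit order
  # plain vector index (a 2-column index matrix would be row/col pairs)
  lin <- as.vector((O - 1L) * nr + seq_len(nr))
  Mord <- matrix(M[lin], nr, nt)

  U <- Mord
  acc <- Mord[, 1L]
  for (k in 2:nt) {
    step <- wrap_phase(Mord[, k] - acc)
    acc <- acc + step
    U[, k] <- acc
  }
  M[lin] <- U

  out <- matrix(phi4, nvox, nt)
  out[ok, ] <- M
  array(out, d)
}

#' 4D Laplacian phase unwrapping
#'
#' Estimates the unwrapped phase by solving the Poisson problem
#' `lap(phi_est) = cos(phi_w) * lap(sin(phi_w)) - sin(phi_w) * lap(cos(phi_w))`
#' spectrally: a discrete cosine transform (Neumann boundary) over the three
#' spatial axes combined with a Fourier transform over the periodic time
#' axis diagonalizes the discrete Laplacian, the zero eigenvalue is dropped
#' (zero-mean gauge), and the estimate is snapped back to congruence with
#' the wrapped input: `phi_out = phi_w + 2*pi*round((phi_est - phi_w)/(2*pi))`,
#' so the output differs from the input by exact integer multiples of
#' `2*pi`.
#'
#' The spectral solve assumes a smooth underlying phase over the whole
#' grid. Vessel data violate that at the lumen boundary, where the phase
#' jumps to the empty (noise-only or undefined) background and the smooth
#' Poisson estimate would mis-snap boundary voxels; when a lumen mask is
#' present, voxels outside it are therefore replaced by a harmonic
#' (Jacobi-diffused) extension of the boundary phasors before the solve and
#' restored afterwards. Phantoms without a mask (all voxels valid) are
#' solved as-is.
#'
#' @param phase a `phase_map`.
#' @param fill_iters Jacobi iterations of the background phasor fill.
#' @return a `phase_map` with `wrapped = FALSE`.
#' @export
unwrap_laplacian4d <- function(phase, fill_iters = 20L) {
  stopifnot(inherits(phase, "phase_map"))
  mask <- phase$mask
  if (!is.null(mask) && all(mask)) mask <- NULL
  phi <- lapply(phase$phi, unwrap_laplacian_array, mask = mask,
                fill_iters = fill_iters,
                wrapped_fill = isTRUE(phase$wrapped))
  structure(list(phi = phi, wrapped = FALSE, mask = phase$mask,
                 venc = phase$venc),
            class = "phase_map")
}

unwrap_laplacian_array <- function(phi4, mask = NULL, fill_iters = 20L,
                                   wrapped_fill = TRUE) {
  if (all(phi4 == 0, na.rm = TRUE)) return(phi4)
  d <- dim(phi4)
  bad <- !is.finite(phi4)
  w <- phi4
  w[bad] <- 0
  if (!is.null(mask)) {
    w <- fill_background_phase(w, mask, fill_iters, wrapped = wrapped_fill)
  }

  eig <- laplace_eigenvalues(d)
  sp <- sin(w); cp <- cos(w)
  rhs <- cp * spectral_apply(sp, eig) - sp * spectral_apply(cp, eig)
  inv_eig <- 1 / eig
  inv_eig[eig == 0] <- 0
  est <- spectral_apply(rhs, inv_eig)
  est <- est + mean(w)   # gauge: the solve drops the DC component

  k2pi <- round((est - w) / (2 * pi))
  # Cleanup mode (already-unwrapped input, wrapped_fill = FALSE): the stage
  # acts as a second-pass cleaner after temporal unwrapping. A temporal
  # failure anchors a voxel on a wrapped frame and therefore offsets its
  # whole time series by one constant multiple of 2*pi, so only corrections
  # that are constant (and nonzero) across the cycle are trusted; per-frame
  # snap errors at steep wall gradients are time-varying and vetoed.
  if (!wrapped_fill && d[4] > 1L) {
    kmat <- matrix(k2pi, prod(d[1:3]), d[4])
    k2pi <- k2pi * rep(rows_all_equal(kmat), d[4])
  }
  out <- w + 2 * pi * k2pi
  out[bad] <- phi4[bad]
  if (!is.null(mask)) {
    bg <- rep(!mask, d[4])
    out[bg] <- phi4[bg]   # background keeps its original (noise) phase
  }
  out
}

# Extend the lumen phase into the background by Jacobi diffusion; lumen
# voxels stay fixed. Wrapped input diffuses the phasor components
# (wrap-robust); already-unwrapped input diffuses the raw values, which
# continues steep end-face phase smoothly instead of re-wrapping it.
fill_background_phase <- function(w, mask, iters, wrapped = TRUE) {
  d <- dim(w)
  bg <- !mask
  for (k in seq_len(d[4])) {
    wk <- w[, , , k]
    if (wrapped) {
      ck <- jacobi_fill3(cos(wk), mask, iters)
      sk <- jacobi_fill3(sin(wk), mask, iters)
      wk[bg] <- atan2(sk[bg], ck[bg])
    } else {
      fk <- jacobi_fill3(wk, mask, iters)
      wk[bg] <- fk[bg]
    }
    w[, , , k] <- wk
  }
  w
}

# Rows whose entries are all equal (to the first column).
rows_all_equal <- function(m) {
  rowSums(m != m[, 1L]) == 0L
}

# Eigenvalue array of the 4D discrete Laplacian under DCT-II (Neumann) along
# the three spatial axes and DFT (periodic) along time.
laplace_eigenvalues <- function(d) {
  lam <- function(n) 2 * cos(pi * (0:(n - 1)) / n) - 2
  lam_t <- function(n) 2 * cos(2 * pi * (0:(n - 1)) / n) - 2
  e1 <- lam(d[1]); e2 <- lam(d[2]); e3 <- lam(d[3]); e4 <- lam_t(d[4])
  arr <- array(e1, d)
  arr <- arr + array(rep(e2, each = d[1]), d)
  arr <- arr + array(rep(e3, each = d[1] * d[2]), d)
  arr + array(rep(e4, each = d[1] * d[2] * d[3]), d)
}

# Multiply the 4D spectrum of `f` by `factor_arr` and transform back:
# DCT-II (orthonormal) in space, FFT in time. Implemented with cyclic axis
# rotations so every matrix product acts on the leading axis (one aperm per
# stage instead of two).
spectral_apply <- function(f, factor_arr) {
  d <- dim(f)
  rot <- function(x) aperm(x, c(2, 3, 4, 1))
  mul <- function(M, x) {
    dx <- dim(x)
    y <- M %*% matrix(x, dx[1])
    dim(y) <- dx
    y
  }
  C <- lapply(d[1:3], dct_matrix)
  # forward: after three mul+rot steps the time axis leads
  f <- rot(mul(C[[1]], f))
  f <- rot(mul(C[[2]], f))
  f <- rot(mul(C[[3]], f))
  g <- stats::mvfft(matrix(f, d[4]))
  g <- g * matrix(aperm(factor_arr, c(4, 1, 2, 3)), d[4])
  f <- Re(stats::mvfft(g, inverse = TRUE)) / d[4]
  dim(f) <- d[c(4, 1, 2, 3)]
  # inverse DCTs, same rotation pattern
  f <- rot(f)                      # back to (1, 2, 3, 4)
  f <- rot(mul(t(C[[1]]), f))
  f <- rot(mul(t(C[[2]]), f))
  f <- mul(t(C[[3]]), f)           # dims (3, 4, 1, 2)
  aperm(f, c(3, 4, 1, 2))
}

# Orthonormal DCT-II matrix (rows = frequencies).
dct_matrix <- function(n) {
  j <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(j, 2 * j + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  C
}



#' Apply manual 2*pi phase corrections
#'
#' Override hook replacing an operator's manual unwrap step: adds
#' `2*pi*n_wraps` to listed voxels.
#'
#' @param phase a `phase_map`.
#' @param corrections data frame with columns `direction` (1..3 or
#'   "x"/"y"/"z"), `i`, `j`, `k`, `t` (1-based voxel and frame indices) and
#'   `n_wraps` (integer, may be negative).
#' @return the corrected `phase_map`.
#' @export
apply_phase_corrections <- function(phase, corrections) {
  stopifnot(inherits(phase, "phase_map"),
            all(c("direction", "i", "j", "k", "t", "n_wraps") %in%
                  names(corrections)))
  dir_idx <- corrections$direction
  if (is.character(dir_idx)) dir_idx <- match(dir_idx, c("x", "y", "z"))
  for (r in seq_len(nrow(corrections))) {
    di <- dir_idx[r]
    phase$phi[[di]][corrections$i[r], corrections$j[r], corrections$k[r],
                    corrections$t[r]] <-
      phase$phi[[di]][corrections$i[r], corrections$j[r], corrections$k[r],
                      corrections$t[r]] + 2 * pi * corrections$n_wraps[r]
  }
  phase
}
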