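#' Synthesize phase-contrast MR signals from a ground-truth flow field
#'
#' Forward MR signal model of turbulence mapping with simple four-point
#' encoding: one flow-compensated reference segment plus three one-sided
#' velocity encodings. With `kv = pi / venc`, the encoded signal in a voxel
#' with mean velocity `v_i` and Gaussian intravoxel velocity distribution of
#' standard deviation `sigma_i` is
#' `s_enc_i = M0 * exp(-kv^2 sigma_i^2 / 2) * exp(1i * kv * v_i)`,
#' i.e. the intravoxel spread attenuates the magnitude and the mean velocity
#' sets the phase (which wraps beyond VENC). Independent zero-mean complex
#' Gaussian noise with standard deviation `M0 / snr` per real and imaginary
#' channel is added to every segment; background voxels contain noise only,
#' so magnitude statistics are Rician in the lumen and Rayleigh in the
#' background.
#'
#' @param field a `flow_field` (ground truth).
#' @return an object of class `signal_set`: `s_ref` (complex 4D array),
#'   `s_enc` (list of three complex 4D arrays, x/y/z encodings), `mask`,
#'   `config`.
#' @export
synthesize_signals <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  config <- field$config
  kv <- pi / config$venc
  mask <- field$geometry$mask
  nt <- config$n_frames
  d4 <- c(field$geometry$dim, nt)
  m0 <- array(0, d4)
  m0[rep(mask, nt)] <- 1   # tissue magnitude 1 inside the lumen, all frames

  s_ref <- m0 * (1 + 0i)
  lum <- which(m0 > 0)   # transcendentals only where tissue exists
  s_enc <- lapply(c("x", "y", "z"), function(ax) {
    att <- exp(-kv^2 * field$sigma[[ax]][lum]^2 / 2)
    phi <- kv * field$v[[ax]][lum]
    out <- array(0 + 0i, d4)
    out[lum] <- att * cos(phi) + (att * sin(phi)) * 1i
    out
  })
  names(s_enc) <- c("x", "y", "z")

  if (is.finite(config$snr)) {
    if (!is.null(config$seed)) set.seed(as.integer(config$seed))
    sd_n <- 1 / config$snr
    n <- length(s_ref)
    noise <- function() {
      array(complex(real = stats::rnorm(n, sd = sd_n),
                    imaginary = stats::rnorm(n, sd = sd_n)), d4)
    }
    s_ref <- s_ref + noise()
    s_enc <- lapply(s_enc, function(s) s + noise())
  }

  structure(list(s_ref = s_ref, s_enc = s_enc, mask = mask,
                 config = config),
            class = "signal_set")
}

#' Phase-difference maps from a signal set
#'
#' Computes, per encoding direction, the phase of the encoded segment
#' relative to the flow-compensated reference:
#' `phi_i = Arg(s_enc_i * Conj(s_ref))`, which lies in `(-pi, pi]` and is
#' therefore wrapped. Voxels with zero reference magnitude (possible only in
#' noiseless background) get `NA` and are excluded from all downstream
#' regional reductions.
#'
#' @param signals a `signal_set`.
#' @return an object of class `phase_map`: `phi` (list of three 4D arrays,
#'   rad), `wrapped = TRUE`, `mask`, `venc`.
#' @export
phase_difference <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  d4 <- dim(signals$s_ref)
  def <- which(Mod(signals$s_ref) > 0)
  arg_ref <- Arg(signals$s_ref[def])
  phi <- lapply(signals$s_enc, function(s) {
    p <- array(NA_real_, d4)
    p[def] <- wrap_phase(Arg(s[def]) - arg_ref)
    p
  })
  structure(list(phi = phi, wrapped = TRUE, mask = signals$mask,
                 venc = signals$config$venc),
            class = "phase_map")
}
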