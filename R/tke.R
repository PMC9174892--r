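#' Velocity from phase
#'
#' Linear phase-contrast scaling: `v_i = phi_i * venc / pi`, so a phase of
#' `pi` maps to the velocity-encoding value.
#'
#' @param phase a `phase_map` (normally unwrapped).
#' @param venc velocity encoding (m/s); defaults to the value carried by the
#'   phase map.
#' @return an object of class `velocity_map`: `v` (list of three 4D arrays,
#'   m/s), `venc`, `mask`.
#' @export
velocity_from_phase <- function(phase, venc = phase$venc) {
  stopifnot(inherits(phase, "phase_map"), venc > 0)
  v <- lapply(phase$phi, function(p) p * venc / pi)
  structure(list(v = v, venc = venc, mask = phase$mask),
            class = "velocity_map")
}

#' Largest IVSD resolvable above the noise floor
#'
#' Magnitude noise turns Rayleigh at low SNR and sets a floor below which
#' further turbulence-induced signal loss cannot be observed. The floor is
#' reached when the attenuated magnitude equals the noise level, i.e. when
#' `exp(-kv^2 sigma^2 / 2) = 1/snr`, giving
#' `sigma_max = sqrt(2 * log(snr)) / kv`. This caps the largest resolvable
#' turbulent kinetic energy.
#'
#' @param snr tissue-magnitude-to-noise ratio (> 1).
#' @param kv velocity-encoding sensitivity (rad per m/s), `pi / venc`.
#' @return `sigma_max` (m/s).
#' @export
noise_floor_sigma_max <- function(snr, kv) {
  stopifnot(kv > 0)
  if (!is.finite(snr)) return(Inf)
  if (snr <= 1) stop("snr must exceed 1: no resolvable IVSD range")
  sqrt(2 * log(snr)) / kv
}

#' Intravoxel velocity standard deviation from magnitude ratios
#'
#' Inverts the Gaussian signal model: with `r = |s_enc| / |s_ref|`,
#' `sigma = sqrt(2 * log(1 / r)) / kv`. Ratios at or above 1 (noise pushing
#' the encoded magnitude above the reference) clip to `sigma = 0`; ratios at
#' or below the noise floor `1/snr` saturate to `sigma_max` and are flagged.
#' Voxels with zero reference magnitude get `NA` and are excluded from
#' regional statistics downstream.
#'
#' @param mag_ref reference magnitude array.
#' @param mag_enc encoded magnitude array (same shape).
#' @param kv encoding sensitivity `pi / venc` (rad per m/s).
#' @param snr optional SNR defining the saturation floor; `NULL` or `Inf`
#'   disables saturation handling.
#' @return list with `sigma` (array, m/s) and `saturated` (logical array).
#' @export
ivsd_from_magnitudes <- function(mag_ref, mag_enc, kv, snr = NULL) {
  stopifnot(kv > 0, all(dim(mag_ref) == dim(mag_enc)))
  if (any(mag_ref < 0, na.rm = TRUE) || any(mag_enc < 0, na.rm = TRUE)) {
    stop("magnitudes must be non-negative")
  }
  d <- dim(mag_ref)
  def <- which(is.finite(mag_ref) & mag_ref > 0)
  r <- mag_enc[def] / mag_ref[def]
  saturated <- array(FALSE, d)
  sigma <- array(NA_real_, d)
  if (!is.null(snr) && is.finite(snr)) {
    s_max <- noise_floor_sigma_max(snr, kv)
    sat <- r <= 1 / snr
    saturated[def] <- sat
  } else {
    sat <- rep(FALSE, length(r))
  }
  r <- pmin(r, 1)
  s <- sqrt(-2 * log(r)) / kv
  if (any(sat)) s[sat] <- s_max
  sigma[def] <- s
  list(sigma = sigma, saturated = saturated)
}

#' Turbulent kinetic energy from the three IVSD fields
#'
#' `tke = rho/2 * (sigma_x^2 + sigma_y^2 + sigma_z^2)` per voxel, in J/m^3.
#'
#' @param sigma list of three co-registered IVSD arrays (m/s).
#' @param rho blood density (kg/m^3).
#' @return an object of class `tke_map`: `tke` (4D array, J/m^3), `sigma`,
#'   `rho`, `filtered = FALSE`.
#' @export
tke_from_ivsd <- function(sigma, rho = 1060) {
  stopifnot(length(sigma) == 3L, rho > 0)
  tke <- (rho / 2) * (sigma[[1]]^2 + sigma[[2]]^2 + sigma[[3]]^2)
  structure(list(tke = tke, sigma = sigma, rho = rho, filtered = FALSE),
            class = "tke_map")
}

#' Spatial 3x3x3 median filter of a TKE map, restricted to the mask
#'
#' Reduces the impact of noise on the peak-maximum-TKE pathway. Each frame
#' is filtered independently; the 27-voxel kernel is restricted to masked
#' voxels, so boundary voxels take the median over their masked neighbours
#' only (midpoint of the two central values for even counts). Total and
#' median TKE are computed from the unfiltered map; only the maximum-TKE
#' parameter uses the filtered one.
#'
#' @param map a `tke_map`.
#' @param mask logical 3D lumen mask.
#' @return a `tke_map` with `filtered = TRUE`.
#' @export
median_filter_tke <- function(map, mask) {
  stopifnot(inherits(map, "tke_map"), is.logical(mask),
            all(dim(mask) == dim(map$tke)[1:3]))
  d <- dim(map$tke)
  out <- map$tke
  for (k in seq_len(d[4])) {
    out[, , , k] <- median_filter3_masked(map$tke[, , , k, drop = FALSE][, , , 1],
                                          mask)
  }
  structure(list(tke = out, sigma = map$sigma, rho = map$rho,
                 filtered = TRUE),
            class = "tke_map")
}

#' High-level reconstruction: signals to velocity and TKE maps
#'
#' Runs the full turbulence-mapping inversion on a signal set:
#' phase-difference computation, optional temporal and/or Laplacian 4D
#' unwrapping (temporal first, then Laplacian), velocity scaling, IVSD from
#' magnitude ratios with noise-floor saturation, TKE, and the median-filtered
#' TKE companion map.
#'
#' @param signals a `signal_set`.
#' @param rho blood density (kg/m^3).
#' @param unwrap character vector choosing unwrap stages, any of
#'   `"temporal"`, `"laplacian"`; default both.
#' @param corrections optional manual correction table passed to
#'   [apply_phase_corrections()] after the automatic stages.
#' @return list with `velocity` (`velocity_map`), `tke` (unfiltered
#'   `tke_map`), `tke_filtered`, `sigma` (list of arrays), `saturated`
#'   (list of logical arrays), `phase` (unwrapped `phase_map`).
#' @export
reconstruct_maps <- function(signals, rho = 1060,
                             unwrap = c("temporal", "laplacian"),
                             corrections = NULL) {
  stopifnot(inherits(signals, "signal_set"))
  unwrap <- match.arg(unwrap, several.ok = TRUE)
  phase <- phase_difference(signals)
  if ("temporal" %in% unwrap) phase <- unwrap_temporal(phase)
  if ("laplacian" %in% unwrap) phase <- unwrap_laplacian4d(phase)
  if (!is.null(corrections)) phase <- apply_phase_corrections(phase, corrections)
  velocity <- velocity_from_phase(phase, signals$config$venc)

  kv <- pi / signals$config$venc
  mag_ref <- Mod(signals$s_ref)
  est <- lapply(signals$s_enc, function(s) {
    ivsd_from_magnitudes(mag_ref, Mod(s), kv, snr = signals$config$snr)
  })
  sigma <- lapply(est, `[[`, "sigma")
  saturated <- lapply(est, `[[`, "saturated")
  tke <- tke_from_ivsd(sigma, rho)
  tke_filtered <- median_filter_tke(tke, signals$mask)
  list(velocity = velocity, tke = tke, tke_filtered = tke_filtered,
       sigma = sigma, saturated = saturated, phase = phase)
}
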