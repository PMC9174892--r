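#' Acquisition configuration for the synthetic 4D flow scanner surrogate
#'
#' Bundles the acquisition parameters the simulator mimics: velocity
#' encoding, spatial and temporal resolution, signal-to-noise ratio and blood
#' density. Defaults follow a typical aortic 4D flow protocol at 3T:
#' VENC 140 cm/s, 2.8 mm isotropic voxels, 41.6 ms nominal temporal
#' resolution.
#'
#' @param venc velocity encoding (m/s); velocities beyond it alias (wrap).
#' @param voxel_mm isotropic voxel edge (mm).
#' @param dt_ms nominal temporal resolution (ms). The effective frame spacing
#'   of a simulated cycle is `60000 / (heart_rate * n_frames)` so a cardiac
#'   cycle always contains `n_frames` samples; `dt_ms` documents the protocol
#'   the defaults were chosen for (41.6 ms at 66 bpm gives about 20 frames).
#' @param n_frames timeframes per cardiac cycle.
#' @param snr ratio of tissue magnitude to the standard deviation of each
#'   real/imaginary noise channel. Use `Inf` for noiseless data.
#' @param rho blood density (kg/m^3). 1060 is the standard literature value.
#' @param seed integer seed controlling noise generation; `NULL` leaves the
#'   RNG state alone.
#' @return an object of class `acq_config`.
#' @export
acquisition_config <- function(venc = 1.4, voxel_mm = 2.8, dt_ms = 41.6,
                               n_frames = 20L, snr = 30, rho = 1060,
                               seed = NULL) {
  stopifnot(venc > 0, voxel_mm > 0, dt_ms > 0, n_frames >= 2, snr > 0,
            rho > 0)
  structure(list(venc = venc, voxel_mm = voxel_mm, dt_ms = dt_ms,
                 n_frames = as.integer(n_frames), snr = snr, rho = rho,
                 seed = seed),
            class = "acq_config")
}

#' @export
print.acq_config <- function(x, ...) {
  cat("4D flow acquisition surrogate\n")
  cat(sprintf("  VENC %.2f m/s | voxel %.1f mm | %d frames | SNR %s | rho %g kg/m^3\n",
              x$venc, x$voxel_mm, x$n_frames,
              if (is.finite(x$snr)) format(x$snr) else "Inf", x$rho))
  invisible(x)
}

#' Flow scenario: one physiological condition for one subject
#'
#' Describes the pulsatile flow and turbulence state of one simulated
#' condition (rest or dobutamine stress): heart rate, stroke volume, the
#' systolic waveform and the intravoxel velocity standard deviation (IVSD)
#' amplitude and timing. Defaults are centred on a healthy adult at rest
#' (HR 66 bpm, SV 88 ml); `stress_scenario()` builds the matching stress
#' condition.
#'
#' @param condition `"rest"` or `"stress"`.
#' @param heart_rate beats per minute.
#' @param stroke_volume_ml stroke volume (ml); the flow waveform integrates
#'   to this volume over one cycle.
#' @param sigma_peak peak IVSD amplitude (m/s) of the turbulence template.
#' @param sigma_timing fraction of the cycle at which IVSD peaks; default
#'   0.22, shortly after peak systole of the default waveform.
#' @param waveform list with `name` (only `"half_sine"` is built in) and
#'   `systolic_fraction`, the fraction of the cycle occupied by systolic
#'   outflow.
#' @param peak_mean_speed optional inlet peak mean speed (m/s). When given it
#'   is checked for consistency with `stroke_volume_ml` (2% tolerance) at
#'   field-generation time; normally it is derived from the waveform.
#' @param sigma_aniso length-3 multipliers applied to the (by default
#'   isotropic) IVSD field in x/y/z.
#' @return an object of class `flow_scenario`.
#' @export
flow_scenario <- function(condition = c("rest", "stress"),
                          heart_rate = 66, stroke_volume_ml = 88,
                          sigma_peak = 0.33, sigma_timing = 0.22,
                          waveform = list(name = "half_sine",
                                          systolic_fraction = 0.45),
                          peak_mean_speed = NULL,
                          sigma_aniso = c(1, 1, 1)) {
  condition <- match.arg(condition)
  stopifnot(heart_rate > 0, stroke_volume_ml > 0, sigma_peak >= 0,
            sigma_timing >= 0, sigma_timing < 1,
            length(sigma_aniso) == 3L, all(sigma_aniso >= 0))
  if (is.null(waveform$systolic_fraction)) waveform$systolic_fraction <- 0.45
  stopifnot(waveform$systolic_fraction > 0, waveform$systolic_fraction <= 1)
  structure(list(condition = condition, heart_rate = heart_rate,
                 stroke_volume_ml = stroke_volume_ml, sigma_peak = sigma_peak,
                 sigma_timing = sigma_timing, waveform = waveform,
                 peak_mean_speed = peak_mean_speed,
                 sigma_aniso = sigma_aniso),
            class = "flow_scenario")
}

#' Derive a dobutamine-stress scenario from a rest scenario
#'
#' Dobutamine raises heart rate (target: 60% above rest), stroke volume and
#' turbulence intensity. The IVSD amplitude is scaled by `sqrt(tke_fold)` so
#' that ground-truth peak total TKE rises by `tke_fold` (TKE is quadratic in
#' IVSD and the aortic volume is unchanged).
#'
#' @param rest a `flow_scenario` with `condition == "rest"`.
#' @param hr_factor heart-rate multiplier (default 108/66, the cohort-mean
#'   ratio of a 60%-increase protocol).
#' @param sv_factor stroke-volume multiplier (default 102/88).
#' @param tke_fold target fold increase of ground-truth peak total TKE.
#' @return a `flow_scenario` with `condition == "stress"`.
#' @export
stress_scenario <- function(rest, hr_factor = 108 / 66, sv_factor = 102 / 88,
                            tke_fold = 2.8) {
  stopifnot(inherits(rest, "flow_scenario"), rest$condition == "rest",
            hr_factor > 0, sv_factor > 0, tke_fold > 0)
  flow_scenario(condition = "stress",
                heart_rate = rest$heart_rate * hr_factor,
                stroke_volume_ml = rest$stroke_volume_ml * sv_factor,
                sigma_peak = rest$sigma_peak * sqrt(tke_fold),
                sigma_timing = rest$sigma_timing,
                waveform = rest$waveform,
                sigma_aniso = rest$sigma_aniso)
}

# Frame times (s) of one cardiac cycle for a scenario under a config.
frame_times <- function(scenario, config) {
  cycle_s <- 60 / scenario$heart_rate
  (seq_len(config$n_frames) - 1L) * cycle_s / config$n_frames
}
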