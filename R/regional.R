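#' Regional hemodynamic parameter time series
#'
#' Computes, per region (AAo, AoA, DAo and the whole TAo) and per timeframe,
#' the five hemodynamic parameters: average speed `v_avg` (mean of the
#' velocity magnitude, m/s), maximum speed `v_max` (m/s), total TKE
#' `tke_total` (volume integral of TKE over the region, mJ, from the
#' unfiltered map), maximum TKE `tke_max` (largest voxel value, J/m^3, from
#' the median-filtered map) and median TKE `tke_med` (J/m^3, unfiltered map,
#' midpoint interpolation for even voxel counts). Undefined (`NA`) voxels
#' are excluded from every reduction; an empty region yields `NA` rows.
#'
#' @param velocity a `velocity_map`.
#' @param tke_unfiltered an unfiltered `tke_map`.
#' @param tke_filtered the matching median-filtered `tke_map`.
#' @param regions an `aorta_regions`.
#' @return a data frame of class `hemo_timeseries` with columns `region`,
#'   `frame` (1-based), `v_avg`, `v_max`, `tke_total`, `tke_max`, `tke_med`.
#' @export
timeseries_parameters <- function(velocity, tke_unfiltered, tke_filtered,
                                  regions) {
  stopifnot(inherits(velocity, "velocity_map"),
            inherits(tke_unfiltered, "tke_map"),
            inherits(tke_filtered, "tke_map"),
            inherits(regions, "aorta_regions"))
  if (tke_filtered$filtered != TRUE || tke_unfiltered$filtered != FALSE) {
    stop("pass the unfiltered map as tke_unfiltered and the filtered map as tke_filtered")
  }
  d4 <- dim(tke_unfiltered$tke)
  nt <- d4[4]
  nvox <- prod(d4[1:3])
  vox_m3 <- (regions$voxel_mm / 1000)^3

  region_idx <- list(AAo = which(regions$labels == 1L),
                     AoA = which(regions$labels == 2L),
                     DAo = which(regions$labels == 3L),
                     TAo = which(!is.na(regions$labels)))

  speed2 <- velocity$v$x^2 + velocity$v$y^2 + velocity$v$z^2
  rows <- vector("list", 4L * nt)
  ri <- 0L
  for (rn in region_names()) {
    idx <- region_idx[[rn]]
    for (k in seq_len(nt)) {
      ri <- ri + 1L
      if (length(idx) == 0L) {
        rows[[ri]] <- data.frame(region = rn, frame = k, v_avg = NA_real_,
                                 v_max = NA_real_, tke_total = NA_real_,
                                 tke_max = NA_real_, tke_med = NA_real_)
        next
      }
      off <- (k - 1L) * nvox
      sp <- sqrt(speed2[off + idx])
      tu <- tke_unfiltered$tke[off + idx]
      tf <- tke_filtered$tke[off + idx]
      sp <- sp[is.finite(sp)]
      tu_f <- tu[is.finite(tu)]
      tf_f <- tf[is.finite(tf)]
      rows[[ri]] <- data.frame(
        region = rn, frame = k,
        v_avg = if (length(sp)) mean(sp) else NA_real_,
        v_max = if (length(sp)) max(sp) else NA_real_,
        tke_total = if (length(tu_f)) sum(tu_f) * vox_m3 * 1000 else NA_real_,
        tke_max = if (length(tf_f)) max(tf_f) else NA_real_,
        tke_med = median_midpoint(tu_f))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hemo_timeseries", "data.frame")
  out
}

#' Cycle peaks of the regional parameter time series
#'
#' For each region and parameter independently, the peak is the maximum over
#' timeframes; ties resolve to the earliest frame. Frames with undefined
#' values are ignored; a series with no defined frame is an error.
#'
#' @param series a `hemo_timeseries`.
#' @return a data frame of class `peak_parameters` with columns `region`,
#'   `parameter`, `peak_value`, `peak_frame`.
#' @export
peak_parameters <- function(series) {
  stopifnot(inherits(series, "hemo_timeseries"))
  params <- c("v_avg", "v_max", "tke_total", "tke_max", "tke_med")
  rows <- list()
  for (rn in unique(series$region)) {
    sub <- series[series$region == rn, ]
    sub <- sub[order(sub$frame), ]
    for (p in params) {
      vals <- sub[[p]]
      ok <- is.finite(vals)
      if (!any(ok)) stop("all frames undefined for ", rn, "/", p)
      pk <- max(vals[ok])
      fr <- sub$frame[ok][which(vals[ok] == pk)[1]]   # earliest tie
      rows[[length(rows) + 1L]] <- data.frame(region = rn, parameter = p,
                                              peak_value = pk, peak_frame = fr)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("peak_parameters", "data.frame")
  out
}

#' Ground-truth regional parameters of a flow field
#'
#' Runs the regional reduction on the generator's own velocity and IVSD
#' fields (no MR encoding, no noise), yielding the ground truth that a
#' perfect reconstruction should recover. The maximum-TKE pathway applies
#' the same 3x3x3 median filter as the reconstruction.
#'
#' @param field a `flow_field`.
#' @param regions an `aorta_regions`.
#' @param rho blood density (kg/m^3).
#' @return list with `timeseries` (`hemo_timeseries`) and `peaks`
#'   (`peak_parameters`).
#' @export
ground_truth_parameters <- function(field, regions, rho = 1060) {
  stopifnot(inherits(field, "flow_field"))
  vel <- structure(list(v = field$v, venc = field$config$venc,
                        mask = field$geometry$mask),
                   class = "velocity_map")
  tke <- tke_from_ivsd(field$sigma, rho)
  tkef <- median_filter_tke(tke, field$geometry$mask)
  ts <- timeseries_parameters(vel, tke, tkef, regions)
  list(timeseries = ts, peaks = peak_parameters(ts))
}
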