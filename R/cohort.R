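#' Default cohort sampling ranges
#'
#' Mean/SD pairs for the per-subject draws of a simulated rest + dobutamine
#' stress cohort, centred on a healthy-adult study population: rest heart
#' rate 66 +/- 9 bpm, rest stroke volume 88 +/- 13 ml, a stress heart-rate
#' factor of 108/66 (the 60%-increase dobutamine target), a stress
#' stroke-volume factor of 102/88, and a ground-truth peak-total-TKE fold
#' increase of 2.8 under stress. `sigma_peak_rest` is calibrated so the
#' default geometry's ground-truth rest peak total TKE over the whole
#' thoracic aorta is about 2.9 mJ.
#'
#' @param sigma_peak_rest mean/SD of the rest IVSD amplitude (m/s).
#' @param tke_fold mean/SD of the stress/rest fold change of ground-truth
#'   peak total TKE.
#' @return named list of `c(mean, sd)` pairs.
#' @export
cohort_ranges <- function(sigma_peak_rest = c(0.33, 0.05),
                          tke_fold = c(2.8, 0.2)) {
  list(hr_rest = c(66, 9),
       sv_rest = c(88, 13),
       hr_stress_factor = c(108 / 66, 0.06),
       sv_stress_factor = c(102 / 88, 0.10),
       sigma_peak_rest = sigma_peak_rest,
       tke_fold = tke_fold)
}

#' Simulate a paired rest/stress cohort with known ground truth
#'
#' Draws per-subject physiological parameters from the given ranges, builds
#' a rest and a dobutamine-stress `flow_scenario` per subject, and returns
#' them with a ground-truth cohort table (heart rate, stroke volume, cardiac
#' output, IVSD amplitude and, when a geometry is supplied, the analytic
#' ground-truth peak total TKE per condition). All draws are reproducible
#' from `seed`; per-subject/condition child seeds are provided for the
#' signal-synthesis stage.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed master integer seed.
#' @param ranges sampling ranges, see [cohort_ranges()]. Every entry is a
#'   `c(mean, sd)` pair; SDs of zero give a deterministic cohort.
#' @param geometry optional `aorta_geometry` used to evaluate ground-truth
#'   peak total TKE (whole thoracic aorta).
#' @param config an `acq_config` (frame timing for the ground-truth peak).
#' @return an object of class `flow_cohort`: `subjects` (list with `id`,
#'   `rest`, `stress` scenarios and `seeds`), `truth` (data frame, one row
#'   per subject and condition), `ranges`, `seed`.
#' @export
make_cohort <- function(n_subjects = 12, seed = 1, ranges = cohort_ranges(),
                        geometry = NULL, config = acquisition_config()) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  needed <- names(cohort_ranges())
  if (!all(needed %in% names(ranges))) {
    stop("ranges must contain: ", paste(needed, collapse = ", "))
  }
  for (nm in needed) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || !all(is.finite(rg)) || rg[1] <= 0 || rg[2] < 0) {
      stop("invalid range for ", nm, ": need c(mean > 0, sd >= 0)")
    }
  }

  seeds <- derive_seeds(seed, 3L * n_subjects)
  set.seed(as.integer(seed))
  draw <- function(nm, lower) {
    rg <- ranges[[nm]]
    pmax(stats::rnorm(n_subjects, rg[1], rg[2]), lower)
  }
  hr_rest <- draw("hr_rest", 30)
  sv_rest <- draw("sv_rest", 30)
  hr_fac <- draw("hr_stress_factor", 1)
  sv_fac <- draw("sv_stress_factor", 0.5)
  sig_rest <- draw("sigma_peak_rest", 0.02)
  fold <- draw("tke_fold", 1)

  template_integral <- if (!is.null(geometry)) {
    sigma_template_integral(geometry)
  } else NA_real_

  subjects <- vector("list", n_subjects)
  truth <- list()
  for (i in seq_len(n_subjects)) {
    rest <- flow_scenario("rest", heart_rate = hr_rest[i],
                          stroke_volume_ml = sv_rest[i],
                          sigma_peak = sig_rest[i])
    stress <- stress_scenario(rest, hr_factor = hr_fac[i],
                              sv_factor = sv_fac[i], tke_fold = fold[i])
    subjects[[i]] <- list(id = sprintf("S%02d", i), rest = rest,
                          stress = stress,
                          seeds = c(rest = seeds[3 * i - 2],
                                    stress = seeds[3 * i - 1]))
    for (cond in c("rest", "stress")) {
      sc <- if (cond == "rest") rest else stress
      gt_tke <- if (is.na(template_integral)) NA_real_ else {
        gt_peak_tke_total(sc, config, template_integral)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        subject = subjects[[i]]$id, condition = cond,
        hr = sc$heart_rate, sv = sc$stroke_volume_ml,
        co = derived_co(sc$heart_rate, sc$stroke_volume_ml, digits = NULL),
        sigma_peak = sc$sigma_peak,
        gt_peak_tke_total = gt_tke)
    }
  }
  structure(list(subjects = subjects, truth = do.call(rbind, truth),
                 ranges = ranges, seed = seed, config = config),
            class = "flow_cohort")
}

# Volume integral of the squared spatial IVSD template over the mask (m^3):
# ground-truth TKE_total(t) = (3*rho/2) * sigma_peak^2 * h(t)^2 * integral.
sigma_template_integral <- function(geometry, sigma_template = NULL) {
  if (is.null(sigma_template)) sigma_template <- default_sigma_template
  g <- sigma_template(geometry$voxel_s[geometry$mask])
  g <- g / max(g)
  sum(g^2) * (geometry$voxel_mm / 1000)^3
}

# Analytic ground-truth peak TKE_total (mJ) over the whole thoracic aorta
# for one scenario: peak over the discrete frame grid of the temporal bump.
gt_peak_tke_total <- function(scenario, config, template_integral,
                              rho = 1060) {
  t_s <- frame_times(scenario, config)
  cycle_s <- 60 / scenario$heart_rate
  h <- exp(-0.5 * ((t_s / cycle_s - scenario$sigma_timing) / 0.08)^2)
  aniso2 <- sum(scenario$sigma_aniso^2)
  (rho / 2) * aniso2 * scenario$sigma_peak^2 * max(h)^2 *
    template_integral * 1000
}

#' Realize one subject/condition dataset of a cohort
#'
#' Builds the ground-truth flow field and synthesizes the MR signal set for
#' one subject and condition, using that subject's child seed for the noise.
#'
#' @param cohort a `flow_cohort`.
#' @param subject subject index or id.
#' @param condition `"rest"` or `"stress"`.
#' @param geometry an `aorta_geometry`.
#' @param config an `acq_config`; its `seed` is overridden by the subject's
#'   child seed.
#' @return list with `field` (`flow_field`) and `signals` (`signal_set`).
#' @export
realize_subject <- function(cohort, subject, condition, geometry,
                            config = cohort$config) {
  stopifnot(inherits(cohort, "flow_cohort"))
  if (is.character(subject)) {
    subject <- match(subject, vapply(cohort$subjects, `[[`, "", "id"))
  }
  sub <- cohort$subjects[[subject]]
  condition <- match.arg(condition, c("rest", "stress"))
  config$seed <- unname(sub$seeds[condition])
  field <- make_flow_field(geometry, sub[[condition]], config)
  list(field = field, signals = synthesize_signals(field))
}
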