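# Hand-built maps on the real geometry let every reduction be checked
# against closed-form values.

mk_tke_map <- function(arr, filtered = FALSE) {
  structure(list(tke = arr, sigma = NULL, rho = 1060, filtered = filtered),
            class = "tke_map")
}

mk_velocity_map <- function(v_list, venc = 1.4, mask) {
  structure(list(v = v_list, venc = venc, mask = mask),
            class = "velocity_map")
}

test_that("regional reductions match closed forms on constant fields", {
  g <- fx_geometry()
  r <- fx_regions()
  nt <- 3L
  d4 <- c(g$dim, nt)
  m4 <- rep(g$mask, nt)
  tke <- array(0, d4); tke[m4] <- 100
  z <- array(0, d4); z[m4] <- 0.5
  vel <- mk_velocity_map(list(x = array(0, d4), y = array(0, d4), z = z),
                         mask = g$mask)
  ts <- timeseries_parameters(vel, mk_tke_map(tke),
                              mk_tke_map(tke, filtered = TRUE), r)
  for (rn in c("AAo", "AoA", "DAo", "TAo")) {
    sub <- ts[ts$region == rn, ]
    # uniform TKE: total = value * volume (100 J/m^3 over V ml -> 0.1*V mJ)
    expect_equal(sub$tke_total, rep(100 * r$volumes_ml[[rn]] * 1e-3, nt),
                 tolerance = 1e-12)
    expect_equal(sub$tke_max, rep(100, nt))
    expect_equal(sub$tke_med, rep(100, nt))
    expect_equal(sub$v_avg, rep(0.5, nt))
    expect_equal(sub$v_max, rep(0.5, nt))
  }
  expect_error(timeseries_parameters(vel, mk_tke_map(tke), mk_tke_map(tke), r),
               "filtered")
})

test_that("singleton regions and even-count medians", {
  d3 <- c(4, 4, 4)
  labels <- array(NA_integer_, d3)
  labels[1, 1, 1] <- 1L                   # AAo: one voxel
  labels[2, 1:4, 1] <- 3L                 # DAo: four voxels
  regions <- structure(list(labels = labels,
                            volumes_ml = c(AAo = 1, AoA = 0, DAo = 4,
                                           TAo = 5) * 2.8^3 / 1000,
                            cuts = c(s1 = 0.3, s2 = 0.5), voxel_mm = 2.8),
                       class = "aorta_regions")
  d4 <- c(d3, 1L)
  tke <- array(0, d4)
  tke[1, 1, 1, 1] <- 55
  tke[2, 1:4, 1, 1] <- c(0, 0, 0, 100)    # even count, >2 zeros -> median 0
  v <- array(0, d4); v[1, 1, 1, 1] <- 0.3; v[2, 1:4, 1, 1] <- 1:4 / 10
  vel <- mk_velocity_map(list(x = v, y = array(0, d4), z = array(0, d4)),
                         mask = !is.na(labels))
  ts <- timeseries_parameters(vel, mk_tke_map(tke),
                              mk_tke_map(tke, filtered = TRUE), regions)
  aao <- ts[ts$region == "AAo", ]
  expect_equal(aao$v_avg, aao$v_max)      # singleton reductions agree
  expect_equal(aao$tke_med, aao$tke_max)
  dao <- ts[ts$region == "DAo", ]
  expect_equal(dao$tke_med, 0)
  # two central values 0 and 100 -> midpoint 50
  tke[2, 1:4, 1, 1] <- c(0, 0, 100, 100)
  ts2 <- timeseries_parameters(vel, mk_tke_map(tke),
                               mk_tke_map(tke, filtered = TRUE), regions)
  expect_equal(ts2$tke_med[ts2$region == "DAo"], 50)
  # empty region (AoA) yields undefined markers
  expect_true(is.na(ts$tke_total[ts$region == "AoA"]))
})

test_that("peak identification: maxima with earliest-frame tie-breaking", {
  df <- data.frame(region = "TAo", frame = 1:4,
                   v_avg = c(1, 3, 3, 2), v_max = c(1, 2, 3, 4),
                   tke_total = c(4, 3, 2, 1), tke_max = c(1, 3, 3, 2),
                   tke_med = c(NA, 1, 5, 2))
  class(df) <- c("hemo_timeseries", "data.frame")
  pk <- peak_parameters(df)
  get <- function(p) pk[pk$parameter == p, ]
  expect_equal(get("v_avg")$peak_value, 3)
  expect_equal(get("v_avg")$peak_frame, 2)      # tie -> earliest
  expect_equal(get("v_max")$peak_frame, 4)      # monotone -> last frame
  expect_equal(get("tke_total")$peak_frame, 1)
  expect_equal(get("tke_med")$peak_value, 5)    # NA frames ignored
  df$v_avg <- NA_real_
  expect_error(peak_parameters(df), "undefined")
})

test_that("additivity and super-additivity of regional TKE_total", {
  g <- fx_geometry()
  r <- fx_regions()
  cfg <- acquisition_config(snr = 30, seed = 5)
  ff <- make_flow_field(g, flow_scenario("rest"), cfg)
  maps <- reconstruct_maps(synthesize_signals(ff))
  ts <- timeseries_parameters(maps$velocity, maps$tke, maps$tke_filtered, r)
  wide <- split(ts, ts$region)
  tot <- wide$AAo$tke_total + wide$AoA$tke_total + wide$DAo$tke_total
  expect_equal(wide$TAo$tke_total, tot, tolerance = 1e-12)   # framewise, exact
  pk <- peak_parameters(ts)
  ptot <- pk[pk$parameter == "tke_total", ]
  expect_lte(ptot$peak_value[ptot$region == "TAo"],
             sum(ptot$peak_value[ptot$region != "TAo"]) + 1e-12)
  # enlarging a region cannot reduce its maxima (unfiltered pathway)
  r_wide <- divide_regions(g, 0.30, 0.60)
  ts_w <- timeseries_parameters(maps$velocity, maps$tke, maps$tke_filtered,
                                r_wide)
  expect_true(all(ts_w$v_max[ts_w$region == "AoA"] >=
                    ts$v_max[ts$region == "AoA"] - 1e-12))
})

test_that("noiseless reconstruction recovers the generator's ground-truth peaks", {
  ff <- fx_rest_field()
  r <- fx_regions()
  maps <- reconstruct_maps(synthesize_signals(ff), unwrap = "temporal")
  ts <- timeseries_parameters(maps$velocity, maps$tke, maps$tke_filtered, r)
  pk <- peak_parameters(ts)
  gt <- ground_truth_parameters(ff, r)$peaks
  for (p in unique(pk$parameter)) {
    rec <- pk$peak_value[pk$region == "TAo" & pk$parameter == p]
    tru <- gt$peak_value[gt$region == "TAo" & gt$parameter == p]
    expect_equal(rec, tru, tolerance = 1e-8)
  }
})
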