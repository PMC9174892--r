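kv14 <- pi / 1.4

test_that("IVSD inversion of the magnitude-ratio signal model", {
  # inverse of the forward example: ratio exp(-kv^2*0.3^2/2) -> sigma 0.300
  r <- exp(-kv14^2 * 0.3^2 / 2)
  est <- ivsd_from_magnitudes(array(1, c(1, 1, 1, 1)),
                              array(r, c(1, 1, 1, 1)), kv14)
  expect_equal(est$sigma[1], 0.300, tolerance = 1e-12)
  # clipping rules
  one <- array(1, c(1, 1, 1, 1))
  expect_identical(ivsd_from_magnitudes(one, one, kv14)$sigma[1], 0)
  expect_identical(
    ivsd_from_magnitudes(one, array(1.05, dim(one)), kv14)$sigma[1], 0)
  # zero reference magnitude: undefined marker
  expect_true(is.na(ivsd_from_magnitudes(array(0, dim(one)), one,
                                         kv14)$sigma[1]))
  expect_error(ivsd_from_magnitudes(one, array(-1, dim(one)), kv14),
               "non-negative")
})

test_that("noise floor: resolvable IVSD range from SNR", {
  expect_equal(noise_floor_sigma_max(30, kv14), sqrt(2 * log(30)) / kv14)
  expect_equal(noise_floor_sigma_max(30, kv14), 1.162, tolerance = 1e-3)
  expect_error(noise_floor_sigma_max(1, kv14), "snr")
  expect_lt(noise_floor_sigma_max(1 + 1e-9, kv14), 1e-4)    # limit to zero
  snrs <- c(2, 5, 10, 30, 100)
  expect_true(all(diff(vapply(snrs, noise_floor_sigma_max,
                              numeric(1), kv = kv14)) > 0))
  # saturation: ratios at/below 1/snr are set to sigma_max and flagged
  est <- ivsd_from_magnitudes(array(1, c(2, 1, 1, 1)),
                              array(c(1 / 40, 0.9), c(2, 1, 1, 1)),
                              kv14, snr = 30)
  expect_true(est$saturated[1] && !est$saturated[2])
  expect_equal(est$sigma[1], noise_floor_sigma_max(30, kv14))
})

test_that("velocity scaling and TKE arithmetic", {
  p <- phase_map_of(array(c(pi / 2, 0, pi), c(3, 1, 1, 1)), venc = 1.4)
  p$wrapped <- FALSE
  expect_equal(as.vector(velocity_from_phase(p)$v$x), c(0.7, 0, 1.4))

  s <- lapply(1:3, function(i) array(0.2, c(2, 2, 2, 1)))
  tk <- tke_from_ivsd(s, rho = 1060)
  expect_equal(tk$tke[1], 63.6, tolerance = 1e-12)
  expect_identical(tke_from_ivsd(lapply(1:3, function(i)
    array(0, c(1, 1, 1, 1))))$tke[1], 0)
  # quadratic in sigma, linear in rho
  tk2 <- tke_from_ivsd(lapply(s, function(a) 2 * a), rho = 1060)
  expect_equal(tk2$tke, 4 * tk$tke)
  tk3 <- tke_from_ivsd(s, rho = 2120)
  expect_equal(tk3$tke, 2 * tk$tke)
})

test_that("masked 3x3x3 median filter", {
  d <- c(5, 5, 5, 1)
  mask <- array(TRUE, d[1:3])
  mk_map <- function(arr) structure(list(tke = arr, sigma = NULL, rho = 1060,
                                         filtered = FALSE), class = "tke_map")
  # constant field unchanged
  cst <- mk_map(array(7, d))
  expect_equal(median_filter_tke(cst, mask)$tke, array(7, d))
  # isolated spike removed
  sp <- array(0, d); sp[3, 3, 3, 1] <- 1000
  expect_identical(median_filter_tke(mk_map(sp), mask)$tke[3, 3, 3, 1], 0)
  # boundary voxel with 9 masked neighbours: median over those 9 only
  mask2 <- array(FALSE, d[1:3]); mask2[1:3, 1:3, 1] <- TRUE
  vals <- array(0, d); vals[1:3, 1:3, 1, 1] <- matrix(1:9, 3, 3)
  out <- median_filter_tke(mk_map(vals), mask2)$tke
  expect_equal(out[1, 1, 1, 1], stats::median(c(1, 2, 4, 5)))  # corner kernel
  expect_equal(out[2, 2, 1, 1], stats::median(1:9))   # all 9 in kernel
  # property: filtering never raises the masked maximum
  set.seed(42)
  for (i in 1:5) {
    arr <- array(stats::rexp(prod(d)), d)
    m <- array(stats::runif(prod(d[1:3])) < 0.7, d[1:3])
    if (!any(m)) next
    out <- median_filter_tke(mk_map(arr), m)$tke
    expect_lte(max(out[, , , 1][m]), max(arr[, , , 1][m]))
  }
})

test_that("Monte-Carlo IVSD estimator: low bias mid-range, saturation at the floor", {
  set.seed(7)
  snr <- 30
  s_max <- noise_floor_sigma_max(snr, kv14)
  n <- 10000
  sig_frac <- c(0.1, 0.2, 0.35, 0.5, 0.65, 0.8, 0.95, 1.1, 1.25)
  est_mean <- vapply(sig_frac, function(fr) {
    s_true <- fr * s_max
    att <- exp(-kv14^2 * s_true^2 / 2)
    ref <- complex(real = 1 + stats::rnorm(n, sd = 1 / snr),
                   imaginary = stats::rnorm(n, sd = 1 / snr))
    enc <- complex(real = att + stats::rnorm(n, sd = 1 / snr),
                   imaginary = stats::rnorm(n, sd = 1 / snr))
    est <- ivsd_from_magnitudes(array(Mod(ref), c(n, 1, 1, 1)),
                                array(Mod(enc), c(n, 1, 1, 1)),
                                kv14, snr = snr)
    mean(est$sigma)
  }, numeric(1))
  mid <- sig_frac >= 0.2 & sig_frac <= 0.8
  bias <- est_mean[mid] / (sig_frac[mid] * s_max) - 1
  expect_lt(max(abs(bias)), 0.05)
  # monotone saturation: means keep increasing but stay capped near sigma_max
  expect_true(all(diff(est_mean) > 0) || all(diff(est_mean) >= -1e-3))
  high <- sig_frac >= 1
  expect_true(all(est_mean[high] < sig_frac[high] * s_max))
  expect_true(all(est_mean[high] < 1.05 * s_max))
})
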