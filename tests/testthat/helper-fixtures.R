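# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_geometry <- function() {
  if (is.null(.fx$geometry)) .fx$geometry <- aorta_geometry()
  .fx$geometry
}

fx_regions <- function() {
  if (is.null(.fx$regions)) .fx$regions <- divide_regions(fx_geometry())
  .fx$regions
}

fx_config_noiseless <- function() acquisition_config(snr = Inf)

fx_rest_field <- function() {
  if (is.null(.fx$rest_field)) {
    .fx$rest_field <- make_flow_field(fx_geometry(), flow_scenario("rest"),
                                      fx_config_noiseless())
  }
  .fx$rest_field
}

fx_stress_field <- function() {
  if (is.null(.fx$stress_field)) {
    .fx$stress_field <- make_flow_field(fx_geometry(),
                                        stress_scenario(flow_scenario("rest")),
                                        fx_config_noiseless())
  }
  .fx$stress_field
}

# Smooth full-grid phase phantom: time-modulated Gaussian blob whose centre
# exceeds pi (wraps) but whose per-voxel and per-frame increments stay
# below pi, so unwrapping is well posed.
blob_phantom <- function(n = 32, nt = 12, amp = 2.4 * pi, width2 = 90) {
  co <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  r2 <- (co$x - n / 2)^2 + (co$y - n / 2)^2 + (co$z - n / 2)^2
  spatial <- array(exp(-r2 / width2), c(n, n, n))
  truth <- array(0, c(n, n, n, nt))
  for (t in seq_len(nt)) truth[, , , t] <- amp * sin(pi * t / nt) * spatial
  truth
}

phase_map_of <- function(phi4, mask = NULL, wrapped = TRUE, venc = 1.4) {
  if (is.null(mask)) mask <- array(TRUE, dim(phi4)[1:3])
  structure(list(phi = list(x = phi4), wrapped = wrapped, mask = mask,
                 venc = venc),
            class = "phase_map")
}

# A full-grid flow field whose blob core stays above VENC at every frame:
# the temporal anchor itself is aliased there, which is the failure mode the
# Laplacian cleanup stage exists for.
supravenc_field <- function(n = 24, nt = 10, venc = 1.4) {
  co <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  r2 <- (co$x - n / 2)^2 + (co$y - n / 2)^2 + (co$z - n / 2)^2
  spatial <- array(exp(-r2 / 60), c(n, n, n))
  d4 <- c(n, n, n, nt)
  v <- array(0, d4)
  for (t in seq_len(nt)) {
    v[, , , t] <- (1.6 + 0.5 * sin(2 * pi * t / nt)) * venc * spatial
  }
  zero <- array(0, d4)
  geometry <- list(mask = array(TRUE, c(n, n, n)), dim = c(n, n, n),
                   voxel_mm = 2.8)
  config <- acquisition_config(venc = venc, n_frames = nt, snr = Inf)
  structure(list(v = list(x = v, y = zero, z = zero),
                 sigma = list(x = zero, y = zero, z = zero),
                 geometry = geometry, config = config),
            class = "flow_field")
}

expect_congruent <- function(out, wrapped_in, tol = 1e-8) {
  k <- (out - wrapped_in) / (2 * pi)
  expect_lt(max(abs(k - round(k)), na.rm = TRUE), tol)
}
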