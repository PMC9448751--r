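# Shared fixtures, built lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fx_fluid <- function() fluid_properties()
fx_vessel <- function() vessel_model()

fx_decomp <- function() {
  if (is.null(.fx$decomp))
    .fx$decomp <- decompose_waveform(make_waveform(), n_harmonics = 8L)
  .fx$decomp
}

fx_field <- function() {
  if (is.null(.fx$field))
    .fx$field <- womersley_field(fx_decomp(), fx_vessel(), fx_fluid())
  .fx$field
}

# default-waveform acquisition at a given voxel size (noise-free, zero offset)
fx_vox <- function(res_mm, dt_ms = 35) {
  key <- sprintf("vox_%g_%g", res_mm, dt_ms)
  if (is.null(.fx[[key]])) {
    st <- acquisition_settings(voxel_size_mm = res_mm, dt_ms = dt_ms)
    .fx[[key]] <- acquire(fx_field(), fx_vessel(), st, fx_decomp()$period)
  }
  .fx[[key]]
}

# steady Poiseuille-only decomposition with unit centerline velocity
fx_poiseuille_decomp <- function(vessel = fx_vessel()) {
  q0 <- pi * vessel$radius^2 / 2           # 2*Q0/(pi R^2) = 1 m/s
  w <- flow_waveform((0:31) / 32 * 0.9, rep(q0, 32), 0.9)
  decompose_waveform(w, n_harmonics = 1L)
}

# steady Poiseuille field sampler (unit centerline velocity)
fx_poiseuille_field <- function(vessel = fx_vessel()) {
  womersley_field(fx_poiseuille_decomp(vessel), vessel, fx_fluid())
}

# fine-voxel steady Poiseuille acquisition (single frame), cached
fx_fine_poiseuille_vox <- function() {
  if (is.null(.fx$fine_pois)) {
    v <- fx_vessel()
    st <- acquisition_settings(voxel_size_mm = 0.5, dt_ms = 34)
    short <- vessel_model(radius = v$radius, length = 0.006)
    .fx$fine_pois <- acquire(fx_poiseuille_field(short), short, st,
                             period = 0.035)
  }
  .fx$fine_pois
}

# brute-force Wilcoxon signed-rank oracle: literal enumeration over all 2^n
# sign assignments; two-sided p = P(|W* - mu| >= |W - mu|)
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  hits <- 0
  for (m in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    Ws <- sum(r[signs])
    if (abs(Ws - mu) >= abs(W - mu) - 1e-9) hits <- hits + 1
  }
  list(statistic = W, p_value = hits / 2^n)
}
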