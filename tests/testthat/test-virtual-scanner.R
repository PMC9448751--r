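# Virtual scanner: partial-volume voxelization, noise model, I/O.

test_that("acquisition settings validate their invariants", {
  expect_error(acquisition_settings(0), "voxel_size")
  expect_error(acquisition_settings(4, dt_ms = 0), "dt_ms")
  expect_error(acquisition_settings(4, venc_cms = -1), "venc")
  expect_error(acquisition_settings(4, subsamples = 1), "subsamples")
  expect_error(acquisition_settings(4, grid_offset = c(0, 0, 1)), "grid_offset")
})

test_that("voxel values follow the partial-volume averaging rules", {
  vessel <- vessel_model(radius = 0.0125, length = 0.02)
  uniform <- function(x, y, z, t) cbind(0 * x, rep(1, length(x)), 0 * x)
  st <- acquisition_settings(voxel_size_mm = 4, dt_ms = 35)
  vox <- acquire(uniform, vessel, st, period = 0.035)

  # fully interior voxel: exact velocity, magnitude 1
  ctr <- which(vox$magnitude == 1, arr.ind = TRUE)
  expect_gt(nrow(ctr), 0)
  i <- ctr[1, ]
  expect_equal(unname(vox$velocity[i[1], i[2], i[3], , 1]), c(0, 1, 0))

  # fully exterior voxel: magnitude 0, velocity 0
  out <- which(vox$magnitude == 0, arr.ind = TRUE)
  j <- out[1, ]
  expect_equal(unname(vox$velocity[j[1], j[2], j[3], , 1]), c(0, 0, 0))

  # magnitudes are partial-volume fractions in [0, 1]
  expect_true(all(vox$magnitude >= 0 & vox$magnitude <= 1))
  expect_true(all(is.finite(vox$velocity)))
  # frame times span one period, strictly increasing
  expect_true(all(diff(vox$frame_times) > 0))
  expect_equal(vox$dims[4], 1)
})

test_that("a voxel bisected by a planar lumen boundary has magnitude 0.5", {
  # tube end plane (|y| <= L/2) is planar; shift the grid so a voxel layer
  # is centered exactly on it
  vessel <- vessel_model(radius = 0.0125, length = 0.02)
  uniform <- function(x, y, z, t) cbind(0 * x, rep(1, length(x)), 0 * x)
  st <- acquisition_settings(voxel_size_mm = 4, dt_ms = 35,
                             grid_offset = c(0, 0.5, 0))
  vox <- acquire(uniform, vessel, st, period = 0.035)
  yc <- vox$origin[2] + (seq_len(vox$dims[2]) - 0.5) * vox$voxel_size
  jend <- which(abs(yc - 0.01) < 1e-9)
  expect_length(jend, 1)
  # radially central voxel in that layer
  xc <- vox$origin[1] + (seq_len(vox$dims[1]) - 0.5) * vox$voxel_size
  zc <- vox$origin[3] + (seq_len(vox$dims[3]) - 0.5) * vox$voxel_size
  i <- which.min(abs(xc)); k <- which.min(abs(zc))
  expect_equal(vox$magnitude[i, jend, k], 0.5)
  # diluted velocity is half the lumen value; the lumen-mean convention
  # recovers the full value
  expect_equal(vox$velocity[i, jend, k, 2, 1], 0.5)
  vox_lm <- acquire(uniform, vessel, st, period = 0.035,
                    partial_volume = "lumen_mean")
  expect_equal(vox_lm$velocity[i, jend, k, 2, 1], 1)
})

test_that("on a linear field an interior voxel equals the field at its centroid", {
  vessel <- vessel_model(radius = 0.0125, length = 0.02)
  lin <- function(x, y, z, t)
    cbind(0 * x, 0.2 + 3 * x + 5 * y - 2 * z, 0 * x)
  st <- acquisition_settings(voxel_size_mm = 2, dt_ms = 35)
  vox <- acquire(lin, vessel, st, period = 0.035)
  ctr <- which(vox$magnitude == 1, arr.ind = TRUE)
  h <- vox$voxel_size
  for (rIdx in seq_len(min(nrow(ctr), 20))) {
    i <- unname(ctr[rIdx, ])
    cx <- vox$origin[1] + (i[1] - 0.5) * h
    cy <- vox$origin[2] + (i[2] - 0.5) * h
    cz <- vox$origin[3] + (i[3] - 0.5) * h
    expect_equal(vox$velocity[i[1], i[2], i[3], 2, 1],
                 0.2 + 3 * cx + 5 * cy - 2 * cz, tolerance = 1e-10)
  }
})

test_that("coarse voxel speeds never exceed the analytic maximum", {
  vox <- fx_vox(4)
  d <- fx_decomp(); v <- fx_vessel(); fl <- fx_fluid()
  pk <- which.max(reconstruct_flow(d, vox$frame_times))
  sp <- sqrt(vox$velocity[, , , 1, pk]^2 + vox$velocity[, , , 2, pk]^2 +
               vox$velocity[, , , 3, pk]^2)
  rg <- seq(0, v$radius, length.out = 1000)
  u_max <- max(abs(velocity_profile(d, v, fl, rg, vox$frame_times[pk])))
  expect_lte(max(sp), u_max)
})

test_that("the noise model has the venc/SNR scale and is seed-reproducible", {
  expect_equal(noise_sigma(150, 30), sqrt(2) * 1.5 / (pi * 30))
  expect_equal(noise_sigma(150, 30), 0.02251, tolerance = 1e-4)

  vessel <- vessel_model(radius = 0.0125, length = 0.02)
  uniform <- function(x, y, z, t) cbind(0 * x, rep(1, length(x)), 0 * x)
  st_free <- acquisition_settings(4, dt_ms = 35)
  vox <- acquire(uniform, vessel, st_free, period = 0.12)

  # noise-free sentinel: unchanged
  expect_identical(add_noise(vox), vox)

  st <- acquisition_settings(4, dt_ms = 35, snr = 30, seed = 123)
  n1 <- add_noise(vox, st)
  n2 <- add_noise(vox, st)
  expect_identical(n1$velocity, n2$velocity)

  # air voxels stay exactly zero; lumen voxels get zero-mean noise at sigma
  air <- vox$magnitude == 0
  for (f in seq_len(n1$dims[4]))
    expect_true(all(n1$velocity[, , , 1, f][air] == 0))
  lum <- vox$magnitude > 0
  resid <- c(n1$velocity[, , , 1, ][lum], n1$velocity[, , , 3, ][lum])
  expect_equal(sd(resid), noise_sigma(150, 30), tolerance = 0.1)
  expect_lt(abs(mean(resid)), 3 * noise_sigma(150, 30) / sqrt(length(resid)))

  expect_error(add_noise(vox, acquisition_settings(4, snr = 30)), "seed")
})

test_that("aliasing wraps velocities beyond the encoding limit", {
  vessel <- vessel_model(radius = 0.0125, length = 0.02)
  fast <- function(x, y, z, t) cbind(0 * x, rep(1.8, length(x)), 0 * x)
  st <- acquisition_settings(4, dt_ms = 35, venc_cms = 150)
  vox <- acquire(fast, vessel, st, period = 0.035)
  wrapped <- wrap_aliasing(vox)
  ctr <- which(vox$magnitude == 1)
  v_in <- array(vox$velocity[, , , 2, 1], dim = vox$dims[1:3])[ctr]
  v_out <- array(wrapped$velocity[, , , 2, 1], dim = vox$dims[1:3])[ctr]
  expect_equal(unique(round(v_in, 10)), 1.8)
  expect_equal(unique(round(v_out, 10)), 1.8 - 3)  # 1.8 wraps to -1.2
  # below venc nothing changes
  vox15 <- fx_vox(4)
  expect_equal(wrap_aliasing(vox15)$velocity, vox15$velocity)
})

test_that("voxel data round-trips through NIfTI plus metadata sidecar", {
  vox <- fx_vox(4)
  dir <- withr::local_tempdir()
  write_voxel4dflow(vox, dir)
  expect_true(all(file.exists(file.path(
    dir, c("vx.nii.gz", "vy.nii.gz", "vz.nii.gz", "mag.nii.gz", "meta.json")))))
  back <- read_voxel4dflow(dir)
  expect_equal(back$dims, vox$dims)
  expect_equal(back$voxel_size, vox$voxel_size, tolerance = 1e-9)
  expect_equal(back$origin, vox$origin, tolerance = 1e-12)
  expect_equal(back$frame_times, vox$frame_times, tolerance = 1e-12)
  expect_equal(back$velocity, vox$velocity, tolerance = 1e-12)
  expect_equal(back$magnitude, vox$magnitude, tolerance = 1e-12)
})

test_that("max-speed error shrinks monotonically with voxel size on steady flow", {
  # steady Poiseuille, 20 seeded random grid offsets per resolution
  short <- vessel_model(radius = 0.0125, length = 0.008)
  field <- fx_poiseuille_field(short)
  set.seed(314)
  offsets <- replicate(20, runif(3), simplify = FALSE)
  err <- sapply(c(4, 3, 2, 1.5), function(res) {
    e <- sapply(offsets, function(off) {
      st <- acquisition_settings(res, dt_ms = 35, grid_offset = off)
      vox <- acquire(field, short, st, period = 0.035)
      1 - max(vox$velocity[, , , 2, 1])   # analytic max is 1 m/s
    })
    mean(e)
  })
  expect_true(all(err > 0))          # voxel means cannot exceed the field max
  expect_true(all(diff(err) < 0))    # 4 -> 3 -> 2 -> 1.5 mm error decreases
})
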