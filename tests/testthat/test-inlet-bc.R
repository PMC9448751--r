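# Inlet-plane extraction, surface fitting and flow-rate integration.

# hand-built inlet sample set on a disk of lumen voxel centers
make_samples <- function(h = 2e-3, R = 0.0125, n_frames = 4,
                         value_fun = function(x, z, f) rep(1, length(x))) {
  g <- seq(-R, R, by = h)
  pts <- expand.grid(x = g, z = g)
  pts <- pts[pts$x^2 + pts$z^2 <= (R - h / 2)^2, ]
  v <- sapply(seq_len(n_frames), function(f) value_fun(pts$x, pts$z, f))
  structure(
    list(x = pts$x, z = pts$z, v = v,
         frame_times = (seq_len(n_frames) - 0.5) * 0.035,
         period = n_frames * 0.035, voxel_size = h,
         center = c(0, 0), radius = R),
    class = "inlet_samples"
  )
}

test_that("extraction yields one record per lumen slice voxel per frame", {
  vox <- fx_vox(4)
  mask <- segment(vox, 0.5)
  pl <- plane_spec(-fx_vessel()$length / 4, "inlet")
  s <- extract_inlet_samples(vox, mask, pl)
  j <- floor((pl$axis_coordinate - vox$origin[2]) / vox$voxel_size) + 1
  n_expected <- sum(mask$mask[, j, ])
  expect_equal(length(s$x), n_expected)
  expect_equal(dim(s$v), c(n_expected, vox$dims[4]))
  # all sample points lie inside the stored lumen domain
  expect_true(all((s$x - s$center[1])^2 + (s$z - s$center[2])^2 <=
                    s$radius^2))
})

test_that("a uniform axial field is sampled as exactly 1 on interior voxels", {
  vessel <- vessel_model(radius = 0.0125, length = 0.02)
  uniform <- function(x, y, z, t) cbind(0 * x, rep(1, length(x)), 0 * x)
  st <- acquisition_settings(2, dt_ms = 35)
  vox <- acquire(uniform, vessel, st, period = 0.105)
  # interior-only mask: every sampled velocity is exactly 1
  s <- extract_inlet_samples(vox, segment(vox, 0.999), plane_spec(0, "inlet"))
  expect_true(all(s$v == 1))
  # under the lumen-mean convention rim voxels also read 1
  vox_lm <- acquire(uniform, vessel, st, period = 0.105,
                    partial_volume = "lumen_mean")
  s_lm <- extract_inlet_samples(vox_lm, segment(vox_lm, 0.5),
                                plane_spec(0, "inlet"))
  expect_true(all(abs(s_lm$v - 1) < 1e-12))
})

test_that("sampled Poiseuille voxels equal their subsample-rule averages", {
  vessel <- vessel_model(radius = 0.0125, length = 0.02)
  field <- fx_poiseuille_field(vessel)
  st <- acquisition_settings(2, dt_ms = 35)
  vox <- acquire(field, vessel, st, period = 0.035)
  mask <- segment(vox, 0.999)
  pl <- plane_spec(0, "inlet")
  s <- extract_inlet_samples(vox, mask, pl)
  h <- vox$voxel_size
  # independent midpoint-subsample oracle over the same 4^3 rule
  g <- ((1:4) - 0.5) / 4 * h - h / 2
  yc <- vox$origin[2] + (floor((0 - vox$origin[2]) / h) + 0.5) * h
  for (i in seq_len(min(10, length(s$x)))) {
    pts <- expand.grid(x = s$x[i] + g, y = yc + g, z = s$z[i] + g)
    r <- sqrt(pts$x^2 + pts$z^2)
    u <- ifelse(r <= vessel$radius & abs(pts$y) <= vessel$length / 2,
                1 - (r / vessel$radius)^2, 0)
    expect_equal(s$v[i, 1], mean(u), tolerance = 1e-6)
  }
})

test_that("polynomial surfaces are fitted exactly and least-squares optimally", {
  R <- 0.0125
  # samples from u = 1 - (x^2 + z^2)/R^2, degree 2: exact reproduction
  s <- make_samples(value_fun = function(x, z, f) 1 - (x^2 + z^2) / R^2)
  fit <- fit_inlet_surface(s, degree = 2)
  pred <- evaluate_fit(fit, s$x, s$z, s$frame_times[2])
  expect_equal(pred, s$v[, 2], tolerance = 1e-10)

  # constant samples give a constant fit for any degree
  sc <- make_samples(value_fun = function(x, z, f) rep(0.37, length(x)))
  fitc <- fit_inlet_surface(sc, degree = 3)
  expect_equal(evaluate_fit(fitc, c(0, 0.004), c(0, -0.003), 0.05),
               c(0.37, 0.37), tolerance = 1e-10)

  # least-squares optimality: coefficients match a normal-equations oracle
  set.seed(99)
  sr <- make_samples(value_fun = function(x, z, f)
    1 - (x^2 + z^2) / R^2 + 0.05 * rnorm(length(x)))
  fit4 <- fit_inlet_surface(sr, degree = 4)
  xs <- sr$x / sr$radius; zs <- sr$z / sr$radius
  ex <- fit4$exponents
  X <- outer(xs, ex$a, `^`) * outer(zs, ex$b, `^`)
  beta <- solve(crossprod(X), crossprod(X, sr$v[, 1]))
  expect_equal(unname(fit4$coef[, 1]), drop(beta), tolerance = 1e-8)

  # underdetermined frame: 5 points cannot support 15 terms
  tiny <- make_samples(h = 9e-3)
  expect_lt(length(tiny$x), 15)
  expect_error(fit_inlet_surface(tiny, degree = 4), "insufficient")
})

test_that("fit evaluation interpolates in time and clamps outside the lumen", {
  # frame values 0.2 and 0.4 everywhere -> 0.3 midway
  s <- make_samples(n_frames = 2,
                    value_fun = function(x, z, f) rep(0.2 * f, length(x)))
  fit <- fit_inlet_surface(s, degree = 1)
  t_mid <- mean(s$frame_times)
  expect_equal(evaluate_fit(fit, 0, 0, t_mid), 0.3, tolerance = 1e-10)
  expect_equal(evaluate_fit(fit, 0, 0, s$frame_times[1]), 0.2,
               tolerance = 1e-10)
  # outside the lumen radius: hard zero
  expect_identical(evaluate_fit(fit, s$radius * 1.5, 0, t_mid), 0)
})

test_that("flow rate integrates voxel velocities over the slice", {
  # uniform 1 m/s over 25 voxels at 2 mm -> 1e-4 m^3/s
  arr25 <- expand.grid(x = (-2:2) * 2e-3, z = (-2:2) * 2e-3)
  s25 <- structure(
    list(x = arr25$x, z = arr25$z, v = matrix(1, 25, 2),
         frame_times = c(0.0175, 0.0525), period = 0.07, voxel_size = 2e-3,
         center = c(0, 0), radius = 6e-3),
    class = "inlet_samples")
  expect_equal(flow_rate(s25), c(1e-4, 1e-4))
  # an all-zero frame integrates to zero
  s25$v[, 2] <- 0
  expect_equal(flow_rate(s25)[2], 0)

  # fine-voxel Poiseuille: within 2% of (1/2) Umax pi R^2
  vessel <- vessel_model(radius = 0.0125, length = 0.006)
  st <- acquisition_settings(0.5, dt_ms = 35)
  vox <- acquire(fx_poiseuille_field(vessel), vessel, st, period = 0.035)
  s <- extract_inlet_samples(vox, segment(vox, 0.5), plane_spec(0, "inlet"))
  q_true <- 0.5 * 1 * pi * vessel$radius^2
  expect_equal(flow_rate(s)[1], q_true, tolerance = 0.02)
  # the fit-based integral is a different estimator but lands nearby
  fit <- fit_inlet_surface(s, degree = 4)
  expect_equal(flow_rate_from_fit(fit)[1], q_true, tolerance = 0.1)
})

test_that("surface-fit interpolation error grows at coarser resolution", {
  # RMS of the degree-4 fit against the analytic field on a dense grid,
  # peak frame, 10 seeded offsets: larger at 4 mm than at 1.5 mm
  d <- fx_decomp(); v <- fx_vessel(); fl <- fx_fluid()
  field <- fx_field()
  pl <- plane_spec(-v$length / 4, "inlet")
  set.seed(1618)
  offsets <- replicate(10, runif(3), simplify = FALSE)
  g <- seq(-0.9 * v$radius, 0.9 * v$radius, length.out = 25)
  dense <- expand.grid(x = g, z = g)
  dense <- dense[dense$x^2 + dense$z^2 <= (0.9 * v$radius)^2, ]
  rms <- sapply(c(4, 1.5), function(res) {
    mean(sapply(offsets, function(off) {
      st <- acquisition_settings(res, dt_ms = 35, grid_offset = off)
      vox <- acquire(field, v, st, d$period)
      s <- extract_inlet_samples(vox, segment(vox, 0.5), pl)
      pk <- which.max(flow_rate(s))
      fit <- fit_inlet_surface(s, degree = 4)
      pred <- evaluate_fit(fit, dense$x, dense$z, vox$frame_times[pk])
      r <- sqrt(dense$x^2 + dense$z^2)
      truth <- velocity_profile(d, v, fl, r, vox$frame_times[pk])
      sqrt(mean((pred - truth)^2))
    }))
  })
  expect_gt(rms[1], rms[2])
})

test_that("inlet fits and flow series export as structured text", {
  s <- make_samples(n_frames = 3,
                    value_fun = function(x, z, f) f * (1 - (x^2 + z^2) / 0.0125^2))
  fit <- fit_inlet_surface(s, degree = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  export_inlet_fit(fit, path)
  lines <- readLines(path)
  expect_match(lines[1], "^degree 2$")
  expect_length(grep("^coef ", lines), 3)
  # round-trip one coefficient at full precision
  c1 <- as.numeric(strsplit(sub("^coef ", "", grep("^coef ", lines,
                                                   value = TRUE)[1]), " ")[[1]])
  expect_equal(c1, unname(fit$coef[, 1]), tolerance = 1e-15)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(s, csv)
  df <- read.csv(csv)
  expect_equal(names(df), c("frame_time_s", "flow_m3s"))
  expect_equal(df$flow_m3s, flow_rate(s))
})
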