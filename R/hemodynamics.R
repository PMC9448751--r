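# Phase-window construction and plane-level metrics: maximum / mean
# velocity magnitude and eight-sector wall shear stress.

#' Systolic and diastolic phase windows from a flow series
#'
#' Systole is the peak-flow frame plus the frames immediately before and
#' after (cyclically wrapped). Diastole runs from the first post-peak frame
#' where the flow drops below \code{diastole_fraction} of the peak through
#' the end of the cycle, excluding any systolic frame. Tied maxima are
#' broken to the earliest frame (with a message).
#'
#' @param Q per-frame flow series (length >= 5).
#' @param diastole_fraction flow threshold for diastole onset, as a fraction
#'   of the peak (default 0.2).
#' @return An object of class \code{phase_windows} with integer frame-index
#'   vectors \code{systolic_frames} and \code{diastolic_frames} (1-based).
#' @examples
#' phase_windows(c(0, 1, 5, 1, 0.2, 0.1, 0.1))
#' @export
phase_windows <- function(Q, diastole_fraction = 0.2) {
  n <- length(Q)
  if (n < 5L) stop("need at least 5 frames")
  peaks <- which(Q == max(Q))
  if (length(peaks) > 1L)
    message(sprintf("phase_windows: %d tied maxima; using the earliest (frame %d)",
                    length(peaks), peaks[1]))
  p <- peaks[1]
  systolic <- ((p - 2L):p %% n) + 1L               # p-1, p, p+1 wrapped
  thr <- diastole_fraction * Q[p]
  after <- if (p < n) (p + 1L):n else integer(0)
  low <- after[Q[after] < thr]
  diastolic <- if (length(low) == 0L) integer(0) else setdiff(low[1]:n, systolic)
  structure(list(systolic_frames = systolic, diastolic_frames = diastolic,
                 peak_frame = p),
            class = "phase_windows")
}

#' Plane-level velocity metrics
#'
#' Per-voxel velocity magnitudes are averaged across the window frames
#' first; the maximum and mean are then taken over the lumen voxels of the
#' plane's slice.
#'
#' @param vox a \code{\link{acquire}} result.
#' @param mask a \code{\link{segment}} result.
#' @param plane a \code{\link{plane_spec}}.
#' @param window integer frame indices (e.g. a component of
#'   \code{\link{phase_windows}}).
#' @param phase optional label ("systole"/"diastole") carried through.
#' @return A list with \code{max_velocity}, \code{mean_velocity} (m/s) and
#'   \code{phase}.
#' @export
plane_metrics <- function(vox, mask, plane, window, phase = NA_character_) {
  stopifnot(inherits(vox, "voxel4dflow"), inherits(mask, "lumen_mask"))
  if (length(window) == 0L) stop("`window` must be non-empty")
  j <- .slice_index(vox, plane)
  sl <- mask$mask[, j, ]
  if (!any(sl)) stop("empty lumen slice at the requested plane")
  acc <- matrix(0, vox$dims[1], vox$dims[3])
  for (f in window) {
    sp <- sqrt(vox$velocity[, j, , 1, f]^2 + vox$velocity[, j, , 2, f]^2 +
                 vox$velocity[, j, , 3, f]^2)
    acc <- acc + sp
  }
  acc <- acc / length(window)
  vals <- acc[sl]
  list(max_velocity = max(vals), mean_velocity = mean(vals), phase = phase)
}

# sector labels every 45 degrees starting at +x, rotating towards -z
# (radiological anterior): R, RA, A, LA, L, LP, P, RP
.sector_labels <- c("R", "RA", "A", "LA", "L", "LP", "P", "RP")
.sector_angles <- -(0:7) * pi / 4     # direction angle in the x-z plane

#' Eight-sector wall shear stress profile
#'
#' Estimates the wall shear stress at eight equally spaced angular positions
#' on the vessel wall in the analysis plane. Along each of the 8 rays (45
#' degree spacing; sector \code{R} at +x, \code{A} at -z), the through-plane
#' velocity is sampled at \code{fit_points} positions stepping inward from
#' the wall by \code{spacing}; a straight line is fitted over distance from
#' the wall and the WSS is \eqn{\mu |\mathrm{slope}|}, averaged over the
#' window frames. Each sector value is the estimate at the ray angle (a
#' point sample, not a sector average).
#'
#' @param x a \code{voxel4dflow} (sampled by bilinear interpolation of the
#'   through-plane velocity in the slice; default spacing one voxel) or a
#'   continuous field function \code{f(x, y, z, t)} (default spacing R/50).
#' @param vessel a \code{\link{vessel_model}} providing the wall position.
#' @param fluid a \code{\link{fluid_properties}}.
#' @param plane a \code{\link{plane_spec}}; defaults to the vessel mid-plane
#'   for continuous fields.
#' @param window frame indices (voxel input) — or, for a continuous field,
#'   \code{times}: the time instants in s to average over.
#' @param fit_points number of samples per ray (>= 2, default 3).
#' @param spacing sample spacing in m.
#' @param phase optional label carried through.
#' @param ... passed to methods.
#' @return An object of class \code{wss_profile}: named numeric \code{wss}
#'   (Pa, 8 sectors), \code{phase}, \code{spacing}, \code{fit_points}.
#' @export
wss_sectors <- function(x, ...) UseMethod("wss_sectors")

# straight-line slope of u over wall distance d (least squares, closed form)
.ray_slope <- function(d, u) {
  db <- d - mean(d)
  sum(db * u) / sum(db^2)
}

#' @rdname wss_sectors
#' @export
wss_sectors.function <- function(x, vessel, fluid, plane = NULL, times,
                                 fit_points = 3L, spacing = vessel$radius / 50,
                                 phase = NA_character_, ...) {
  stopifnot(inherits(vessel, "vessel_model"), fit_points >= 2L)
  R <- vessel$radius
  y0 <- if (is.null(plane)) vessel$center[2] else plane$axis_coordinate
  d <- (seq_len(fit_points) - 1L) * spacing     # distance inward from wall
  r <- R - d
  if (any(r < 0)) stop("ray samples extend beyond the vessel axis; reduce `spacing` or `fit_points`")
  wss <- numeric(8)
  for (s in 1:8) {
    ang <- .sector_angles[s]
    px <- vessel$center[1] + r * cos(ang)
    pz <- vessel$center[3] + r * sin(ang)
    tau <- vapply(times, function(t) {
      v <- x(px, rep(y0, fit_points), pz, t)
      u <- v[, 1] * vessel$axis[1] + v[, 2] * vessel$axis[2] +
        v[, 3] * vessel$axis[3]
      fluid$dynamic_viscosity * abs(.ray_slope(d, u))
    }, numeric(1))
    wss[s] <- mean(tau)
  }
  structure(list(wss = stats::setNames(wss, .sector_labels), phase = phase,
                 spacing = spacing, fit_points = as.integer(fit_points)),
            class = "wss_profile")
}

# bilinear interpolation of a slice image (nx x nz, voxel centers) at points
.bilinear_slice <- function(img, origin_x, origin_z, h, px, pz) {
  nx <- nrow(img); nz <- ncol(img)
  gx <- (px - origin_x) / h + 0.5   # fractional voxel index
  gz <- (pz - origin_z) / h + 0.5
  i0 <- pmin(pmax(floor(gx), 1), nx - 1)
  k0 <- pmin(pmax(floor(gz), 1), nz - 1)
  fx <- pmin(pmax(gx - i0, 0), 1)
  fz <- pmin(pmax(gz - k0, 0), 1)
  v00 <- img[cbind(i0, k0)];     v10 <- img[cbind(i0 + 1, k0)]
  v01 <- img[cbind(i0, k0 + 1)]; v11 <- img[cbind(i0 + 1, k0 + 1)]
  (1 - fx) * (1 - fz) * v00 + fx * (1 - fz) * v10 +
    (1 - fx) * fz * v01 + fx * fz * v11
}

#' @rdname wss_sectors
#' @export
wss_sectors.voxel4dflow <- function(x, vessel, fluid, plane, window,
                                    fit_points = 3L, spacing = x$voxel_size,
                                    phase = NA_character_, ...) {
  stopifnot(inherits(vessel, "vessel_model"), fit_points >= 2L)
  if (length(window) == 0L) stop("`window` must be non-empty")
  R <- vessel$radius
  j <- .slice_index(x, plane)
  d <- (seq_len(fit_points) - 1L) * spacing
  r <- R - d
  if (any(r < 0)) stop("ray samples extend beyond the vessel axis; reduce `spacing` or `fit_points`")
  wss <- numeric(8)
  for (s in 1:8) {
    ang <- .sector_angles[s]
    px <- vessel$center[1] + r * cos(ang)
    pz <- vessel$center[3] + r * sin(ang)
    tau <- vapply(window, function(f) {
      u <- .bilinear_slice(x$velocity[, j, , 2, f], x$origin[1], x$origin[3],
                           x$voxel_size, px, pz)
      fluid$dynamic_viscosity * abs(.ray_slope(d, u))
    }, numeric(1))
    wss[s] <- mean(tau)
  }
  structure(list(wss = stats::setNames(wss, .sector_labels), phase = phase,
                 spacing = spacing, fit_points = as.integer(fit_points)),
            class = "wss_profile")
}

#' @export
print.wss_profile <- function(x, ...) {
  cat(sprintf("8-sector WSS (Pa)%s:\n",
              if (is.na(x$phase)) "" else paste0(", ", x$phase)))
  print(round(x$wss, 5))
  invisible(x)
}

#' Export metrics and WSS profiles as CSV
#'
#' \code{write_wss_csv} writes \code{(phase, sector, wss_Pa)};
#' \code{write_metrics_csv} writes \code{(phase, max_ms, mean_ms)}.
#'
#' @param profiles a list of \code{wss_profile} objects.
#' @param metrics a list of \code{\link{plane_metrics}} results.
#' @param path output CSV path.
#' @export
write_wss_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(phase = p$phase, sector = names(p$wss), wss_Pa = unname(p$wss))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wss_csv
#' @export
write_metrics_csv <- function(metrics, path) {
  rows <- do.call(rbind, lapply(metrics, function(m)
    data.frame(phase = m$phase, max_ms = m$max_velocity,
               mean_ms = m$mean_velocity)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
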