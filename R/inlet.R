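# Inlet boundary-condition extraction: per-frame through-plane velocities at
# lumen voxel centers on the inlet plane, a spatio-temporal polynomial
# surface fit, and voxel-sum volumetric flow rate.

#' Extract inlet-plane velocity samples
#'
#' Collects the through-plane (vessel-axis, i.e. y) velocity component at
#' every lumen voxel center in the plane's slice, for every frame. The same
#' point set is used across frames.
#'
#' @param vox a \code{\link{acquire}} result.
#' @param mask a \code{\link{segment}} result on the same grid.
#' @param plane a \code{\link{plane_spec}}.
#'
#' @return An object of class \code{inlet_samples}: \code{x}, \code{z}
#'   point coordinates (m), \code{v} (matrix n_points x n_frames of
#'   through-plane velocities, m/s), \code{frame_times}, \code{period},
#'   \code{voxel_size}, and the lumen domain descriptor \code{center} /
#'   \code{radius} used by the surface fit's no-slip clamp.
#' @export
extract_inlet_samples <- function(vox, mask, plane) {
  stopifnot(inherits(vox, "voxel4dflow"), inherits(mask, "lumen_mask"),
            inherits(plane, "plane_spec"))
  if (!all(dim(mask$mask) == vox$dims[1:3]))
    stop("mask and voxel grid dimensions differ")
  j <- .slice_index(vox, plane)
  sl <- mask$mask[, j, ]                     # nx x nz
  idx <- which(sl, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty lumen slice at the requested plane")
  h <- vox$voxel_size
  x <- vox$origin[1] + (idx[, 1] - 0.5) * h
  z <- vox$origin[3] + (idx[, 2] - 0.5) * h
  nf <- vox$dims[4]
  v <- matrix(0, nrow(idx), nf)
  for (f in seq_len(nf)) {
    vy <- vox$velocity[, j, , 2, f]
    v[, f] <- vy[idx]
  }
  ctr <- c(mean(range(x)), mean(range(z)))
  rad <- sqrt(max((x - ctr[1])^2 + (z - ctr[2])^2)) + h / 2
  structure(
    list(x = x, z = z, v = v, frame_times = vox$frame_times,
         period = vox$period, voxel_size = h, center = ctr, radius = rad),
    class = "inlet_samples"
  )
}

# lexicographic 2-D monomial exponents with total degree <= degree
.monomial_exponents <- function(degree) {
  ex <- expand.grid(a = 0:degree, b = 0:degree)
  ex <- ex[ex$a + ex$b <= degree, , drop = FALSE]
  ex[order(ex$a + ex$b, ex$a, ex$b), , drop = FALSE]
}

#' Fit the spatio-temporal inlet surface
#'
#' Per-frame ordinary least squares of the through-plane velocity over the
#' bivariate monomial basis \eqn{x^a z^b}, \eqn{a + b \le} degree
#' (coordinates centered and scaled by the lumen domain for conditioning).
#' Degenerate (rank-deficient) systems fall back to the minimum-norm
#' solution via the singular value decomposition, with a message.
#'
#' @param samples an \code{\link{extract_inlet_samples}} result.
#' @param degree polynomial total degree (default 4).
#' @return An object of class \code{inlet_fit}: \code{degree},
#'   \code{exponents}, per-frame coefficient matrix \code{coef}
#'   (n_terms x n_frames, in the scaled basis), domain \code{center} /
#'   \code{radius}, \code{frame_times} and \code{period}.
#' @export
fit_inlet_surface <- function(samples, degree = 4L) {
  stopifnot(inherits(samples, "inlet_samples"))
  degree <- as.integer(degree)
  ex <- .monomial_exponents(degree)
  n_terms <- nrow(ex)
  n_pts <- length(samples$x)
  if (n_pts < n_terms)
    stop(sprintf(paste("insufficient samples: %d inlet points cannot determine %d",
                       "basis terms (degree %d); too few data points across",
                       "the inlet plane at this resolution"),
                 n_pts, n_terms, degree))
  xs <- (samples$x - samples$center[1]) / samples$radius
  zs <- (samples$z - samples$center[2]) / samples$radius
  X <- outer(xs, ex$a, `^`) * outer(zs, ex$b, `^`)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (!all(pos))
    message(sprintf("inlet surface fit: rank-deficient design (rank %d of %d); minimum-norm solution used",
                    sum(pos), n_terms))
  dinv <- ifelse(pos, 1 / sv$d, 0)
  # coefficients for all frames at once: V D^+ U' Y
  coef <- sv$v %*% (dinv * (t(sv$u) %*% samples$v))
  structure(
    list(degree = degree, exponents = ex, coef = coef,
         center = samples$center, radius = samples$radius,
         frame_times = samples$frame_times, period = samples$period),
    class = "inlet_fit"
  )
}

#' Evaluate the inlet surface fit
#'
#' Polynomial value at (x, z) linearly interpolated in time between the two
#' bracketing frames (cyclically across the period boundary). Points outside
#' the lumen domain return 0 (no-slip clamp).
#'
#' @param fit a \code{\link{fit_inlet_surface}} result.
#' @param x,z in-plane coordinates in m (equal-length vectors).
#' @param t a single time in s (wrapped modulo the period).
#' @return Through-plane velocities in m/s.
#' @export
evaluate_fit <- function(fit, x, z, t) {
  stopifnot(inherits(fit, "inlet_fit"), length(t) == 1L)
  tw <- t %% fit$period
  ft <- fit$frame_times
  nf <- length(ft)
  # bracketing frames, cyclic
  if (tw < ft[1] || tw >= ft[nf]) {
    f0 <- nf; f1 <- 1L
    gap <- (ft[1] + fit$period) - ft[nf]
    w1 <- ((tw - ft[nf]) %% fit$period) / gap
  } else {
    f0 <- findInterval(tw, ft)
    f1 <- f0 + 1L
    w1 <- (tw - ft[f0]) / (ft[f1] - ft[f0])
  }
  cf <- (1 - w1) * fit$coef[, f0] + w1 * fit$coef[, f1]
  xs <- (x - fit$center[1]) / fit$radius
  zs <- (z - fit$center[2]) / fit$radius
  X <- outer(xs, fit$exponents$a, `^`) * outer(zs, fit$exponents$b, `^`)
  val <- drop(X %*% cf)
  val[xs^2 + zs^2 > 1] <- 0
  val
}

#' Volumetric flow rate from inlet samples
#'
#' Riemann voxel-sum integration: per frame, the sum of through-plane
#' velocities times the voxel face area. This integrates the voxel data
#' directly; \code{\link{flow_rate_from_fit}} integrates the polynomial
#' surface instead and generally differs.
#'
#' @param samples an \code{\link{extract_inlet_samples}} result.
#' @return Numeric vector of per-frame flow rates in m^3/s.
#' @export
flow_rate <- function(samples) {
  stopifnot(inherits(samples, "inlet_samples"))
  colSums(samples$v) * samples$voxel_size^2
}

#' Volumetric flow rate from the fitted inlet surface
#'
#' Midpoint-rule integral of \code{\link{evaluate_fit}} over the lumen
#' domain disk, per frame.
#'
#' @param fit an \code{\link{fit_inlet_surface}} result.
#' @param n_grid integration grid points per axis.
#' @return Numeric vector of per-frame flow rates in m^3/s.
#' @export
flow_rate_from_fit <- function(fit, n_grid = 64L) {
  stopifnot(inherits(fit, "inlet_fit"))
  r0 <- fit$radius
  g <- (seq_len(n_grid) - 0.5) / n_grid * 2 * r0 - r0
  pts <- expand.grid(x = fit$center[1] + g, z = fit$center[2] + g)
  cell <- (2 * r0 / n_grid)^2
  vapply(fit$frame_times, function(t)
    sum(evaluate_fit(fit, pts$x, pts$z, t)) * cell, numeric(1))
}

#' Export an inlet fit as structured text
#'
#' Writes the fit in a plain-text block format: degree, domain, frame times,
#' then one line per frame with the coefficients in lexicographic monomial
#' order at 17 significant digits.
#'
#' @param fit an \code{inlet_fit}.
#' @param path output file.
#' @export
export_inlet_fit <- function(fit, path) {
  stopifnot(inherits(fit, "inlet_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("degree %d", fit$degree),
    sprintf("domain_center_m %s", paste(sprintf("%.17g", fit$center), collapse = " ")),
    sprintf("domain_radius_m %.17g", fit$radius),
    sprintf("period_s %.17g", fit$period),
    sprintf("monomials %s", paste(sprintf("x^%dz^%d", fit$exponents$a,
                                          fit$exponents$b), collapse = " ")),
    sprintf("frame_times_s %s", paste(sprintf("%.17g", fit$frame_times),
                                      collapse = " "))), con)
  for (f in seq_along(fit$frame_times))
    writeLines(sprintf("coef %s", paste(sprintf("%.17g", fit$coef[, f]),
                                        collapse = " ")), con)
  invisible(path)
}

#' Export per-frame flow rates as CSV
#'
#' Columns \code{frame_time_s}, \code{flow_m3s}.
#'
#' @param samples an \code{inlet_samples} result.
#' @param path output CSV path.
#' @export
write_flow_csv <- function(samples, path) {
  utils::write.csv(
    data.frame(frame_time_s = samples$frame_times, flow_m3s = flow_rate(samples)),
    path, row.names = FALSE)
  invisible(path)
}
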