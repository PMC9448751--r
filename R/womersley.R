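# Analytic pulsatile flow in a rigid straight tube (Womersley solution),
# driven by the harmonic decomposition of a volumetric flow waveform.
#
# Each harmonic k >= 1 of the flow rate contributes the flow-driven Womersley
# mode
#   u_k(r, t) = Re{ (Q_k / (pi R^2)) *
#                   [1 - J0(b_k r/R) / J0(b_k)] / D_k * e^{i k w t} },
#   b_k = i^{3/2} alpha_k,  alpha_k = R sqrt(k w / nu),
#   D_k = 1 - 2 J1(b_k) / (b_k J0(b_k)),
# and the steady harmonic contributes the Poiseuille profile
#   u_0(r) = (2 Q_0 / (pi R^2)) (1 - (r/R)^2).
# The cross-section integral of each mode recovers its Q_k exactly, so the
# profile conserves the reconstructed flow rate at every instant.

# i^{3/2} = e^{i 3 pi / 4}
.I32 <- complex(real = cos(3 * pi / 4), imaginary = sin(3 * pi / 4))

#' Womersley number
#'
#' \eqn{\alpha = R \sqrt{\omega / \nu}}, the ratio of transient inertial to
#' viscous forces in pulsatile tube flow.
#'
#' @param radius tube radius in m.
#' @param angular_frequency in rad/s.
#' @param kinematic_viscosity in m^2/s (must be positive).
#' @return The dimensionless Womersley number.
#' @examples
#' womersley_number(0.0125, 2 * pi, 3.5e-3 / 1060)  # ~17.24
#' @export
womersley_number <- function(radius, angular_frequency, kinematic_viscosity) {
  if (any(kinematic_viscosity <= 0)) stop("`kinematic_viscosity` must be > 0")
  if (any(radius < 0) || any(angular_frequency < 0))
    stop("`radius` and `angular_frequency` must be non-negative")
  radius * sqrt(angular_frequency / kinematic_viscosity)
}

# Per-harmonic complex constants shared by the profile and the WSS:
# for k >= 1, the profile is Re{ A_k [1 - J0(b_k r/R)/J0(b_k)] e^{ikwt} }
# with A_k = (Q_k / (pi R^2)) / D_k.
.womersley_modes <- function(decomp, vessel, fluid) {
  R <- vessel$radius
  K <- length(decomp$amplitudes) - 1L
  if (K < 1L)
    return(list(K = 0L, A = complex(0), b = complex(0), J0b = complex(0),
                J1b = complex(0), R = R))
  k <- seq_len(K)
  alpha <- womersley_number(R, k * decomp$omega, fluid$kinematic_viscosity)
  b <- .I32 * alpha
  J <- besselJ01_complex(b)
  D <- 1 - 2 * J$J1 / (b * J$J0)
  A <- (decomp$amplitudes[k + 1L] / (pi * R^2)) / D
  list(K = K, A = A, b = b, J0b = J$J0, J1b = J$J1, R = R)
}

#' Axial velocity profile of the Womersley solution
#'
#' Evaluates the analytic axial velocity \eqn{u(r, t)} in m/s for a
#' flow-driven Womersley solution. Satisfies no-slip exactly
#' (\eqn{u(R, t) = 0}) and conserves the reconstructed flow rate:
#' \eqn{2\pi \int_0^R u\, r\, dr = Q(t)}.
#'
#' @param decomp a \code{\link{decompose_waveform}} result.
#' @param vessel a \code{\link{vessel_model}}.
#' @param fluid a \code{\link{fluid_properties}}.
#' @param r radial positions in m (vector, \code{0 <= r <= R}).
#' @param t a single time in s.
#' @return Axial velocities, one per element of \code{r}.
#' @examples
#' d <- decompose_waveform(make_waveform(), 8)
#' velocity_profile(d, vessel_model(), fluid_properties(), r = 0, t = 0.19)
#' @export
velocity_profile <- function(decomp, vessel, fluid, r, t) {
  stopifnot(inherits(decomp, "harmonic_decomposition"),
            inherits(vessel, "vessel_model"),
            inherits(fluid, "fluid_properties"),
            length(t) == 1L)
  R <- vessel$radius
  if (any(r < 0) || any(r > R * (1 + 1e-12)))
    stop("radial positions must satisfy 0 <= r <= R")
  r <- pmin(r, R)
  Q0 <- Re(decomp$amplitudes[1])
  u <- (2 * Q0 / (pi * R^2)) * (1 - (r / R)^2)
  m <- .womersley_modes(decomp, vessel, fluid)
  if (m$K >= 1L) {
    for (k in seq_len(m$K)) {
      J0r <- besselJ01_complex(m$b[k] * r / R)$J0
      u <- u + Re(m$A[k] * (1 - J0r / m$J0b[k]) *
                    exp(1i * k * decomp$omega * t))
    }
    # enforce exact no-slip against quadrature round-off
    u[r == R] <- 0
  }
  u
}

#' Analytic wall shear stress of the Womersley solution
#'
#' \eqn{\tau(t) = -\mu\, \partial u / \partial r} at \eqn{r = R}, in Pa
#' (positive for forward flow). The steady harmonic contributes the
#' Poiseuille value \eqn{4 \mu Q_0 / (\pi R^3)}; each oscillatory mode is
#' differentiated in closed form via
#' \eqn{d J_0(\lambda r / R)/dr = -(\lambda / R) J_1(\lambda r / R)}.
#'
#' @inheritParams velocity_profile
#' @param t times in s (vector).
#' @return Signed wall shear stress in Pa, one per element of \code{t}.
#' @export
analytic_wss <- function(decomp, vessel, fluid, t) {
  stopifnot(inherits(decomp, "harmonic_decomposition"))
  R <- vessel$radius
  mu <- fluid$dynamic_viscosity
  Q0 <- Re(decomp$amplitudes[1])
  tau <- rep(4 * mu * Q0 / (pi * R^3), length(t))
  m <- .womersley_modes(decomp, vessel, fluid)
  if (m$K >= 1L) {
    k <- seq_len(m$K)
    # wall slope coefficient of mode k: A_k * (b_k / R) * J1(b_k) / J0(b_k)
    coef <- m$A * (m$b / R) * m$J1b / m$J0b
    ph <- exp(1i * outer(t, k * decomp$omega))   # |t| x K
    tau <- tau - mu * Re(drop(ph %*% coef))
  }
  tau
}

#' Continuous Womersley velocity field sampler
#'
#' Wraps the analytic solution as a fast vectorized 3-D field
#' \code{f(x, y, z, t)} returning an n x 3 matrix of velocity components
#' (m/s), for use with \code{\link{acquire}}. The radial shape of each
#' harmonic is pre-tabulated on a dense grid and interpolated with cubic
#' splines, so repeated evaluation at many points is cheap. Points outside
#' the lumen (radius beyond R or beyond the tube ends) get zero velocity.
#'
#' @inheritParams velocity_profile
#' @param n_radial number of radial pre-tabulation points.
#' @return A function \code{f(x, y, z, t)}; \code{x}, \code{y}, \code{z} are
#'   equal-length coordinate vectors in m and \code{t} a single time in s.
#' @export
womersley_field <- function(decomp, vessel, fluid, n_radial = 2048L) {
  R <- vessel$radius
  rg <- seq(0, R, length.out = n_radial)
  Q0 <- Re(decomp$amplitudes[1])
  m <- .womersley_modes(decomp, vessel, fluid)
  K <- m$K
  # complex radial shape functions C_k(r): u(r,t) = Re{ sum_k C_k(r) e^{ikwt} }
  shapes <- vector("list", K)
  if (K >= 1L) {
    for (k in seq_len(K)) {
      Ck <- m$A[k] * (1 - besselJ01_complex(m$b[k] * rg / R)$J0 / m$J0b[k])
      shapes[[k]] <- list(
        re = stats::splinefun(rg, Re(Ck), method = "fmm"),
        im = stats::splinefun(rg, Im(Ck), method = "fmm"))
    }
  }
  axis <- vessel$axis
  center <- vessel$center
  half_len <- vessel$length / 2
  omega <- decomp$omega

  # point-set geometry shared by both evaluation paths
  locate <- function(x, y, z) {
    px <- x - center[1]; py <- y - center[2]; pz <- z - center[3]
    ax <- px * axis[1] + py * axis[2] + pz * axis[3]
    r <- sqrt(pmax(px^2 + py^2 + pz^2 - ax^2, 0))
    list(r = r, inside = r <= R & abs(ax) <= half_len)
  }

  f <- function(x, y, z, t) {
    g <- locate(x, y, z)
    u <- numeric(length(x))
    if (any(g$inside)) {
      ri <- g$r[g$inside]
      ui <- (2 * Q0 / (pi * R^2)) * (1 - (ri / R)^2)
      if (K >= 1L) {
        for (k in seq_len(K)) {
          ph <- exp(1i * k * omega * t)
          ui <- ui + Re(complex(real = shapes[[k]]$re(ri),
                                imaginary = shapes[[k]]$im(ri)) * ph)
        }
      }
      u[g$inside] <- ui
    }
    cbind(u * axis[1], u * axis[2], u * axis[3])
  }

  # time-caching fast path used by acquire(): the radial shape of every
  # harmonic is evaluated once per point set, so each frame costs only the
  # complex phase rotation.
  attr(f, "time_cached_sampler") <- function(x, y, z) {
    g <- locate(x, y, z)
    inside <- g$inside
    ri <- g$r[inside]
    u0 <- (2 * Q0 / (pi * R^2)) * (1 - (ri / R)^2)
    C <- if (K >= 1L)
      vapply(seq_len(K), function(k)
        complex(real = shapes[[k]]$re(ri), imaginary = shapes[[k]]$im(ri)),
        complex(length(ri)))
    else NULL
    n <- length(x)
    function(t) {
      ui <- u0
      if (K >= 1L) {
        ph <- exp(1i * seq_len(K) * omega * t)
        ui <- ui + Re(drop(C %*% ph))
      }
      u <- numeric(n)
      u[inside] <- ui
      cbind(u * axis[1], u * axis[2], u * axis[3])
    }
  }
  f
}
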