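# Periodic volumetric inflow waveform and its Fourier representation.

#' Construct a cardiac-style volumetric flow waveform
#'
#' Builds a smooth periodic volumetric flow rate Q(t) with a single sharp
#' systolic peak and low, constant diastolic flow: a raised-cosine lobe over
#' the systolic window (rising to \code{peak_flow} at 60% of the window,
#' a typical peak-systole timing) on top of the end-diastolic level. The
#' waveform is C1-continuous and periodic. The peak time is snapped to the
#' sampling grid so that the sampled maximum equals \code{peak_flow} exactly.
#'
#' @param peak_flow peak volumetric flow in m^3/s.
#' @param period cardiac period in s.
#' @param systolic_fraction fraction of the period occupied by systole,
#'   in (0, 1).
#' @param end_diastolic_flow constant diastolic flow in m^3/s
#'   (\code{0 <= end_diastolic_flow < peak_flow}).
#' @param n_samples number of uniform samples over one period (>= 8).
#'
#' @return An object of class \code{flow_waveform}: fields \code{period},
#'   \code{sample_times} (uniform in \[0, period)), \code{flow_values}
#'   (m^3/s), and \code{params} (the parametric descriptor, including the
#'   snapped \code{peak_time}).
#' @examples
#' w <- make_waveform()
#' max(w$flow_values)  # equals the default peak flow, 2.45e-4 m^3/s
#' @export
make_waveform <- function(peak_flow = 2.45e-4, period = 0.9,
                          systolic_fraction = 0.35,
                          end_diastolic_flow = 1e-5, n_samples = 64L) {
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("`period` must be a single positive number (s)")
  if (n_samples < 8L) stop("`n_samples` must be at least 8")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("`systolic_fraction` must lie in (0, 1)")
  if (end_diastolic_flow < 0 || peak_flow <= end_diastolic_flow)
    stop("need peak_flow > end_diastolic_flow >= 0")
  n_samples <- as.integer(n_samples)

  t_sys <- systolic_fraction * period
  # peak at 60% of the systolic window, snapped to the sampling grid
  dt <- period / n_samples
  peak_time <- max(1L, round(0.6 * t_sys / dt)) * dt
  if (peak_time >= t_sys) peak_time <- floor(t_sys / dt - 1e-9) * dt

  tt <- (seq_len(n_samples) - 1L) * dt
  params <- list(peak_flow = peak_flow, period = period,
                 systolic_fraction = systolic_fraction,
                 end_diastolic_flow = end_diastolic_flow,
                 peak_time = peak_time)
  structure(
    list(period = period, sample_times = tt,
         flow_values = .waveform_eval(tt, params), params = params),
    class = "flow_waveform"
  )
}

# Continuous waveform evaluator: raised-cosine rise/fall within the systolic
# window, constant end-diastolic flow elsewhere; C1 everywhere.
.waveform_eval <- function(t, p) {
  t <- t %% p$period
  t_sys <- p$systolic_fraction * p$period
  tp <- p$peak_time
  s <- numeric(length(t))
  rise <- t <= tp
  s[rise] <- 0.5 * (1 - cos(pi * t[rise] / tp))
  fall <- !rise & t < t_sys
  s[fall] <- 0.5 * (1 + cos(pi * (t[fall] - tp) / (t_sys - tp)))
  p$end_diastolic_flow + (p$peak_flow - p$end_diastolic_flow) * s
}

#' Construct a flow waveform from samples
#'
#' Low-level constructor for a periodic flow waveform given explicit sample
#' times and values (e.g. digitized from an external source). For the
#' parametric cardiac-style waveform use \code{\link{make_waveform}}.
#'
#' @param sample_times strictly increasing times in \[0, period), s.
#' @param flow_values flow rates at those times, m^3/s.
#' @param period cardiac period in s.
#' @return A \code{flow_waveform}.
#' @export
flow_waveform <- function(sample_times, flow_values, period) {
  if (period <= 0) stop("`period` must be positive")
  if (length(sample_times) != length(flow_values))
    stop("`sample_times` and `flow_values` lengths differ")
  if (is.unsorted(sample_times, strictly = TRUE))
    stop("`sample_times` must be strictly increasing")
  if (any(sample_times < 0) || any(sample_times >= period))
    stop("`sample_times` must lie in [0, period)")
  structure(
    list(period = period, sample_times = as.numeric(sample_times),
         flow_values = as.numeric(flow_values), params = NULL),
    class = "flow_waveform"
  )
}

#' Evaluate a flow waveform at arbitrary times
#'
#' @param waveform a \code{flow_waveform}.
#' @param t times in s (wrapped modulo the period).
#' @return Flow values in m^3/s.
#' @export
waveform_at <- function(waveform, t) {
  stopifnot(inherits(waveform, "flow_waveform"))
  if (!is.null(waveform$params)) return(.waveform_eval(t, waveform$params))
  # non-parametric waveform (e.g. read from CSV): periodic linear interpolation
  tt <- c(waveform$sample_times, waveform$sample_times[1] + waveform$period)
  qq <- c(waveform$flow_values, waveform$flow_values[1])
  stats::approx(tt, qq, xout = t %% waveform$period, rule = 2)$y
}

#' Fourier (harmonic) decomposition of a flow waveform
#'
#' Decomposes the periodic flow rate into complex harmonic amplitudes
#' \eqn{Q_0 \ldots Q_K} such that
#' \eqn{Q(t) = \mathrm{Re}\{\sum_k Q_k e^{ik\omega t}\}} with
#' \eqn{\omega = 2\pi/T}. \eqn{Q_0} is real and equals the time-average flow.
#' Non-uniform sample times are resampled to a uniform grid internally
#' (periodic linear interpolation) before the FFT.
#'
#' @param waveform a \code{flow_waveform}.
#' @param n_harmonics number of harmonics K (>= 1); must not exceed the
#'   Nyquist limit \code{floor((n_samples - 1) / 2)}.
#'
#' @return An object of class \code{harmonic_decomposition}: fields
#'   \code{omega} (fundamental angular frequency, rad/s),
#'   \code{amplitudes} (complex vector \eqn{Q_0 \ldots Q_K}, m^3/s) and
#'   \code{period}.
#' @examples
#' d <- decompose_waveform(make_waveform(), n_harmonics = 8)
#' Re(d$amplitudes[1])  # time-average flow
#' @export
decompose_waveform <- function(waveform, n_harmonics = 8L) {
  stopifnot(inherits(waveform, "flow_waveform"))
  if (n_harmonics < 1L) stop("`n_harmonics` must be at least 1")
  tt <- waveform$sample_times
  qq <- waveform$flow_values
  n <- length(tt)
  dt <- diff(tt)
  uniform <- all(abs(dt - dt[1]) < 1e-9 * waveform$period) &&
    abs(tt[1]) < 1e-12
  if (!uniform) {
    tu <- (seq_len(n) - 1L) * waveform$period / n
    # periodic linear interpolation onto the uniform grid
    qq <- stats::approx(c(tt, tt[1] + waveform$period), c(qq, qq[1]),
                        xout = tu, rule = 2)$y
  }
  if (n_harmonics > floor((n - 1) / 2))
    stop(sprintf("`n_harmonics` = %d exceeds the Nyquist limit %d of the sampling",
                 n_harmonics, floor((n - 1) / 2)))
  X <- stats::fft(qq)
  amp <- c(complex(real = Re(X[1]) / n, imaginary = 0),
           2 * X[seq_len(n_harmonics) + 1L] / n)
  structure(
    list(omega = 2 * pi / waveform$period, amplitudes = amp,
         period = waveform$period, n_harmonics = as.integer(n_harmonics)),
    class = "harmonic_decomposition"
  )
}

#' Reconstruct the flow rate from a harmonic decomposition
#'
#' @param decomp a \code{harmonic_decomposition}.
#' @param t times in s.
#' @return \eqn{\mathrm{Re}\{\sum_k Q_k e^{ik\omega t}\}} in m^3/s.
#' @export
reconstruct_flow <- function(decomp, t) {
  stopifnot(inherits(decomp, "harmonic_decomposition"))
  k <- seq_along(decomp$amplitudes) - 1L
  ph <- outer(t, k * decomp$omega)          # |t| x (K+1)
  drop(Re(exp(1i * ph) %*% decomp$amplitudes))
}

#' Read / write a flow waveform as two-column CSV
#'
#' The on-disk format is \code{time_s, flow_m3s}, one row per sample.
#'
#' @param waveform a \code{flow_waveform}.
#' @param path file path.
#' @param period cardiac period in s; when reading, defaults to the last
#'   sample time plus one sample interval.
#' @return \code{write_waveform_csv} returns \code{path} invisibly;
#'   \code{read_waveform_csv} returns a \code{flow_waveform}.
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "flow_waveform"))
  utils::write.csv(
    data.frame(time_s = waveform$sample_times,
               flow_m3s = waveform$flow_values),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, period = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "flow_m3s") %in% names(df)))
    stop("expected columns `time_s`, `flow_m3s`")
  tt <- df$time_s
  if (is.unsorted(tt, strictly = TRUE)) stop("sample times must be strictly increasing")
  if (is.null(period)) {
    period <- tt[length(tt)] + if (length(tt) > 1) tt[2] - tt[1] else 1
  }
  structure(
    list(period = period, sample_times = tt, flow_values = df$flow_m3s,
         params = NULL),
    class = "flow_waveform"
  )
}
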