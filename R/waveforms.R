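# Synthesis of the pulsatile systolic input signal and the phase-shifted,
# ABI-scaled target signal, plus sampled-signal I/O.

#' Waveform specification
#'
#' Describes the synthetic pulsatile flow: a sinusoidal pulse during systole
#' and zero flow during diastole, repeated over a number of cardiac cycles.
#' Defaults correspond to 72 beats per minute (heart period TH = 60/72 s) with
#' systole occupying 2/5 of the cycle (Ts = 0.4 * TH).
#'
#' @param peak_flow Pulse amplitude Q0 (same units as the signal, e.g. m^3/s).
#' @param heart_period Cardiac period TH in seconds; default `60/72`.
#' @param systolic_fraction Fraction of the cycle in systole; default `2/5`.
#' @param n_cycles Number of cardiac cycles; default 3.
#' @param dt Sampling interval in s; default `heart_period/1000`. Must resolve
#'   the systolic pulse (`dt < Ts/20`).
#' @param phase_shift Phase shift in degrees applied by
#'   [phase_shifted_target()]; a shift of 90 delays the pulse by a quarter of
#'   the systolic sine period (Ts/4). Default 90.
#' @param shape `"full_sine"` (value Q0*sin(2*pi*t/Ts) during systole, so one
#'   full sine cycle per systole) or `"half_sine"` (Q0*sin(pi*t/Ts), a single
#'   positive lobe). Default `"full_sine"`.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(peak_flow = 1,
                          heart_period = 60 / 72,
                          systolic_fraction = 2 / 5,
                          n_cycles = 3L,
                          dt = heart_period / 1000,
                          phase_shift = 90,
                          shape = c("full_sine", "half_sine")) {
  shape <- match.arg(shape)
  if (!is.numeric(peak_flow) || length(peak_flow) != 1L ||
      !is.finite(peak_flow) || peak_flow < 0) {
    stop_invalid("'peak_flow' must be a single nonnegative number")
  }
  check_positive_scalar(heart_period, "heart_period")
  check_positive_scalar(systolic_fraction, "systolic_fraction")
  if (systolic_fraction >= 1) {
    stop_invalid("'systolic_fraction' must lie strictly between 0 and 1")
  }
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop_invalid("'n_cycles' must be a positive integer")
  }
  check_positive_scalar(dt, "dt")
  ts <- systolic_fraction * heart_period
  if (dt >= ts / 20) {
    stop_invalid(sprintf(
      "sampling interval dt = %g too coarse: must be < Ts/20 = %g", dt, ts / 20))
  }
  check_number(phase_shift, "phase_shift")
  structure(
    list(peak_flow = peak_flow, heart_period = heart_period,
         systolic_fraction = systolic_fraction, n_cycles = as.integer(n_cycles),
         dt = dt, phase_shift = phase_shift, shape = shape),
    class = "waveform_spec"
  )
}

#' Uniformly sampled signal
#'
#' @param times Strictly increasing uniform time grid starting at 0, in s.
#' @param values Signal values (same length as `times`); must be finite.
#' @return An object of class `sampled_signal` (list with `times`, `values`).
#' @export
sampled_signal <- function(times, values) {
  if (length(times) != length(values)) {
    stop_invalid("'times' and 'values' must have equal length")
  }
  if (length(times) < 2L) stop_invalid("a sampled signal needs at least 2 points")
  if (!all(is.finite(times)) || !all(is.finite(values))) {
    stop_invalid("times and values must be finite")
  }
  if (!is_uniform_grid(times)) {
    stop_invalid("'times' must be a strictly increasing uniform grid")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Sampled signal: %d points, t in [0, %.4g] s, dt = %.4g s\n",
              n, x$times[n], x$times[2] - x$times[1]))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.sampled_signal <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

## Periodic pulse value at time t for a unit-amplitude spec (Q0 = 1).
## Uses index arithmetic when dt divides the heart period, so that values a
## whole period apart are bitwise identical.
pulse_phase <- function(spec, times) {
  th <- spec$heart_period
  tau <- times - th * floor(times / th + 1e-12)
  tau
}

unit_pulse_value <- function(spec, tau) {
  ts <- spec$systolic_fraction * spec$heart_period
  inside <- tau >= 0 & tau < ts
  v <- numeric(length(tau))
  if (spec$shape == "full_sine") {
    v[inside] <- sin(2 * pi * tau[inside] / ts)
  } else {
    v[inside] <- sin(pi * tau[inside] / ts)
  }
  v
}

#' Synthesize the systolic pulse input signal
#'
#' Within each cardiac cycle the flow is Q0*sin(2*pi*t/Ts) (full sine) or
#' Q0*sin(pi*t/Ts) (half sine) during systole, t in (0, Ts), and zero during
#' diastole, t in (Ts, TH). The pattern repeats for `n_cycles` cycles on a
#' uniform grid with step `dt` starting at t = 0.
#'
#' @param spec A [waveform_spec()].
#' @return A [sampled_signal()] covering `[0, n_cycles*TH]`.
#' @export
#' @examples
#' sig <- systolic_pulse(waveform_spec(peak_flow = 2e-13))
#' max(sig$values)  # = Q0
systolic_pulse <- function(spec) {
  if (!inherits(spec, "waveform_spec")) {
    stop_invalid("'spec' must be a waveform_spec")
  }
  n <- round(spec$n_cycles * spec$heart_period / spec$dt)
  times <- seq(0, by = spec$dt, length.out = n + 1L)
  m <- spec$heart_period / spec$dt
  if (abs(m - round(m)) < 1e-9) {
    # exact per-cycle repetition when dt divides TH
    m <- round(m)
    tau <- (seq_len(n + 1L) - 1L) %% m * spec$dt
  } else {
    tau <- pulse_phase(spec, times)
  }
  sampled_signal(times, spec$peak_flow * unit_pulse_value(spec, tau))
}

#' Phase-shifted, amplitude-rescaled target signal
#'
#' Builds the target (capillary-exit) signal on the same grid as `input`: the
#' same pulse shape delayed by `(phase_shift/360)*Ts` and rescaled so that its
#' peak equals `amplitude` (typically the ABI-derived capillary flow from
#' [abi_scaled_capillary_flow()]). Samples before the delayed pulse starts
#' are zero.
#'
#' @param input A [sampled_signal()] produced by [systolic_pulse()] (defines
#'   the time grid).
#' @param spec The [waveform_spec()] used for `input`.
#' @param amplitude Peak value of the target signal; must be nonnegative.
#' @return A [sampled_signal()] on the same grid as `input`.
#' @export
phase_shifted_target <- function(input, spec, amplitude) {
  if (!inherits(input, "sampled_signal")) {
    stop_invalid("'input' must be a sampled_signal")
  }
  if (!inherits(spec, "waveform_spec")) {
    stop_invalid("'spec' must be a waveform_spec")
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude < 0) {
    stop_invalid("'amplitude' must be a single nonnegative number")
  }
  ts <- spec$systolic_fraction * spec$heart_period
  delay <- (spec$phase_shift / 360) * ts
  shifted <- input$times - delay
  tau <- pulse_phase(spec, shifted)
  v <- unit_pulse_value(spec, tau)
  v[shifted < 0] <- 0
  # zero-fill past the end of the generating record
  v[shifted >= spec$n_cycles * spec$heart_period] <- 0
  sampled_signal(input$times, amplitude * v)
}

#' Read a sampled signal from CSV
#'
#' Expects exactly the header `time_s,value`, a strictly increasing uniform
#' time grid and finite values.
#'
#' @param path CSV path.
#' @return A [sampled_signal()].
#' @export
read_signal <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop_invalid(sprintf("cannot parse signal file '%s': %s",
                                        path, conditionMessage(e)),
                                class = "capfit_parse_error")
                 })
  if (!identical(names(df), c("time_s", "value"))) {
    stop_invalid("signal CSV must have header 'time_s,value'",
                 class = "capfit_parse_error")
  }
  if (nrow(df) < 2L) {
    stop_invalid("signal CSV must contain at least 2 samples",
                 class = "capfit_parse_error")
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$value) ||
      !all(is.finite(df$time_s)) || !all(is.finite(df$value))) {
    stop_invalid("signal CSV must be numeric and finite",
                 class = "capfit_parse_error")
  }
  if (!is_uniform_grid(df$time_s)) {
    stop_invalid("signal CSV time grid must be uniform and strictly increasing",
                 class = "capfit_parse_error")
  }
  sampled_signal(df$time_s, df$value)
}

#' Write a sampled signal to CSV
#'
#' Writes with 15 significant digits so that a write/read round trip preserves
#' the signal to at least 12 significant digits.
#'
#' @param signal A [sampled_signal()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  if (!inherits(signal, "sampled_signal")) {
    stop_invalid("'signal' must be a sampled_signal")
  }
  df <- data.frame(time_s = format(signal$times, digits = 15, trim = TRUE,
                                   scientific = NA),
                   value = format(signal$values, digits = 15, trim = TRUE,
                                  scientific = NA))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
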