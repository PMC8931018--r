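#' Sensor geometry specification
#'
#' Describes a square contact-separation triboelectric sensor: side length
#' `D`, total thickness `T` (sponge spacer plus films), and how many
#' identical units are electrically combined.
#'
#' @param side_mm Side length D in mm, within \[10, 100\].
#' @param thickness_mm Thickness T in mm, within \[0.5, 10\].
#' @param n_units Number of identical units (>= 1).
#' @param combination How multiple units are wired: `"single"`, `"series"`
#'   or `"parallel"`.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(side_mm = 20, thickness_mm = 5, n_units = 1,
                        combination = c("single", "series", "parallel")) {
  stop_if_not_scalar_num(side_mm, "side_mm", 10, 100)
  stop_if_not_scalar_num(thickness_mm, "thickness_mm", 0.5, 10)
  stop_if_not_scalar_num(n_units, "n_units", 1)
  combination <- match.arg(combination)
  if (n_units > 1 && combination == "single") {
    stop("`combination` must be series or parallel when n_units > 1", call. = FALSE)
  }
  structure(list(side_mm = side_mm, thickness_mm = thickness_mm,
                 n_units = as.integer(n_units), combination = combination),
            class = "sensor_spec")
}

#' Mechanical excitation of a sensor
#'
#' Periodic press-release drive applied to a sensor, as delivered by a
#' linear motor: peak force, pressing frequency, number of cycles and the
#' acquisition sampling rate.
#'
#' @param force_n Peak pressing force in N (>= 0).
#' @param freq_hz Pressing frequency in Hz (> 0).
#' @param n_cycles Number of press-release cycles.
#' @param rate_hz Sampling rate in Hz; must be at least 20 x `freq_hz` to
#'   resolve the pulse shape.
#' @return An object of class `excitation`.
#' @export
excitation <- function(force_n, freq_hz, n_cycles = 5, rate_hz = 1000) {
  stop_if_not_scalar_num(force_n, "force_n", 0)
  stop_if_not_scalar_num(freq_hz, "freq_hz", lower = .Machine$double.eps)
  stop_if_not_scalar_num(n_cycles, "n_cycles", 1)
  stop_if_not_scalar_num(rate_hz, "rate_hz", lower = .Machine$double.eps)
  if (rate_hz < 20 * freq_hz) {
    stop("`rate_hz` must be at least 20 x `freq_hz`", call. = FALSE)
  }
  structure(list(force_n = force_n, freq_hz = freq_hz,
                 n_cycles = as.integer(n_cycles), rate_hz = rate_hz),
            class = "excitation")
}

#' Default sensor calibration table
#'
#' Anchor points for the simulator, taken from bench characterization of the
#' reference sensor (20 x 20 x 5 mm at 5 N, 1 Hz):
#' * peak open-circuit voltage vs force: linear at 0.376 V/N;
#' * peak voltage vs pressing frequency: flat to within a 0.02 V band
#'   (0.89-0.91 V relative band re-centred on the reference peak);
#' * peak short-circuit current vs frequency: 1.88 nA at 1 Hz rising to
#'   9.66 nA at 5 Hz;
#' * area scaling: voltage factor 1.10 -> 3.08 V and current factor
#'   1.52 -> 4.39 nA from D = 20 to D = 50 mm;
#' * thickness response saturating at T = 2 mm;
#' * durability: amplitude 1.40 V at cycle 0 decaying to 1.38 V at cycle 2000.
#'
#' The measured per-axis sweeps were taken one at a time; they are composed
#' multiplicatively as factors relative to the reference condition, with the
#' force axis carrying the absolute scale (V = 0.376 F at reference
#' geometry). Interpolation between anchors is piecewise linear, which
#' preserves the monotonicity of each anchored series.
#'
#' @return An object of class `teng_calibration`: a list of anchor tables.
#' @export
default_calibration <- function() {
  v_ref <- 0.376 * 5  # peak V_oc at the reference condition (5 N, 1 Hz, 20x20x5)
  cal <- list(
    v_ref = v_ref,
    # absolute peak V_oc vs force at 1 Hz, reference geometry (V/N slope 0.376)
    force_v = data.frame(force_n = c(0, 1, 5), v = 0.376 * c(0, 1, 5)),
    # frequency ripple: printed 0.02 V band mapped to factors relative to v_ref
    freq_v = data.frame(freq_hz = 1:5,
                        factor = 1 + c(0, -0.01, 0.01, 0, -0.01) / v_ref),
    # peak I_sc vs frequency (absolute, nA) at 5 N, reference geometry
    freq_i = data.frame(freq_hz = c(1, 5), i_na = c(1.88, 9.66)),
    # area factors relative to D = 20 mm (measured at T = 2 mm)
    area_v = data.frame(side_mm = c(20, 50), factor = c(1.10, 3.08) / 1.10),
    area_i = data.frame(side_mm = c(20, 50), factor = c(1.52, 4.39) / 1.52),
    # thickness factor, saturating at T = 2 mm (reference thickness 5 mm)
    thick = data.frame(thickness_mm = c(0.5, 1, 2, 5, 10),
                       factor = c(0.60, 0.85, 1, 1, 1)),
    # durability endpoints over 2000 press-release cycles
    durability = data.frame(cycle = c(0, 2000), scale = c(1, 1.38 / 1.40))
  )
  stopifnot(all(vapply(cal[-1], function(d) all(d[[2]] >= 0), TRUE)))
  structure(cal, class = "teng_calibration")
}

# Piecewise-linear interpolation within the anchored range; out-of-range
# values either error (calibrated use) or clamp/extend (extrapolate = TRUE).
cal_interp <- function(tab, x, xname, extrapolate = FALSE, slope_extend = FALSE) {
  xs <- tab[[1]]
  ys <- tab[[2]]
  if (any(x < min(xs) | x > max(xs))) {
    if (!extrapolate) {
      stop(sprintf("`%s` = %g outside calibrated range [%g, %g]; set extrapolate = TRUE",
                   xname, x[which(x < min(xs) | x > max(xs))][1], min(xs), max(xs)),
           call. = FALSE)
    }
    if (slope_extend) {
      # extend the terminal linear segments
      lo <- x < min(xs); hi <- x > max(xs)
      out <- stats::approx(xs, ys, xout = pmin(pmax(x, min(xs)), max(xs)))$y
      n <- length(xs)
      out[lo] <- ys[1] + (ys[2] - ys[1]) / (xs[2] - xs[1]) * (x[lo] - xs[1])
      out[hi] <- ys[n] + (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1]) * (x[hi] - xs[n])
      return(out)
    }
  }
  stats::approx(xs, ys, xout = x, rule = 2)$y
}

#' Unit-amplitude biphasic press-release pulse template
#'
#' One mouth open-close (press-release) cycle transfers charge in four
#' stages: nothing flows while the mouth is closed (stage I), current flows
#' one way while pressing (II) until the opening maximum (III), then the
#' opposite way while releasing (IV). The template is a smooth raised-cosine
#' pair: a positive lobe over the pressing half-cycle and a mirror-image
#' negative lobe over the release half-cycle, zero at both stage boundaries,
#' with zero net area over a full cycle (charge conservation).
#'
#' @param phase Numeric vector of cycle phases in \[0, 1).
#' @return Unit-amplitude template values in \[-1, 1\].
#' @examples
#' cycle_shape(c(0, 0.25, 0.5, 0.75))
#' @export
cycle_shape <- function(phase) {
  if (!is.numeric(phase) || any(!is.finite(phase)) || any(phase < 0 | phase >= 1)) {
    stop("`phase` must lie in [0, 1)", call. = FALSE)
  }
  ifelse(phase < 0.5,
         0.5 * (1 - cos(4 * pi * phase)),
         -0.5 * (1 - cos(4 * pi * (phase - 0.5))))
}

#' Peak open-circuit voltage of a simulated sensor
#'
#' Composes the calibrated per-axis responses multiplicatively relative to
#' the reference condition (20 x 20 x 5 mm, 5 N, 1 Hz): linear force
#' response at 0.376 V/N, near-constant frequency response (0.02 V ripple),
#' monotone area scaling and a thickness response that saturates at 2 mm.
#'
#' @param spec A [sensor_spec()].
#' @param exc An [excitation()].
#' @param cal A calibration table from [default_calibration()].
#' @param extrapolate Allow inputs outside the anchored ranges (clamped, or
#'   slope-extended for force).
#' @return Peak open-circuit voltage in V (single unit).
#' @export
peak_voltage <- function(spec, exc, cal = default_calibration(), extrapolate = FALSE) {
  stopifnot(inherits(spec, "sensor_spec"), inherits(exc, "excitation"),
            inherits(cal, "teng_calibration"))
  v_f <- cal_interp(cal$force_v, exc$force_n, "force_n", extrapolate, slope_extend = TRUE)
  g_freq <- cal_interp(cal$freq_v, exc$freq_hz, "freq_hz", extrapolate)
  g_area <- cal_interp(cal$area_v, spec$side_mm, "side_mm", extrapolate)
  g_thk <- cal_interp(cal$thick, spec$thickness_mm, "thickness_mm", extrapolate)
  max(v_f, 0) * g_freq * g_area * g_thk
}

#' Peak short-circuit current of a simulated sensor
#'
#' Current rises monotonically with pressing frequency (more charge
#' transferred per unit time), anchored at 1.88 nA (1 Hz) and 9.66 nA
#' (5 Hz) for the reference sensor at 5 N, and scales with force, area and
#' thickness factors as for voltage.
#'
#' @inheritParams peak_voltage
#' @return Peak short-circuit current in nA (single unit).
#' @export
peak_current <- function(spec, exc, cal = default_calibration(), extrapolate = FALSE) {
  stopifnot(inherits(spec, "sensor_spec"), inherits(exc, "excitation"),
            inherits(cal, "teng_calibration"))
  i_f <- cal_interp(cal$freq_i, exc$freq_hz, "freq_hz", extrapolate)
  g_force <- exc$force_n / 5  # linear force scaling relative to the 5 N reference
  g_area <- cal_interp(cal$area_i, spec$side_mm, "side_mm", extrapolate)
  g_thk <- cal_interp(cal$thick, spec$thickness_mm, "thickness_mm", extrapolate)
  i_f * g_force * g_area * g_thk
}

#' Simulate a periodic press-release waveform
#'
#' Repeats the biphasic [cycle_shape()] template for `n_cycles` cycles and
#' scales it to the calibrated peak ([peak_voltage()] or [peak_current()]).
#' Deterministic for fixed inputs.
#'
#' @inheritParams peak_voltage
#' @param kind `"voc"` for open-circuit voltage, `"isc"` for short-circuit
#'   current.
#' @return A [waveform()] of length `round(n_cycles * rate_hz / freq_hz)`.
#' @examples
#' w <- simulate_waveform(sensor_spec(), excitation(5, 1, n_cycles = 3))
#' max(abs(w$samples))
#' @export
simulate_waveform <- function(spec, exc, cal = default_calibration(),
                              kind = c("voc", "isc"), extrapolate = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(exc, "excitation"))
  if (exc$rate_hz < 20 * exc$freq_hz) {
    stop("sampling rate too low for the pressing frequency (aliasing)", call. = FALSE)
  }
  peak <- if (kind == "voc") peak_voltage(spec, exc, cal, extrapolate)
          else peak_current(spec, exc, cal, extrapolate)
  n <- round(exc$n_cycles * exc$rate_hz / exc$freq_hz)
  t <- (seq_len(n) - 1) / exc$rate_hz
  ph <- (t * exc$freq_hz) %% 1
  waveform(peak * cycle_shape(ph), rate = exc$rate_hz,
           units = if (kind == "voc") "V" else "nA", kind = kind)
}

#' Combine waveforms of identical sensor units
#'
#' Ideal superposition of electrically combined units: a series chain adds
#' voltages (currents unchanged), a parallel bank adds currents (voltages
#' unchanged). Consequently the series voltage amplitude exceeds the
#' parallel voltage amplitude for identical units.
#'
#' @param waveforms List of [waveform()] objects with equal sampling rates,
#'   lengths and units.
#' @param mode `"series"` or `"parallel"`.
#' @return A combined [waveform()].
#' @export
combine_sensors <- function(waveforms, mode = c("series", "parallel")) {
  mode <- match.arg(mode)
  stopifnot(length(waveforms) >= 1, all(vapply(waveforms, inherits, TRUE, "waveform")))
  rates <- vapply(waveforms, function(w) w$rate, 0)
  lens <- vapply(waveforms, function(w) length(w$samples), 0L)
  units <- vapply(waveforms, function(w) w$units, "")
  if (length(unique(rates)) != 1L) stop("sampling rates differ", call. = FALSE)
  if (length(unique(lens)) != 1L) stop("waveform lengths differ", call. = FALSE)
  if (length(unique(units)) != 1L) stop("units differ", call. = FALSE)
  mat <- vapply(waveforms, function(w) w$samples, numeric(lens[1]))
  mat <- matrix(mat, nrow = lens[1])
  is_voltage <- units[1] == "V"
  adds <- (mode == "series" && is_voltage) || (mode == "parallel" && !is_voltage)
  out <- if (adds) rowSums(mat) else rowMeans(mat)
  waveform(out, rate = rates[1], units = units[1], kind = waveforms[[1]]$kind)
}

#' Thevenin load circuit for a sensor used as a power supply
#'
#' @param r_internal Internal (source) resistance in Ohm.
#' @param v_source_peak Peak source voltage in V. If `NULL`, supply
#'   `p_matched` instead and the source peak is solved from the
#'   matched-load power `p_matched = v^2 / (4 r_internal)`.
#' @param p_matched Optional maximum (matched-load) power in W.
#' @return An object of class `load_circuit`.
#' @export
load_circuit <- function(r_internal, v_source_peak = NULL, p_matched = NULL) {
  stop_if_not_scalar_num(r_internal, "r_internal", lower = .Machine$double.eps)
  if (is.null(v_source_peak)) {
    if (is.null(p_matched)) stop("supply `v_source_peak` or `p_matched`", call. = FALSE)
    stop_if_not_scalar_num(p_matched, "p_matched", lower = 0)
    v_source_peak <- sqrt(4 * p_matched * r_internal)
  }
  stop_if_not_scalar_num(v_source_peak, "v_source_peak", lower = 0)
  structure(list(r_internal = r_internal, v_source_peak = v_source_peak),
            class = "load_circuit")
}

#' Load-resistance sweep: delivered voltage and power
#'
#' For a Thevenin source with internal resistance `R_i`, the load sees
#' `V(R) = V_p R / (R + R_i)` and receives `P(R) = V_p^2 R / (R + R_i)^2`.
#' `V(R)` rises monotonically towards `V_p`; `P(R)` peaks exactly at the
#' matched load `R = R_i`.
#'
#' @param circ A [load_circuit()].
#' @param r_values Positive load resistances in Ohm.
#' @return A data frame with columns `r_ohm`, `v`, `p_w`.
#' @export
load_sweep <- function(circ, r_values) {
  stopifnot(inherits(circ, "load_circuit"))
  if (!is.numeric(r_values) || any(!is.finite(r_values)) || any(r_values <= 0)) {
    stop("`r_values` must be positive and finite", call. = FALSE)
  }
  v <- circ$v_source_peak * r_values / (r_values + circ$r_internal)
  p <- circ$v_source_peak^2 * r_values / (r_values + circ$r_internal)^2
  data.frame(r_ohm = r_values, v = v, p_w = p)
}

#' Durability amplitude decay
#'
#' Linear amplitude attenuation over repeated press-release cycles,
#' interpolated between the calibration endpoints (scale 1 at cycle 0 down
#' to 1.38/1.40 at cycle 2000) and clamped beyond.
#'
#' @param cycle_index Non-negative cycle count(s).
#' @param cal Calibration table.
#' @return Amplitude scale factor(s) in (0, 1\].
#' @export
durability_decay <- function(cycle_index, cal = default_calibration()) {
  stopifnot(inherits(cal, "teng_calibration"))
  if (!is.numeric(cycle_index) || any(!is.finite(cycle_index)) || any(cycle_index < 0)) {
    stop("`cycle_index` must be non-negative", call. = FALSE)
  }
  stats::approx(cal$durability$cycle, cal$durability$scale,
                xout = cycle_index, rule = 2)$y
}
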