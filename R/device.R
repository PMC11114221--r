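#' Organic synaptic device parameters
#'
#' Bundles the conductance bounds and nonlinearity constants of the
#' saturating-exponential long-term potentiation/depression (LTP/LTD) model.
#' Potentiation follows \eqn{G_{LTP}(P) = B_P [1 - e^{-P/A_P}] + G_{min}} and
#' depression the boundary-consistent mirror
#' \eqn{G_{LTD}(P) = G_{max} - B_D [1 - e^{-P/A_D}]}, where each \eqn{B} is
#' tied to its \eqn{A} so that the curve spans exactly
#' \eqn{[G_{min}, G_{max}]} over \eqn{P \in [0, P_{max}]} (see [b_coeff()]).
#' Large \eqn{|A|} means near-linear conductance updates; the defaults
#' describe a low-nonlinearity (MoO3-modified-like) device.
#'
#' @param g_min minimum channel conductance (uS); must be positive.
#' @param g_max maximum channel conductance (uS); must exceed `g_min`.
#' @param p_max number of pulses needed to traverse the full conductance
#'   range (integer >= 1).
#' @param a_p potentiation nonlinearity constant (pulses, nonzero; sign free).
#' @param a_d depression nonlinearity constant (pulses, nonzero; sign free).
#' @return An object of class `device_params`.
#' @examples
#' d <- device_params()
#' g_ltp(d, 0:5)
#' @export
device_params <- function(g_min = 100, g_max = 170, p_max = 100,
                          a_p = 300, a_d = 300) {
  stopifnot(is.numeric(g_min), is.numeric(g_max), is.numeric(p_max),
            is.numeric(a_p), is.numeric(a_d))
  if (!is.finite(g_min) || !is.finite(g_max) || g_min <= 0 || g_max <= g_min)
    stop("device_params: need g_max > g_min > 0")
  if (!is.finite(p_max) || p_max < 1 || p_max != round(p_max))
    stop("device_params: p_max must be an integer >= 1")
  if (!is.finite(a_p) || a_p == 0 || !is.finite(a_d) || a_d == 0)
    stop("device_params: nonlinearity constants must be finite and nonzero")
  structure(list(g_min = g_min, g_max = g_max, p_max = as.integer(p_max),
                 a_p = a_p, a_d = a_d),
            class = "device_params")
}

#' @export
print.device_params <- function(x, ...) {
  cat(sprintf("Synaptic device: G in [%.4g, %.4g] uS, P_max = %d, A_P = %.4g, A_D = %.4g\n",
              x$g_min, x$g_max, x$p_max, x$a_p, x$a_d))
  invisible(x)
}

#' Presynaptic pulse protocol
#'
#' The pulse train applied per LTP or LTD phase. Defaults follow the
#' characterization protocol: +/-2.5 V pulses, 100 ms duration, 5 Hz,
#' 100 pulses per phase.
#'
#' @param amplitude presynaptic voltage (V, signed).
#' @param duration pulse width (ms), positive.
#' @param frequency pulse rate (Hz), positive; pulses must not overlap, i.e.
#'   `duration <= 1000/frequency`.
#' @param n_pulses pulses per phase (integer >= 1).
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(amplitude = 2.5, duration = 100, frequency = 5,
                           n_pulses = 100) {
  if (duration <= 0 || frequency <= 0 || n_pulses < 1)
    stop("pulse_protocol: duration, frequency must be positive; n_pulses >= 1")
  if (duration > 1000 / frequency)
    stop("pulse_protocol: pulses overlap (duration > 1000/frequency)")
  structure(list(amplitude = amplitude, duration = duration,
                 frequency = frequency, n_pulses = as.integer(n_pulses)),
            class = "pulse_protocol")
}

#' Span-matching fitting constant B
#'
#' \eqn{B = (G_{max} - G_{min}) / [1 - e^{-P_{max}/A}]}. This is the unique
#' constant for which the saturating-exponential curve with nonlinearity `a`
#' spans exactly `[g_min, g_max]` over `p` in `[0, p_max]`. For `a < 0`
#' (concave-up curves) `B` is negative and the span condition still holds.
#'
#' @param params a [device_params()] object.
#' @param a nonlinearity constant (pulses); defaults to `params$a_p`.
#' @return The fitting constant B (uS).
#' @export
b_coeff <- function(params, a = params$a_p) {
  stopifnot(inherits(params, "device_params"))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a == 0)
    stop("b_coeff: 'a' must be a single finite nonzero number")
  (params$g_max - params$g_min) / (1 - exp(-params$p_max / a))
}

#' LTP conductance after p potentiation pulses
#'
#' @param params a [device_params()] object.
#' @param p pulse count(s) in `[0, p_max]` (need not be integer).
#' @return Conductance (uS); `g_min` at `p = 0`, `g_max` at `p = p_max`,
#'   strictly increasing in between.
#' @export
g_ltp <- function(params, p) {
  stopifnot(inherits(params, "device_params"))
  if (any(!is.finite(p)) || any(p < 0) || any(p > params$p_max))
    stop("g_ltp: p outside [0, p_max]")
  b_coeff(params, params$a_p) * (1 - exp(-p / params$a_p)) + params$g_min
}

#' LTD conductance after p depression pulses
#'
#' Boundary-consistent depression curve
#' \eqn{G_{LTD}(P) = G_{max} - B_D [1 - e^{-P/A_D}]}: starts at `g_max`,
#' ends at `g_min` after `p_max` pulses. With `a_d = a_p` it is the exact
#' mirror `g_min + g_max - g_ltp(p)`.
#'
#' @inheritParams g_ltp
#' @return Conductance (uS), strictly decreasing in `p`.
#' @export
g_ltd <- function(params, p) {
  stopifnot(inherits(params, "device_params"))
  if (any(!is.finite(p)) || any(p < 0) || any(p > params$p_max))
    stop("g_ltd: p outside [0, p_max]")
  params$g_max - b_coeff(params, params$a_d) * (1 - exp(-p / params$a_d))
}

#' Inverse of the LTP curve
#'
#' Pulse position at which the LTP curve passes through conductance `g`.
#' Used by the device-aware trainer to step a synapse along the curve from
#' its current state.
#'
#' @param params a [device_params()] object.
#' @param g conductance(s) in `[g_min, g_max]`.
#' @return Fractional pulse position(s) in `[0, p_max]`.
#' @export
ltp_pulse_position <- function(params, g) {
  stopifnot(inherits(params, "device_params"))
  if (any(g < params$g_min - 1e-9) || any(g > params$g_max + 1e-9))
    stop("ltp_pulse_position: conductance outside [g_min, g_max]")
  B <- b_coeff(params, params$a_p)
  frac <- pmin(pmax((g - params$g_min) / B, 0), 1 - 1e-12)
  -params$a_p * log(1 - frac)
}

#' Simulate one LTP/LTD cycle
#'
#' Applies `n_pulses` potentiation pulses followed by `n_pulses` depression
#' pulses and records the conductance after each pulse, with optional
#' additive i.i.d. Gaussian measurement noise. Noisy values are clamped to
#' `[g_min - 3 noise_sd, g_max + 3 noise_sd]`. Deterministic given `seed`.
#'
#' @param params a [device_params()] object.
#' @param protocol a [pulse_protocol()]; `n_pulses` must not exceed `p_max`.
#' @param noise_sd measurement noise SD (uS, >= 0).
#' @param seed integer RNG seed.
#' @return A `conductance_trace`: data frame with columns `phase`
#'   (`"potentiation"`/`"depression"`), `pulse` (1-based within phase) and
#'   `conductance_uS`.
#' @export
simulate_ltpd_cycle <- function(params, protocol = pulse_protocol(),
                                noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params, "device_params"), inherits(protocol, "pulse_protocol"))
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("simulate_ltpd_cycle: noise_sd must be >= 0")
  n <- protocol$n_pulses
  if (n > params$p_max)
    stop("simulate_ltpd_cycle: protocol n_pulses exceeds device p_max")
  g <- c(g_ltp(params, seq_len(n)), g_ltd(params, seq_len(n)))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    g <- g + stats::rnorm(2L * n, 0, noise_sd)
    g <- pmin(pmax(g, params$g_min - 3 * noise_sd), params$g_max + 3 * noise_sd)
  }
  structure(data.frame(
    phase = rep(c("potentiation", "depression"), each = n),
    pulse = c(seq_len(n), seq_len(n)),
    conductance_uS = g,
    stringsAsFactors = FALSE
  ), class = c("conductance_trace", "data.frame"))
}

# residual sum of squares of one phase against the curve with curvature u = 1/a;
# endpoints (lo,hi) fixed, u = 0 is the straight-line limit
.phase_rss <- function(u, p, g, p_max, lo, hi) {
  span <- hi - lo
  f <- if (abs(u) < 1e-12) p / p_max else (1 - exp(-p * u)) / (1 - exp(-p_max * u))
  sum((g - (lo + span * f))^2)
}

.fit_phase_a <- function(p, g, p_max, lo, hi, interval = c(-2, 2)) {
  opt <- stats::optimize(.phase_rss, interval = interval, p = p, g = g,
                         p_max = p_max, lo = lo, hi = hi, tol = 1e-12)
  u <- opt$minimum
  a <- if (abs(u) < 1e-9) sign(u + (u == 0)) * 1e9 else 1 / u
  list(a = a, rss = opt$objective)
}

#' Fit LTP/LTD nonlinearity constants from a conductance trace
#'
#' Recovers `a_p` and `a_d` by least squares on each phase, with the span
#' constraint built in: endpoints are taken from the trace extremes and the
#' fitting constant B is tied to the curvature through [b_coeff()], so only
#' one parameter per phase is free. The search is over `u = 1/a`, making the
#' straight-line limit (`|a| -> Inf`) an interior point. Issues a warning
#' (not an error) when a phase is not monotone-dominant, as expected for
#' traces overwhelmed by noise.
#'
#' @param trace a `conductance_trace` from [simulate_ltpd_cycle()] or read
#'   from file; needs >= 5 points per phase.
#' @return A [device_params()] object with fitted `a_p`, `a_d` and endpoint
#'   estimates, plus attribute `"rss"` (per-phase residual sums of squares).
#' @export
fit_nonlinearity <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("phase", "pulse", "conductance_uS") %in% names(trace)))
  pot <- trace[trace$phase == "potentiation", ]
  dep <- trace[trace$phase == "depression", ]
  if (nrow(pot) < 5 || nrow(dep) < 5)
    stop("fit_nonlinearity: need >= 5 points per phase")
  g_lo <- min(trace$conductance_uS)
  g_hi <- max(trace$conductance_uS)
  if (g_hi <= g_lo) stop("fit_nonlinearity: degenerate trace (no span)")
  p_max <- max(trace$pulse)
  for (ph in list(pot = pot, dep = dep)) {
    d <- diff(ph$conductance_uS[order(ph$pulse)])
    if (abs(sum(sign(d))) < length(d) / 2)
      warning("fit_nonlinearity: phase not monotone-dominant; fit may be poor")
  }
  fp <- .fit_phase_a(pot$pulse, pot$conductance_uS, p_max, g_lo, g_hi)
  # depression measured from g_hi downward: mirror onto an increasing curve
  fd <- .fit_phase_a(dep$pulse, g_lo + g_hi - dep$conductance_uS, p_max, g_lo, g_hi)
  out <- device_params(g_min = g_lo, g_max = g_hi, p_max = p_max,
                       a_p = fp$a, a_d = fd$a)
  attr(out, "rss") <- c(potentiation = fp$rss, depression = fd$rss)
  out
}

#' Exponential EPSC relaxation
#'
#' Single-exponential decay of an excitatory postsynaptic conductance
#' transient toward its resting level: `g0 + delta_g * exp(-t/tau)`.
#' Retention time constants of roughly 700 s (modified device) versus 5 s
#' (pristine device) reproduce the qualitative memory contrast.
#'
#' @param g0 resting conductance (uS).
#' @param delta_g transient amplitude just after the pulse (uS).
#' @param tau relaxation time constant (s, > 0).
#' @param t elapsed time(s) (s, >= 0).
#' @return Conductance at time `t` (uS).
#' @export
epsc_relaxation <- function(g0, delta_g, tau = 700, t = 0) {
  if (!is.numeric(tau) || tau <= 0) stop("epsc_relaxation: tau must be > 0")
  if (any(t < 0)) stop("epsc_relaxation: t must be >= 0")
  g0 + delta_g * exp(-t / tau)
}

#' Paired-pulse facilitation index
#'
#' Percent amplitude of the second of two rapidly evoked EPSCs relative to
#' the first: `100 * a2 / a1`. Values above 100 indicate facilitation.
#'
#' @param a1 first EPSC amplitude (> 0).
#' @param a2 second EPSC amplitude.
#' @return PPF index (percent).
#' @export
ppf_index <- function(a1, a2) {
  if (any(!is.numeric(a1)) || any(a1 <= 0)) stop("ppf_index: a1 must be > 0")
  100 * a2 / a1
}
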