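#' Calcium sensor filters
#'
#' The regulation error signal is built from a three-way decomposition of
#' intracellular calcium. Three first-order low-passes with increasing time
#' constants (tau_F < tau_S < tau_D) track the calcium signal; the rectified
#' differences `|c_fast - c_slow|` (spike-band magnitude) and
#' `|c_slow - c_dc|` (slow-wave magnitude) are themselves low-pass averaged
#' with tau_avg to give stationary readouts. The DC readout is `c_dc`
#' directly.
#'
#' `update_filters()` advances the filter states by one step given the
#' instantaneous calcium value; it is the R reference implementation of the
#' update embedded in the compiled simulator.
#'
#' @param filters named numeric vector
#'   (c_fast, c_slow, c_dc, a_fast, a_slow).
#' @param Ca intracellular calcium (uM).
#' @param dt step (ms), > 0.
#' @param const constants from [dynamics_constants()].
#' @return Updated filter vector.
#' @export
update_filters <- function(filters, Ca, dt, const = dynamics_constants()) {
  stopifnot(dt > 0)
  aF <- 1 - exp(-dt / const$tau_fast_ms)
  aS <- 1 - exp(-dt / const$tau_slow_ms)
  aD <- 1 - exp(-dt / const$tau_dc_ms)
  aA <- 1 - exp(-dt / const$tau_avg_ms)
  filters["c_fast"] <- filters["c_fast"] + aF * (Ca - filters["c_fast"])
  filters["c_slow"] <- filters["c_slow"] + aS * (Ca - filters["c_slow"])
  filters["c_dc"]   <- filters["c_dc"]   + aD * (Ca - filters["c_dc"])
  filters["a_fast"] <- filters["a_fast"] +
    aA * (abs(filters["c_fast"] - filters["c_slow"]) - filters["a_fast"])
  filters["a_slow"] <- filters["a_slow"] +
    aA * (abs(filters["c_slow"] - filters["c_dc"]) - filters["a_slow"])
  filters
}

#' Sensor readouts from filter states
#'
#' @param filters filter vector as in [update_filters()].
#' @return Named vector `(F, S, D)` in uM: averaged spike-band magnitude,
#'   averaged slow-wave magnitude, and DC calcium.
#' @export
sensor_readouts <- function(filters) {
  c(F = unname(filters["a_fast"]),
    S = unname(filters["a_slow"]),
    D = unname(filters["c_dc"]))
}

#' Sensor errors
#'
#' Componentwise readout minus target (uM). Positive error means activity
#' (calcium) above target.
#'
#' @param readouts named `(F, S, D)` readouts.
#' @param targets named `(F, S, D)` setpoints, strictly positive.
#' @return Named error vector `(F, S, D)`.
#' @export
sensor_errors <- function(readouts, targets) {
  stopifnot(all(targets > 0))
  setNames(as.numeric(readouts[c("F", "S", "D")] - targets[c("F", "S", "D")]),
           c("F", "S", "D"))
}

#' Calibrate sensor targets from a reference trace
#'
#' Targets are the time-averaged sensor readouts over a stable bursting
#' window at the end of the trace. The window must classify as bursting and
#' contain at least 10 burst periods; calibrating on a silent or unstable
#' trace is an error.
#'
#' @param trace a [simulate()] trace recorded with sensor readouts.
#' @param window_s averaging window at the end of the trace (s).
#' @return Named targets `(F, S, D)` in uM.
#' @export
calibrate_targets <- function(trace, window_s = 60) {
  t_end <- max(trace$time_p)
  w0 <- t_end - window_s
  cls <- classify_window(trace, start = w0, end = t_end)
  if (cls$state != "bursting")
    stop("calibration requires a stable bursting reference window; got ",
         cls$state)
  if (is.na(cls$n_bursts) || cls$n_bursts < 10)
    stop("calibration window must contain at least 10 bursts")
  keep <- trace$time_p >= w0
  ro <- trace$sensor_errors[keep, , drop = FALSE]
  # stored errors are relative to the run's configured targets
  tg <- trace$regulation$targets
  targets <- colMeans(ro) + tg
  if (any(targets <= 0)) stop("calibrated targets must be strictly positive")
  setNames(as.numeric(targets), c("F", "S", "D"))
}
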