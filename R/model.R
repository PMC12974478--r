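#' Intrinsic parameter state
#'
#' The regulated parameter vector of one model neuron: seven maximal
#' conductances (uS, strictly positive), a fixed unregulated leak
#' conductance, and eleven half-(in)activation shifts (mV, deviations from
#' the baseline half-voltages in [channel_table()]; all-zero shifts means the
#' baseline curves exactly).
#'
#' @param gmax numeric length-7 vector, named or in order
#'   Na, CaT, CaS, A, KCa, Kd, H.
#' @param half_shifts numeric length-11 vector, order
#'   Na_act, Na_inact, CaT_act, CaT_inact, CaS_act, CaS_inact, A_act,
#'   A_inact, KCa_act, Kd_act, H_act.
#' @param leak_g leak conductance (uS), fixed.
#' @return An object of class `intrinsic_state`.
#' @export
intrinsic_state <- function(gmax, half_shifts = rep(0, 11), leak_g = 0.02) {
  gmax <- as.numeric(gmax)
  half_shifts <- as.numeric(half_shifts)
  if (length(gmax) != 7) stop("gmax must have length 7")
  if (length(half_shifts) != 11) stop("half_shifts must have length 11")
  if (any(!is.finite(gmax)) || any(gmax <= 0))
    stop("all maximal conductances must be finite and strictly positive")
  if (any(!is.finite(half_shifts))) stop("half_shifts must be finite")
  if (!is.finite(leak_g) || leak_g < 0) stop("leak_g must be non-negative")
  structure(list(gmax = setNames(gmax, .ds_channels),
                 half_shifts = setNames(half_shifts, .ds_curves),
                 leak_g = leak_g),
            class = "intrinsic_state")
}

#' @export
print.intrinsic_state <- function(x, ...) {
  cat("<intrinsic_state>\n  gmax (uS):\n")
  print(round(x$gmax, 5))
  cat("  half shifts (mV):\n")
  print(round(x$half_shifts, 3))
  cat("  leak_g:", x$leak_g, "uS\n")
  invisible(x)
}

#' Environment (extracellular condition) for one epoch
#'
#' @param E_K potassium reversal potential (mV).
#' @param E_leak leak reversal potential (mV).
#' @param epoch_label one of `"baseline"`, `"perturbation"`, `"wash"`.
#' @return An `environment_state` object.
#' @export
environment_state <- function(E_K = -80, E_leak = -50,
                              epoch_label = c("baseline", "perturbation", "wash")) {
  epoch_label <- match.arg(epoch_label)
  structure(list(E_K = E_K, E_leak = E_leak, epoch_label = epoch_label),
            class = "environment_state")
}

# Reversal potentials of the baseline and high-potassium conditions.
# Elevated extracellular potassium shifts E_K from -80 to -55 mV and, because
# the leak is partly a potassium conductance, E_leak from -50 to -32 mV.
.ds_env <- list(baseline = c(E_K = -80, E_leak = -50),
                perturbation = c(E_K = -55, E_leak = -32),
                wash = c(E_K = -80, E_leak = -50))

#' Initial dynamic state at a holding voltage
#'
#' Gates at their steady-state values for `V` (and resting calcium), calcium
#' at its resting value, sensor filters initialized to the calcium value with
#' zero band magnitudes.
#'
#' @param V holding voltage (mV).
#' @param Ca initial intracellular calcium (uM).
#' @param const constants from [dynamics_constants()].
#' @param targets optional named `(F, S, D)` sensor setpoints. When given,
#'   the slow sensor filters start at their operating point (band averages
#'   at F and S, DC at D) instead of at the instantaneous calcium, so a
#'   regulated run does not begin with a spurious sensor warm-up error (the
#'   DC filter alone takes a minute to converge from cold).
#' @return A `dynamic_state` list (V, gates, Ca, filters, t).
#' @export
init_dynamic_state <- function(V = -50, Ca = NULL, const = dynamics_constants(),
                               targets = NULL) {
  if (is.null(Ca)) Ca <- const$ca_rest
  gates <- vapply(1:11, function(g) gate_inf_r(g, V), numeric(1))
  gates[9] <- gates[9] * Ca / (Ca + const$kca_half_uM)
  filters <- c(c_fast = Ca, c_slow = Ca, c_dc = Ca, a_fast = 0, a_slow = 0)
  if (!is.null(targets)) {
    filters["c_dc"] <- unname(targets["D"])
    filters["a_fast"] <- unname(targets["F"])
    filters["a_slow"] <- unname(targets["S"])
  }
  structure(list(V = V, gates = gates, Ca = Ca, filters = filters, t = 0),
            class = "dynamic_state")
}
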