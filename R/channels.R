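#' Channel roster of the seven-current burster
#'
#' Returns the definition table of the model's seven voltage-gated currents:
#' activation exponent `p`, whether the channel carries an inactivation gate
#' (exponent `q = 1`), the baseline half-(in)activation voltages (mV), the
#' fixed sigmoid slopes (mV), and the reversal mode. Four channels (Na, CaT,
#' CaS, A) inactivate, so the model exposes 11 shiftable half-voltage curves
#' in total. Baselines are the canonical values of the crustacean
#' stomatogastric seven-conductance lineage; regulation shifts them but never
#' touches slopes or gate time constants.
#'
#' The H current activates on hyperpolarization: its "activation" curve is a
#' decreasing sigmoid (the `inactivation` functional form in
#' [gate_steady_state()]).
#'
#' @return A data.frame with one row per channel.
#' @export
channel_table <- function() {
  data.frame(
    name = .ds_channels,
    p = c(3L, 3L, 3L, 3L, 4L, 4L, 1L),
    has_inactivation = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    v_half_act = c(-25.5, -27.1, -33.0, -27.2, -28.3, -12.3, -70.0),
    v_half_inact = c(-48.9, -32.1, -60.0, -56.9, NA, NA, NA),
    slope_act = c(5.29, 7.2, 8.1, 8.7, 12.6, 11.8, 6.0),
    slope_inact = c(5.18, 5.5, 6.2, 4.9, NA, NA, NA),
    act_decreasing = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    reversal_mode = c("fixed", "calcium-nernst", "calcium-nernst",
                      "E_K", "E_K", "E_K", "fixed"),
    calcium_coupling = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Fixed biophysical and sensor constants
#'
#' Calibration constants of the model family: membrane capacitance,
#' intracellular calcium dynamics (`tau_ca_ms`, `f_ca`, `ca_rest`), the
#' calcium Nernst setup (fixed extracellular calcium, temperature), fixed
#' reversal potentials, the KCa calcium half-saturation, spike-detector
#' contract values, and the calcium-sensor filter time constants
#' (tau_F < tau_S < tau_D < tau_avg, enforced here).
#'
#' @param ... named overrides of individual constants.
#' @return Named list of constants.
#' @export
dynamics_constants <- function(...) {
  tK <- 283
  const <- list(
    C_nF = 0.628,
    tau_ca_ms = 200,
    f_ca = 14.96,          # uM per nA of calcium current
    ca_rest = 0.05,        # uM
    ca_ext_uM = 3000,      # 3 mM fixed extracellular calcium
    temperature_K = tK,
    nernst_ca_mV = 1e3 * 8.314462618 * tK / (2 * 96485.33212),
    E_Na = 50,
    E_H = -20,
    kca_half_uM = 3,
    spike_threshold_mV = -20,
    spike_min_sep_ms = 2,
    tau_fast_ms = 50,
    tau_slow_ms = 1000,
    tau_dc_ms = 60000,
    tau_avg_ms = 5000
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(const)) stop("unknown constant: ", nm)
    const[[nm]] <- over[[nm]]
  }
  taus <- unlist(const[c("tau_fast_ms", "tau_slow_ms", "tau_dc_ms")])
  if (any(diff(taus) <= 0))
    stop("sensor filter time constants must satisfy tau_F < tau_S < tau_D")
  if (const$tau_avg_ms <= const$tau_slow_ms)
    stop("tau_avg must exceed tau_S so band magnitudes average over cycles")
  const
}

#' Steady-state value of a gating variable
#'
#' Boltzmann sigmoid with a shiftable half-voltage. Activation form
#' `1/(1 + exp(-(V - Vh)/s))`, inactivation form `1/(1 + exp((V - Vh)/s))`,
#' with `Vh = v_half_base + shift`. For the calcium-activated potassium
#' current the voltage sigmoid is multiplied by `Ca/(Ca + K_half)`.
#'
#' @param V membrane voltage (mV); must be finite.
#' @param v_half_base baseline half-voltage (mV).
#' @param shift regulated half-voltage shift (mV).
#' @param slope sigmoid slope (mV), strictly positive.
#' @param kind `"activation"` or `"inactivation"`.
#' @param Ca intracellular calcium (uM) for the KCa factor, or `NULL`.
#' @param kca_half calcium half-saturation (uM).
#' @return Value in `[0, 1]`.
#' @export
gate_steady_state <- function(V, v_half_base, shift = 0, slope,
                              kind = c("activation", "inactivation"),
                              Ca = NULL, kca_half = 3) {
  kind <- match.arg(kind)
  if (any(!is.finite(V))) stop("V must be finite")
  stopifnot(slope > 0)
  x <- (V - (v_half_base + shift)) / slope
  val <- if (kind == "activation") 1 / (1 + exp(-x)) else 1 / (1 + exp(x))
  if (!is.null(Ca)) val <- val * Ca / (Ca + kca_half)
  val
}

#' Instantaneous ionic current
#'
#' Standard Hodgkin-Huxley product form `gmax * m^p * h^q * (V - E_rev)`,
#' outward positive.
#'
#' @param gmax maximal conductance (uS), non-negative.
#' @param m,h activation / inactivation gate values in `[0, 1]`.
#' @param p,q gate exponents (q = 0 when the channel has no inactivation).
#' @param V membrane voltage (mV).
#' @param E_rev reversal potential (mV).
#' @return Current in nA.
#' @export
ionic_current <- function(gmax, m, h = 1, p, q = 0, V, E_rev) {
  stopifnot(gmax >= 0)
  gmax * m^p * (if (q > 0) h^q else 1) * (V - E_rev)
}

#' Nernst reversal potential
#'
#' `E = (R T / z F) ln(conc_out / conc_in)` in mV. Used at every integration
#' step to compute the calcium reversal from instantaneous intracellular
#' calcium against a fixed extracellular concentration.
#'
#' @param conc_in,conc_out ion concentrations (same units), strictly positive.
#' @param valence ionic charge.
#' @param temperature_K absolute temperature (K).
#' @return Reversal potential in mV.
#' @export
nernst_reversal <- function(conc_in, conc_out, valence, temperature_K = 283) {
  if (any(conc_in <= 0) || any(conc_out <= 0))
    stop("concentrations must be strictly positive")
  1e3 * 8.314462618 * temperature_K / (valence * 96485.33212) *
    log(conc_out / conc_in)
}

# R-side mirrors of the compiled gate kinetics, indexed like the gate vector
# (mNa hNa mCaT hCaT mCaS hCaS mA hA mKCa mKd mH). Used as the independent
# reference path in tests; the compiled loop is the production path.
gate_inf_r <- function(g, v) {
  sig <- function(x) 1 / (1 + exp(x))
  switch(g,
    sig(-(v + 25.5) / 5.29), sig((v + 48.9) / 5.18),
    sig(-(v + 27.1) / 7.2),  sig((v + 32.1) / 5.5),
    sig(-(v + 33.0) / 8.1),  sig((v + 60.0) / 6.2),
    sig(-(v + 27.2) / 8.7),  sig((v + 56.9) / 4.9),
    sig(-(v + 28.3) / 12.6), sig(-(v + 12.3) / 11.8),
    sig((v + 70.0) / 6.0))
}

gate_tau_r <- function(g, v) {
  sig <- function(x) 1 / (1 + exp(x))
  switch(g,
    1.32 - 1.26 * sig(-(v + 120) / 25),
    (0.67 * sig(-(v + 62.9) / 10)) * (1.5 + sig((v + 34.9) / 3.6)),
    21.7 - 21.3 * sig(-(v + 68.1) / 20.5),
    105 - 89.8 * sig(-(v + 55) / 16.9),
    1.4 + 7 / (exp((v + 27) / 10) + exp(-(v + 70) / 13)),
    60 + 150 / (exp((v + 55) / 9) + exp(-(v + 65) / 16)),
    11.6 - 10.4 * sig(-(v + 32.9) / 15.2),
    38.6 - 29.2 * sig(-(v + 38.9) / 26.5),
    90.3 - 75.1 * sig(-(v + 46) / 22.7),
    7.2 - 6.4 * sig(-(v + 28.3) / 19.2),
    272 + 1499 * sig(-(v + 42.2) / 8.73))
}
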