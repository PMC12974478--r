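#' Default regulation weight matrices
#'
#' Signed couplings from the three sensor errors (F, S, D) to the per-channel
#' conductance drive (7 x 3) and per-curve half-shift drive (11 x 3).
#' Entries are signed O(1) constants (half-shift rows additionally carry the
#' gain `halfshift_gain_mV`), chosen by physiological role and polarity and
#' tuned once during calibration of the reference burster:
#'
#' * spike-band error drives the spike machinery (Na down when calcium is
#'   above target, Kd and A up),
#' * slow-wave error drives the burst oscillator (CaT, CaS, H down when
#'   above target, KCa up),
#' * DC error drives the overall inward/outward balance.
#'
#' The rows are chosen so the 7 x 3 map has full column rank: the closed
#' loop can only rest where all three sensor errors vanish, not merely a
#' weighted sum. Each half-voltage curve inherits its channel's error
#' combination, signed so that a drive which would shrink the current also
#' shifts the curve in the current-reducing direction (activation rightward,
#' inactivation leftward; mirrored for the hyperpolarization-activated H).
#'
#' Regulation consumes target-normalized (relative) errors, so conductance
#' weights are O(1) and half-shift weights are in mV per unit relative
#' error.
#'
#' @param halfshift_gain_mV magnitude of half-shift weight entries (mV).
#' @return List with matrices `w_g` (7 x 3) and `w_half` (11 x 3).
#' @export
default_weights <- function(halfshift_gain_mV = 0.05) {
  w_g <- matrix(c(
    #   F   S   D
      0.5,  0,  1,   # Na
        0,  1,  1,   # CaT
        0,  1,  1,   # CaS
        0,  0, -1,   # A
        0,  0, -1,   # KCa
        0,  0, -1,   # Kd
        0,  1,  0),  # H
    nrow = 7, byrow = TRUE,
    dimnames = list(.ds_channels, c("F", "S", "D")))
  # per-channel "reduce this current" drive; the spike-band error acts on
  # the fast shiftable spike machinery (Na, Kd) rather than on densities
  d_sh <- matrix(c(
       1,  0,  1,   # Na
       0,  1,  1,   # CaT
       0,  1,  1,   # CaS
       0,  0, -1,   # A
       0, -1, -1,   # KCa
      -1,  0, -1,   # Kd
       0,  1,  0),  # H
    nrow = 7, byrow = TRUE)
  # conductance and shift pathways share the same polarity logic but the
  # density loop reads Na through the spike-band sensor alone
  # curve rows derive from the channel drive rows: -row for increasing
  # activation curves (shift right to reduce the current), +row for
  # inactivation curves and for the decreasing activation curve of H
  chan_of <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 6, 7)
  curve_sign <- c(-1, 1, -1, 1, -1, 1, -1, 1, -1, -1, 1)
  w_half <- d_sh[chan_of, ] * curve_sign * halfshift_gain_mV
  dimnames(w_half) <- list(.ds_curves, c("F", "S", "D"))
  list(w_g = w_g, w_half = w_half)
}

#' Build a regulation configuration
#'
#' Variants map to the experiment families: `full` is the standard
#' dual-timescale controller (tau_g = 600 s slow conductances, tau_half = 6 s
#' fast half-shifts); `half_only` freezes conductances (tau_g = Inf);
#' `gmax_only` freezes half-shifts (tau_half = Inf); `reversed` swaps the
#' timescales (tau_g = 6 s, tau_half = 600 s); `half_disabled` is the
#' reversed controller with half-shifts disabled entirely (tau_g = 6 s,
#' tau_half = Inf); `none` disables both.
#'
#' The update laws are `tau_g dg_i/dt = -g_i (W_g e)_i` (multiplicative, so
#' conductances stay positive) and
#' `tau_half dDelta_j/dt = -(W_h e)_j - lambda tau_half (Delta_j - A_j)`,
#' where `e` is the target-normalized (dead-zoned) sensor error and `A` the
#' model's structural shift anchor -- its own initial half-voltage offsets,
#' toward which shifts relax when activity is on target. The `lambda` leak
#' softly discourages extreme shifts without imposing hard bounds.
#'
#' @param variant one of `"full"`, `"half_only"`, `"gmax_only"`,
#'   `"reversed"`, `"half_disabled"`, `"none"`.
#' @param targets named `(F, S, D)` sensor setpoints (uM); may be attached
#'   later via [with_targets()].
#' @param lambda restoring rate on shifts (1/s).
#' @param halfshift_gain_mV gain of the half-shift weights.
#' @param error_deadzone half-width (as a fraction of each target) of the
#'   tolerance band within which deviations are ignored; regulation responds
#'   only to sustained deviations beyond it, which makes the calibrated
#'   bursting state a genuine fixed point.
#' @param tau_g,tau_half override the variant's time constants (s; Inf
#'   freezes).
#' @return A `regulation_config` list.
#' @export
make_regulation_config <- function(variant = c("full", "half_only", "gmax_only",
                                               "reversed", "half_disabled", "none"),
                                   targets = NULL, lambda = 1 / 300,
                                   halfshift_gain_mV = 0.05,
                                   error_deadzone = 0.25,
                                   tau_g = NULL, tau_half = NULL) {
  variant <- match.arg(variant)
  taus <- switch(variant,
    full          = c(600, 6),
    half_only     = c(Inf, 6),
    gmax_only     = c(600, Inf),
    reversed      = c(6, 600),
    half_disabled = c(6, Inf),
    none          = c(Inf, Inf))
  if (!is.null(tau_g)) taus[1] <- tau_g
  if (!is.null(tau_half)) taus[2] <- tau_half
  if (any(taus <= 0)) stop("time constants must be positive (Inf allowed)")
  w <- default_weights(halfshift_gain_mV)
  if (is.null(targets)) targets <- c(F = 1, S = 1, D = 1)
  structure(list(variant = variant,
                 tau_g = taus[1], tau_half = taus[2],
                 enable_g = is.finite(taus[1]) && variant != "none",
                 enable_half = is.finite(taus[2]) && variant != "none",
                 w_g = w$w_g, w_half = w$w_half,
                 lambda = lambda,
                 halfshift_gain_mV = halfshift_gain_mV,
                 error_deadzone = error_deadzone,
                 shift_anchor = rep(0, 11),
                 targets = targets),
            class = "regulation_config")
}

#' Pin the structural shift anchor of a regulation config
#'
#' By default [simulate()] anchors the shift-restoring term at the starting
#' model's own half-voltage offsets. Reconfiguration experiments start a
#' model from somebody else's shift values while its structural identity is
#' unchanged; they pin the anchor explicitly with this helper.
#'
#' @param cfg a `regulation_config`.
#' @param anchor 11-vector of structural half-voltage offsets (mV).
#' @return The config with the anchor pinned.
#' @export
with_shift_anchor <- function(cfg, anchor) {
  stopifnot(inherits(cfg, "regulation_config"), length(anchor) == 11,
            all(is.finite(anchor)))
  cfg$shift_anchor <- as.numeric(anchor)
  cfg$shift_anchor_set <- TRUE
  cfg
}

#' Attach calibrated targets to a regulation config
#'
#' @param cfg a `regulation_config`.
#' @param targets named `(F, S, D)` setpoints (uM), strictly positive.
#' @return The config with targets set.
#' @export
with_targets <- function(cfg, targets) {
  stopifnot(inherits(cfg, "regulation_config"),
            all(is.finite(targets)), all(targets > 0))
  cfg$targets <- setNames(as.numeric(targets[c("F", "S", "D")]),
                          c("F", "S", "D"))
  cfg
}

# target-normalized error with dead zone, used by both update laws:
# deviations within +/- deadzone of the target are treated as on-target
.rel_error <- function(errors, targets, deadzone = 0) {
  e <- as.numeric(errors[c("F", "S", "D")]) / as.numeric(targets[c("F", "S", "D")])
  sign(e) * pmax(abs(e) - deadzone, 0)
}

#' One-step slow conductance update (R reference)
#'
#' Multiplicative law `tau_g dg/dt = -g (W_g e)`, integrated with one forward
#' step; identity when the slow pathway is frozen (`tau_g = Inf` or
#' disabled). Output is strictly positive for any bounded error.
#'
#' @param gmax 7-vector of conductances (uS), > 0.
#' @param errors sensor errors (uM) from [sensor_errors()].
#' @param cfg regulation config with targets set.
#' @param dt step (ms).
#' @return Updated 7-vector.
#' @export
conductance_update <- function(gmax, errors, cfg, dt) {
  stopifnot(all(gmax > 0))
  if (!cfg$enable_g || !is.finite(cfg$tau_g)) return(gmax)
  e <- .rel_error(errors, cfg$targets, cfg$error_deadzone)
  drive <- as.numeric(cfg$w_g %*% e)
  fac <- 1 - (dt * 1e-3 / cfg$tau_g) * drive
  gmax * pmax(fac, 1e-6)
}

#' One-step fast half-shift update (R reference)
#'
#' `tau_half dDelta/dt = -(W_h e) - lambda tau_half Delta`; no clipping, the
#' lambda leak realizes the soft discouragement of extreme shifts. Identity
#' when the pathway is frozen (`tau_half = Inf` or disabled).
#'
#' @param shifts 11-vector of half-voltage shifts (mV).
#' @param errors sensor errors (uM).
#' @param cfg regulation config with targets set.
#' @param dt step (ms).
#' @return Updated 11-vector.
#' @export
halfshift_update <- function(shifts, errors, cfg, dt) {
  if (!cfg$enable_half || !is.finite(cfg$tau_half)) return(shifts)
  e <- .rel_error(errors, cfg$targets, cfg$error_deadzone)
  drive <- as.numeric(cfg$w_half %*% e)
  shifts + (dt * 1e-3) *
    (-drive / cfg$tau_half - cfg$lambda * (shifts - cfg$shift_anchor))
}
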