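#' Advance the membrane/gating/calcium state by one step (R reference)
#'
#' Pure-R mirror of one step of the compiled integrator, without regulation:
#' conductances and currents are evaluated at the incoming state, gates relax
#' by exponential Euler toward their steady states with fixed
#' voltage-dependent time constants, calcium advances by forward Euler,
#' voltage by exponential Euler toward its instantaneous resting point
#' (exact for the voltage equation with frozen gates, and unconditionally
#' stable in the stiff high-conductance regime), then the sensor filters are
#' updated with the new calcium. Used for small-n verification of the
#' production loop; not meant for long simulations.
#'
#' @param state a [init_dynamic_state()] list.
#' @param intrinsic an [intrinsic_state()].
#' @param env an [environment_state()].
#' @param dt step (ms), `0 < dt <= 0.1`.
#' @param const constants from [dynamics_constants()].
#' @return The advanced `dynamic_state`.
#' @export
step_dynamics <- function(state, intrinsic, env, dt,
                          const = dynamics_constants()) {
  stopifnot(dt > 0, dt <= 0.1)
  V <- state$V; gates <- state$gates; Ca <- state$Ca
  g <- intrinsic$gmax; sh <- intrinsic$half_shifts
  ECa <- const$nernst_ca_mV * log(const$ca_ext_uM / max(Ca, 1e-6))
  geff <- c(
    Na  = g[["Na"]]  * gates[1]^3 * gates[2],
    CaT = g[["CaT"]] * gates[3]^3 * gates[4],
    CaS = g[["CaS"]] * gates[5]^3 * gates[6],
    A   = g[["A"]]   * gates[7]^3 * gates[8],
    KCa = g[["KCa"]] * gates[9]^4,
    Kd  = g[["Kd"]]  * gates[10]^4,
    H   = g[["H"]]   * gates[11],
    leak = intrinsic$leak_g
  )
  erev <- c(const$E_Na, ECa, ECa, env$E_K, env$E_K, env$E_K, const$E_H,
            env$E_leak)
  ICaT <- geff[["CaT"]] * (V - ECa)
  ICaS <- geff[["CaS"]] * (V - ECa)
  caFac <- Ca / (Ca + const$kca_half_uM)
  new_gates <- vapply(1:11, function(gi) {
    minf <- gate_inf_r(gi, V - sh[gi])
    if (gi == 9) minf <- minf * caFac
    minf + (gates[gi] - minf) * exp(-dt / gate_tau_r(gi, V))
  }, numeric(1))
  Ca2 <- Ca + dt * (-const$f_ca * (ICaT + ICaS) - Ca +
                      const$ca_rest) / const$tau_ca_ms
  Ca2 <- max(Ca2, 0)
  Gtot <- sum(geff)
  Vinf <- sum(geff * erev) / Gtot
  V2 <- Vinf + (V - Vinf) * exp(-dt * Gtot / const$C_nF)
  if (!all(is.finite(c(V2, Ca2, new_gates)))) {
    bad <- c("V", "Ca", paste0("gate", 1:11))[!is.finite(c(V2, Ca2, new_gates))][1]
    stop("integration failure: ", bad, " non-finite at t = ",
         (state$t + dt * 1e-3), " s")
  }
  structure(list(V = V2, gates = new_gates, Ca = Ca2,
                 filters = update_filters(state$filters, Ca2, dt, const),
                 t = state$t + dt * 1e-3),
            class = "dynamic_state")
}

#' Simulate a model neuron under a perturbation schedule
#'
#' Runs the compiled integrator over the whole schedule with the given
#' regulation configuration. The dynamics are deterministic: identical inputs
#' give identical traces. Voltage and calcium are recorded every
#' `record_interval` ms; the intrinsic parameters (7 conductances, 11
#' half-shifts) and the sensor errors every `param_interval` ms; spike peak
#' times are detected online at full `dt` resolution with the package's
#' detector contract (threshold -20 mV, 2 ms minimum separation).
#'
#' @param intrinsic an [intrinsic_state()].
#' @param schedule a [build_schedule()] schedule.
#' @param regulation a [make_regulation_config()] config (targets must be
#'   set if any pathway is enabled).
#' @param dt integration step (ms), `0 < dt <= 0.1`.
#' @param record_interval voltage/calcium sampling interval (ms). Use
#'   <= 1 ms if you intend to re-run peak detection on the stored trace.
#' @param param_interval intrinsic-parameter sampling interval (ms),
#'   <= 1000 so snapshot windows are well sampled.
#' @param record_v store the voltage/calcium series (disable to save memory
#'   on long ensemble runs; spike times are always recorded).
#' @param init optional [init_dynamic_state()] to start from.
#' @param const constants from [dynamics_constants()].
#' @param use_tables use the precomputed lookup-table fast path for gate
#'   kinetics (default); `FALSE` evaluates the closed forms exactly.
#' @return A `sim_trace` object.
#' @export
simulate <- function(intrinsic, schedule,
                     regulation = make_regulation_config("none"),
                     dt = 0.05, record_interval = 1, param_interval = 1000,
                     record_v = TRUE, init = NULL,
                     const = dynamics_constants(), use_tables = TRUE) {
  stopifnot(inherits(intrinsic, "intrinsic_state"),
            inherits(schedule, "perturbation_schedule"),
            inherits(regulation, "regulation_config"))
  if (param_interval > 1000) stop("param_interval must be <= 1000 ms")
  if (record_interval < dt) stop("record_interval must be >= dt")
  if ((regulation$enable_g || regulation$enable_half) &&
      any(regulation$targets <= 0))
    stop("regulation enabled but targets are not calibrated")
  # shifts relax toward the model's structural configuration unless the
  # caller pinned a different anchor (e.g. reconfiguration re-exposures)
  if (is.null(regulation$shift_anchor_set) || !regulation$shift_anchor_set)
    regulation$shift_anchor <- unname(intrinsic$half_shifts)
  if (is.null(init)) {
    tg <- if (regulation$enable_g || regulation$enable_half)
      regulation$targets else NULL
    init <- init_dynamic_state(const = const, targets = tg)
  }
  out <- simulate_core(
    v0 = init$V, gates0 = init$gates, ca_init = init$Ca,
    filters0 = init$filters,
    gmax0 = unname(intrinsic$gmax), gleak = intrinsic$leak_g,
    shifts0 = unname(intrinsic$half_shifts),
    schedule = schedule_matrix(schedule),
    reg = regulation, consts = const,
    dt = dt, v_rec_ms = record_interval, p_rec_ms = param_interval,
    record_v = record_v, use_tables = use_tables)
  colnames(out$gmax) <- .ds_channels
  colnames(out$half_shifts) <- .ds_curves
  colnames(out$sensor_errors) <- c("F", "S", "D")
  structure(list(
    time_v = out$t_v, V = out$V, Ca = out$Ca,
    time_p = out$t_p, gmax = out$gmax, half_shifts = out$half_shifts,
    sensor_errors = out$sensor_errors,
    spike_times = out$spike_times,
    schedule = schedule, regulation = regulation,
    intrinsic0 = intrinsic,
    dt = dt, record_interval = record_interval,
    param_interval = param_interval,
    final = out$final, const = const),
    class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("<sim_trace>", max(x$time_p), "s,", length(x$spike_times), "spikes,",
      nrow(x$gmax), "parameter samples\n")
  invisible(x)
}

#' Final intrinsic state of a trace
#'
#' @param trace a `sim_trace`.
#' @return An [intrinsic_state()] with the end-of-run conductances and
#'   half-shifts.
#' @export
final_intrinsic <- function(trace) {
  intrinsic_state(trace$final$gmax, trace$final$half_shifts,
                  trace$intrinsic0$leak_g)
}

#' Write / read a trace as plain-text CSV + JSON
#'
#' Two CSV files (`voltage.csv`: time_s, V_mV, Ca_uM; `params.csv`: time_s,
#' seven conductances, eleven half-shifts, three sensor errors), a
#' `spikes.csv`, and a JSON manifest carrying the schedule, regulation
#' variant, dt and initial intrinsic state.
#'
#' @param trace a `sim_trace`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (length(trace$time_v))
    write.csv(data.frame(time_s = trace$time_v, V_mV = trace$V,
                         Ca_uM = trace$Ca),
              file.path(dir, "voltage.csv"), row.names = FALSE)
  p <- data.frame(time_s = trace$time_p, trace$gmax, trace$half_shifts,
                  err = trace$sensor_errors, check.names = FALSE)
  write.csv(p, file.path(dir, "params.csv"), row.names = FALSE)
  write.csv(data.frame(spike_time_s = trace$spike_times),
            file.path(dir, "spikes.csv"), row.names = FALSE)
  manifest <- list(
    dt = trace$dt, record_interval = trace$record_interval,
    param_interval = trace$param_interval,
    schedule = trace$schedule$epochs,
    regulation_variant = trace$regulation$variant,
    targets = as.list(trace$regulation$targets),
    gmax0 = as.list(trace$intrinsic0$gmax),
    half_shifts0 = as.list(trace$intrinsic0$half_shifts),
    leak_g = trace$intrinsic0$leak_g)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
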