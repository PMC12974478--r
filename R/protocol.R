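#' Build a repeated high-potassium perturbation schedule
#'
#' A baseline lead, then `n_cycles` of (perturbation, wash), with the final
#' wash extended by `tail_s`. Perturbation epochs carry the high-potassium
#' reversal potentials (E_K = -55 mV, E_leak = -32 mV); baseline and wash
#' epochs carry (-80, -50). Defaults give the canonical 220-min protocol:
#' 10 min lead + 3 x (30 min perturbation + 30 min wash) + 30 min extra on
#' the final wash.
#'
#' @param lead_s baseline lead duration (s).
#' @param n_cycles number of perturbation/wash cycles (>= 1).
#' @param pert_s,wash_s perturbation and wash durations (s).
#' @param tail_s extra duration appended to the final wash (s).
#' @return A `perturbation_schedule` object: a data.frame of epochs
#'   (label, start, duration, E_K, E_leak) plus `total_duration`.
#' @export
build_schedule <- function(lead_s = 600, n_cycles = 3, pert_s = 1800,
                           wash_s = 1800, tail_s = 1800) {
  durs <- c(lead_s, pert_s, wash_s, tail_s)
  if (any(durs < 0)) stop("durations must be non-negative")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  labels <- c("baseline", rep(c("perturbation", "wash"), n_cycles))
  duration <- c(lead_s, rep(c(pert_s, wash_s), n_cycles))
  duration[length(duration)] <- duration[length(duration)] + tail_s
  keep <- duration > 0
  labels <- labels[keep]; duration <- duration[keep]
  start <- cumsum(c(0, duration[-length(duration)]))
  ek <- vapply(labels, function(l) .ds_env[[l]]["E_K"], numeric(1))
  el <- vapply(labels, function(l) .ds_env[[l]]["E_leak"], numeric(1))
  epochs <- data.frame(label = labels, start = start, duration = duration,
                       E_K = unname(ek), E_leak = unname(el),
                       stringsAsFactors = FALSE)
  structure(list(epochs = epochs,
                 total_duration = sum(duration),
                 lead_s = lead_s, n_cycles = n_cycles,
                 pert_s = pert_s, wash_s = wash_s, tail_s = tail_s),
            class = "perturbation_schedule")
}

#' @export
print.perturbation_schedule <- function(x, ...) {
  cat("<perturbation_schedule> total", x$total_duration, "s\n")
  print(x$epochs)
  invisible(x)
}

#' Environment in effect at a given time
#'
#' Epoch boundaries are half-open `[start, start + duration)`; environment
#' switches are instantaneous steps.
#'
#' @param schedule a [build_schedule()] object.
#' @param t time in seconds, `0 <= t < total_duration`.
#' @return An [environment_state()] for the containing epoch.
#' @export
env_for_time <- function(schedule, t) {
  ep <- schedule$epochs
  if (length(t) != 1 || !is.finite(t) || t < 0 || t >= schedule$total_duration)
    stop("t out of schedule range [0, ", schedule$total_duration, ")")
  i <- findInterval(t, ep$start)
  environment_state(ep$E_K[i], ep$E_leak[i], ep$label[i])
}

#' Named schedule profiles
#'
#' `"full"` is the acceptance-scale 220-min protocol. `"ci"` is the
#' scaled-down profile used for fast qualitative runs: 2-min lead and tail,
#' three 5-min perturbation / 5-min wash cycles (34 min total). The
#' regulation time constants are unchanged, so the fast/slow separation
#' survives, but slow-process claims are only fully validated at full scale.
#'
#' @param profile `"full"` or `"ci"`.
#' @return A `perturbation_schedule`.
#' @export
schedule_profile <- function(profile = c("full", "ci")) {
  profile <- match.arg(profile)
  if (profile == "full") build_schedule()
  else build_schedule(lead_s = 120, n_cycles = 3, pert_s = 300,
                      wash_s = 300, tail_s = 120)
}

# rows of the schedule matrix handed to the compiled loop
schedule_matrix <- function(schedule) {
  ep <- schedule$epochs
  as.matrix(ep[, c("start", "duration", "E_K", "E_leak")])
}

# epoch index table helpers used by metrics/geometry
perturbation_epochs <- function(schedule) {
  which(schedule$epochs$label == "perturbation")
}
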