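#' Reconfigure a model between experiment runs
#'
#' Builds the re-exposure initial condition from a finished run:
#' `keep = "final_gmax"` retains the final maximal conductances from the end
#' of the source run while resetting all half-(in)activation shifts to the
#' model's pre-perturbation values; `keep = "final_halfshifts"` does the
#' converse (final shifts, original conductances).
#'
#' @param member an ensemble member (list with `id`, `intrinsic`).
#' @param source_result an [run_protocol_experiment()] result containing the
#'   model's final intrinsic state.
#' @param keep `"final_gmax"` or `"final_halfshifts"`.
#' @return An [intrinsic_state()].
#' @export
reconfigure_model <- function(member, source_result,
                              keep = c("final_gmax", "final_halfshifts")) {
  keep <- match.arg(keep)
  fin <- source_result$final_intrinsic[[as.character(member$id)]]
  if (is.null(fin)) stop("source run has no final snapshot for model ", member$id)
  init <- member$intrinsic
  if (keep == "final_gmax")
    intrinsic_state(fin$gmax, init$half_shifts, init$leak_g)
  else
    intrinsic_state(init$gmax, fin$half_shifts, init$leak_g)
}

#' Run one experiment family over an ensemble
#'
#' Simulates every ensemble member under the regulation variant and
#' perturbation schedule, then computes per-perturbation burst-onset
#' latencies, per-epoch activity classifications, and trajectory summaries
#' in both parameter spaces. Reconfiguration variants (`reconfig_keep_g`,
#' `reconfig_keep_half`) rebuild each model's initial state from
#' `source_result` via [reconfigure_model()] and run the full controller.
#' Integration failures are recorded per model and the run continues.
#'
#' @param ensemble a `model_ensemble` (or a list with `members`).
#' @param variant regulation variant (`"full"`, `"half_only"`,
#'   `"gmax_only"`, `"reversed"`, `"half_disabled"`, `"reconfig_keep_g"`,
#'   `"reconfig_keep_half"`).
#' @param schedule a [build_schedule()] schedule or a [schedule_profile()]
#'   name (`"full"`, `"ci"`).
#' @param dt integration step (ms).
#' @param record_interval voltage sampling (ms).
#' @param source_result source run for reconfiguration variants.
#' @param keep_traces retain full traces in the result (memory heavy).
#' @param classification_window per-epoch classification window (s).
#' @return An `experiment_result`.
#' @export
run_protocol_experiment <- function(ensemble, variant = "full",
                                    schedule = "full", dt = 0.05,
                                    record_interval = 5,
                                    source_result = NULL,
                                    keep_traces = FALSE,
                                    classification_window = 60) {
  if (is.character(schedule)) schedule <- schedule_profile(schedule)
  reconfig <- variant %in% c("reconfig_keep_g", "reconfig_keep_half")
  reg_variant <- if (reconfig) "full" else variant
  if (reconfig && is.null(source_result))
    stop("reconfiguration variants need a source_result")
  members <- ensemble$members
  latency <- list(); classes <- list(); summaries <- list()
  final_intr <- list(); init_intr <- list(); failures <- character(0)
  traces <- if (keep_traces) list() else NULL
  for (m in members) {
    intr <- if (!reconfig) m$intrinsic else
      reconfigure_model(m, source_result,
                        keep = if (variant == "reconfig_keep_g")
                          "final_gmax" else "final_halfshifts")
    reg <- make_regulation_config(reg_variant, targets = m$targets)
    if (reconfig) # structural identity stays the member's own offsets
      reg <- with_shift_anchor(reg, unname(m$intrinsic$half_shifts))
    tr <- tryCatch(
      simulate(intr, schedule, reg, dt = dt,
               record_interval = record_interval, param_interval = 1000),
      error = function(e) e)
    if (inherits(tr, "error")) {
      failures[as.character(m$id)] <- conditionMessage(tr)
      next
    }
    latency[[length(latency) + 1L]] <- perturbation_latencies(tr, m$id)
    classes[[length(classes) + 1L]] <-
      epoch_classifications(tr, classification_window, m$id)
    summaries[[as.character(m$id)]] <- trajectory_summary(tr)
    init_intr[[as.character(m$id)]] <- intr
    final_intr[[as.character(m$id)]] <- final_intrinsic(tr)
    if (keep_traces) traces[[as.character(m$id)]] <- tr
  }
  structure(list(
    variant = variant,
    schedule = schedule, dt = dt,
    latency = do.call(rbind, latency),
    classifications = do.call(rbind, classes),
    summaries = summaries,
    initial_intrinsic = init_intr,
    final_intrinsic = final_intr,
    failures = failures,
    traces = traces,
    manifest = list(variant = variant, dt = dt,
                    n_models = length(members),
                    ensemble_seed = if (!is.null(ensemble$spec))
                      ensemble$spec$seed else NA,
                    schedule = schedule$epochs)),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$variant, "variant,",
      length(x$final_intrinsic), "models,",
      length(x$failures), "failures\n")
  invisible(x)
}

#' Aggregate experiment results into the summary tables
#'
#' Emits the population-level tables: burst-onset latency by perturbation
#' index with group medians and nonparametric statistics, displacement-norm
#' tables per parameter space with statistics across protocol phases,
#' per-model sphere radius / outside distance / angles, and headline counts
#' (models with positive conductance-space outside distance, models with
#' both half-shift angles above 90 degrees, models with latency improvement
#' after the first perturbation). Models with no spikes in an epoch appear
#' as `NA` latencies and are excluded from the statistics with their count
#' noted.
#'
#' @param result an `experiment_result` (or list of them; tables gain a
#'   `variant` column).
#' @return A `report_bundle` list of data.frames and test results.
#' @export
aggregate_and_report <- function(result) {
  results <- if (inherits(result, "experiment_result")) list(result) else result
  one <- function(res) {
    lat <- res$latency
    lat_groups <- split(lat$latency_s[!is.na(lat$latency_s)],
                        lat$perturbation_index[!is.na(lat$latency_s)])
    lat_stats <- if (length(lat_groups) >= 2 &&
                     all(vapply(lat_groups, length, 1L) > 0))
      dunn_bonferroni(lat_groups) else NULL
    norms <- function(space) {
      do.call(rbind, lapply(names(res$summaries), function(id) {
        nm <- res$summaries[[id]][[space]]$norms
        data.frame(model_id = id, phase = names(nm), norm = unname(nm),
                   stringsAsFactors = FALSE)
      }))
    }
    gnorm <- norms("conductance"); hnorm <- norms("halfshift")
    norm_stats <- function(df) {
      gr <- split(df$norm, df$phase)
      gr <- gr[rownames(displacements(matrix(0, 7, 1)))]
      dunn_bonferroni(gr)
    }
    geom <- do.call(rbind, lapply(names(res$summaries), function(id) {
      s <- res$summaries[[id]]
      data.frame(model_id = id,
                 g_radius = s$conductance$radius,
                 g_outside = s$conductance$outside_distance,
                 h_radius = s$halfshift$radius,
                 h_outside = s$halfshift$outside_distance,
                 angle_pwp = s$angles["pwp"], angle_wpw = s$angles["wpw"],
                 stringsAsFactors = FALSE)
    }))
    lat_wide <- stats::reshape(lat, idvar = "model_id",
                               timevar = "perturbation_index",
                               direction = "wide")
    improved <- sum(lat_wide$latency_s.1 >
                      pmax(lat_wide$latency_s.2, lat_wide$latency_s.3),
                    na.rm = TRUE)
    list(variant = res$variant,
         latency = lat,
         latency_medians = tapply(lat$latency_s, lat$perturbation_index,
                                  median, na.rm = TRUE),
         latency_missing = tapply(lat$latency_s, lat$perturbation_index,
                                  function(z) sum(is.na(z))),
         latency_stats = lat_stats,
         conductance_norms = gnorm,
         conductance_norm_stats = if (nrow(gnorm)) norm_stats(gnorm) else NULL,
         halfshift_norms = hnorm,
         halfshift_norm_stats = if (nrow(hnorm)) norm_stats(hnorm) else NULL,
         geometry = geom,
         classifications = res$classifications,
         counts = c(
           n_models = length(res$summaries),
           n_outside_positive = sum(geom$g_outside > 0),
           n_outside_beyond_2r = sum(geom$g_outside > geom$g_radius),
           n_angles_gt90 = sum(geom$angle_pwp > 90 & geom$angle_wpw > 90),
           n_latency_improved = improved),
         failures = res$failures)
  }
  structure(lapply(results, one), class = "report_bundle")
}

#' Write a report bundle to CSV files
#'
#' @param report a [aggregate_and_report()] bundle.
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rep in report) {
    pre <- file.path(dir, rep$variant)
    write.csv(rep$latency, paste0(pre, "_latency.csv"), row.names = FALSE)
    write.csv(rep$geometry, paste0(pre, "_geometry.csv"), row.names = FALSE)
    write.csv(rep$conductance_norms, paste0(pre, "_gnorms.csv"),
              row.names = FALSE)
    write.csv(rep$halfshift_norms, paste0(pre, "_hnorms.csv"),
              row.names = FALSE)
    write.csv(rep$classifications, paste0(pre, "_classes.csv"),
              row.names = FALSE)
    if (!is.null(rep$latency_stats))
      write.csv(rep$latency_stats$pairwise, paste0(pre, "_latency_stats.csv"),
                row.names = FALSE)
  }
  invisible(dir)
}
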