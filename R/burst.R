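#' Detect spike peaks in a voltage trace
#'
#' Local maxima above `threshold` (default -20 mV) separated by at least
#' `min_sep` (default 2 ms); the peak time is the sample time of the maximum.
#' Requires uniform, detection-grade sampling (interval <= 1 ms).
#'
#' @param V_samples voltage samples (mV).
#' @param sample_times sample times (s), uniform.
#' @param threshold peak threshold (mV).
#' @param min_sep minimum peak separation (s).
#' @return A `spike_train` object (sorted `peak_times`, threshold).
#' @export
detect_spike_peaks <- function(V_samples, sample_times, threshold = -20,
                               min_sep = 0.002) {
  stopifnot(length(V_samples) == length(sample_times))
  if (length(V_samples) < 3) return(spike_train(numeric(0), threshold))
  dts <- diff(sample_times)
  if (max(dts) - min(dts) > 1e-9 + 1e-6 * max(dts))
    stop("detect_spike_peaks requires uniform sampling")
  if (dts[1] > 1e-3 + 1e-12)
    stop("sampling too coarse for spike detection (need <= 1 ms, got ",
         signif(dts[1] * 1e3, 3), " ms)")
  n <- length(V_samples)
  mid <- V_samples[2:(n - 1)]
  is_peak <- mid >= V_samples[1:(n - 2)] & mid > V_samples[3:n] &
    mid >= threshold
  idx <- which(is_peak) + 1L
  if (length(idx) > 1) {
    keep <- idx[1]
    last <- sample_times[idx[1]]
    for (i in idx[-1]) {
      if (sample_times[i] - last >= min_sep) {
        keep <- c(keep, i)
        last <- sample_times[i]
      }
    }
    idx <- keep
  }
  spike_train(sample_times[idx], threshold)
}

#' Spike train container
#'
#' @param peak_times spike peak times (s), strictly increasing.
#' @param detection_threshold threshold used by the detector (mV).
#' @return A `spike_train` object.
#' @export
spike_train <- function(peak_times, detection_threshold = -20) {
  peak_times <- as.numeric(peak_times)
  if (is.unsorted(peak_times, strictly = TRUE) && length(peak_times) > 1)
    stop("peak_times must be strictly increasing")
  structure(list(peak_times = peak_times,
                 detection_threshold = detection_threshold),
            class = "spike_train")
}

#' Burst-onset latency within an epoch
#'
#' Interspike intervals are computed among the spikes falling in
#' `[epoch_onset, epoch_end)`. If any ISI exceeds 5 s (a prolonged quiescent
#' interval), burst onset is the first spike after the last such interval;
#' otherwise the first detected spike is the onset. Latency is onset minus
#' epoch onset; `NA` if the epoch contains no spikes.
#'
#' @param train a [spike_train()] (or numeric spike times).
#' @param epoch_onset,epoch_end epoch bounds (s).
#' @param quiescence_s prolonged-quiescence ISI threshold (s), fixed at 5.
#' @return Latency in seconds, or `NA_real_`.
#' @export
time_to_first_burst <- function(train, epoch_onset, epoch_end,
                                quiescence_s = 5) {
  st <- if (inherits(train, "spike_train")) train$peak_times else as.numeric(train)
  st <- st[st >= epoch_onset & st < epoch_end]
  if (length(st) == 0) return(NA_real_)
  if (length(st) == 1) return(st[1] - epoch_onset)
  isi <- diff(st)
  long <- which(isi > quiescence_s)
  onset <- if (length(long)) st[max(long) + 1L] else st[1]
  onset - epoch_onset
}

#' Burst grouping statistics of a spike train
#'
#' Spikes are grouped into bursts by intra-burst ISI below
#' `intra_burst_isi` (default 0.5 s): a spike preceded by a longer gap opens
#' a new burst. The burst period is the mean interval between successive
#' burst start times.
#'
#' @param train a [spike_train()] or numeric spike times (>= 2 spikes).
#' @param intra_burst_isi grouping threshold (s).
#' @return List: `burst_period` (s, `NA` if fewer than 2 bursts),
#'   `spikes_per_burst` (mean), `n_bursts`, `burst_starts`, `period_cv`.
#' @export
burst_statistics <- function(train, intra_burst_isi = 0.5) {
  st <- if (inherits(train, "spike_train")) train$peak_times else as.numeric(train)
  if (length(st) < 2) stop("burst_statistics needs at least 2 spikes")
  new_burst <- c(TRUE, diff(st) >= intra_burst_isi)
  burst_id <- cumsum(new_burst)
  starts <- st[new_burst]
  n_bursts <- length(starts)
  period <- if (n_bursts >= 2) mean(diff(starts)) else NA_real_
  cv <- if (n_bursts >= 3) sd(diff(starts)) / mean(diff(starts)) else
    if (n_bursts == 2) 0 else NA_real_
  list(burst_period = period,
       spikes_per_burst = mean(tabulate(burst_id)),
       n_bursts = n_bursts,
       burst_starts = starts,
       period_cv = cv)
}

#' Classify an activity window
#'
#' Over a window of at least `min_window` seconds: `silent` = no spikes and
#' mean voltage below -40 mV; `depolarization_block` = no spikes and mean
#' voltage at or above -40 mV; `bursting` = at least 2 bursts with >= 2
#' spikes per burst and inter-burst period CV < 0.3; anything else `tonic`.
#'
#' @param trace a `sim_trace` (voltage must be recorded), or a list with
#'   `time_v`, `V`, `spike_times`.
#' @param start,end window bounds (s); default the whole trace.
#' @param min_window minimum window length (s).
#' @param intra_burst_isi burst grouping threshold (s).
#' @return List: `state`, `mean_V`, `n_spikes`, `n_bursts`, `burst_period`,
#'   `period_cv`.
#' @export
classify_window <- function(trace, start = NULL, end = NULL, min_window = 60,
                            intra_burst_isi = 0.5) {
  if (is.null(start)) start <- min(trace$time_v)
  if (is.null(end)) end <- max(trace$time_v)
  if (end - start < min_window)
    stop("classification window must be at least ", min_window, " s")
  keep <- trace$time_v >= start & trace$time_v < end
  if (!any(keep)) stop("window contains no voltage samples")
  mv <- mean(trace$V[keep])
  st <- trace$spike_times[trace$spike_times >= start & trace$spike_times < end]
  out <- list(state = "tonic", mean_V = mv, n_spikes = length(st),
              n_bursts = NA_integer_, burst_period = NA_real_,
              period_cv = NA_real_)
  if (length(st) == 0) {
    out$state <- if (mv < -40) "silent" else "depolarization_block"
    out$n_bursts <- 0L
    return(out)
  }
  if (length(st) >= 2) {
    bs <- burst_statistics(st, intra_burst_isi)
    out$n_bursts <- bs$n_bursts
    out$burst_period <- bs$burst_period
    out$period_cv <- bs$period_cv
    spb <- tabulate(cumsum(c(TRUE, diff(st) >= intra_burst_isi)))
    if (sum(spb >= 2) >= 2 && bs$n_bursts >= 2 &&
        !is.na(bs$period_cv) && bs$period_cv < 0.3)
      out$state <- "bursting"
  }
  out
}

#' Latency table for all perturbation epochs of a trace
#'
#' @param trace a `sim_trace`.
#' @param model_id identifier copied into the table.
#' @return data.frame (model_id, perturbation_index, latency_s).
#' @export
perturbation_latencies <- function(trace, model_id = 1L) {
  ep <- trace$schedule$epochs
  pidx <- which(ep$label == "perturbation")
  lat <- vapply(seq_along(pidx), function(k) {
    i <- pidx[k]
    time_to_first_burst(trace$spike_times, ep$start[i],
                        ep$start[i] + ep$duration[i])
  }, numeric(1))
  data.frame(model_id = model_id, perturbation_index = seq_along(pidx),
             latency_s = lat)
}

#' Classification table for the wash/baseline epochs of a trace
#'
#' Each epoch is classified over its final `window_s` seconds (the settled
#' part of the epoch).
#'
#' @param trace a `sim_trace` with voltage recorded.
#' @param window_s classification window (s).
#' @param model_id identifier copied into the table.
#' @return data.frame (model_id, epoch, label, state, mean_V).
#' @export
epoch_classifications <- function(trace, window_s = 60, model_id = 1L) {
  ep <- trace$schedule$epochs
  res <- lapply(seq_len(nrow(ep)), function(i) {
    e <- ep$start[i] + ep$duration[i]
    cls <- classify_window(trace, start = e - window_s, end = e,
                           min_window = window_s)
    data.frame(model_id = model_id, epoch = i, label = ep$label[i],
               state = cls$state, mean_V = cls$mean_V,
               n_bursts = cls$n_bursts)
  })
  do.call(rbind, res)
}
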