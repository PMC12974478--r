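test_that("peak detector contract on constructed traces", {
  tt <- seq(0, 2, by = 0.001)
  # constant below threshold: nothing
  expect_length(detect_spike_peaks(rep(-60, length(tt)), tt)$peak_times, 0)
  # single triangular pulse peaking at 1.0 s
  fx <- synth_spike_V(1.0, total_s = 2)
  st <- detect_spike_peaks(fx$V, fx$times)
  expect_equal(st$peak_times, 1.0, tolerance = 1e-9)
  # 3 bursts x 4 spikes with known times
  spk <- as.vector(outer(seq(0, 0.15, by = 0.05), c(1, 3, 5), "+"))
  fx <- synth_spike_V(spk, total_s = 6)
  st <- detect_spike_peaks(fx$V, fx$times)
  expect_length(st$peak_times, 12)
  expect_equal(st$peak_times, sort(spk), tolerance = 2e-3)
  # coarse sampling refused
  expect_error(detect_spike_peaks(rep(0, 100), seq(0, 0.99, by = 0.01)),
               "coarse")
})

test_that("burst-onset latency implements the 5 s quiescence rule", {
  # ISIs [1,1,7,0.5,0.5]: last long gap ends at 10 -> latency 10
  expect_equal(time_to_first_burst(c(1, 2, 3, 10, 10.5, 11), 0, 30), 10)
  # no ISI above 5 s: first detected spike is the onset
  expect_equal(time_to_first_burst(c(0.5, 1.0, 1.5), 0, 30), 0.5)
  # no spikes: latency missing
  expect_true(is.na(time_to_first_burst(numeric(0), 0, 30)))
  # spikes outside the epoch are ignored
  expect_equal(time_to_first_burst(c(-5, 2, 3), 0, 30), 2)
})

test_that("latency is translation invariant and missing iff no spikes", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(0:12, 1)
    spk <- sort(runif(n, 0, 40))
    lat <- time_to_first_burst(spk, 0, 40)
    expect_identical(is.na(lat), n == 0L)
    shift <- runif(1, -100, 100)
    expect_equal(time_to_first_burst(spk + shift, shift, 40 + shift), lat)
  }
})

test_that("burst statistics group spikes by the intra-burst ISI", {
  spk <- as.vector(outer(c(0, 0.1, 0.2), c(0, 2, 4, 6), "+"))
  bs <- burst_statistics(sort(spk))
  expect_equal(bs$n_bursts, 4)
  expect_equal(bs$burst_period, 2)
  expect_equal(bs$spikes_per_burst, 3)
  # tonic 1 Hz spiking: every spike its own burst, period 1
  bs <- burst_statistics(0:10)
  expect_equal(bs$n_bursts, 11)
  expect_equal(bs$burst_period, 1)
  expect_error(burst_statistics(1), "at least 2")
})

test_that("window classification follows the committed thresholds", {
  tt <- seq(0, 70, by = 0.01)
  flat <- function(v) list(time_v = tt, V = rep(v, length(tt)),
                           spike_times = numeric(0))
  expect_equal(classify_window(flat(-60))$state, "silent")
  expect_equal(classify_window(flat(-30))$state, "depolarization_block")
  expect_error(classify_window(flat(-60), 0, 30), "at least")
  # regular synthetic bursting
  spk <- sort(as.vector(outer(c(0, 0.1, 0.2), seq(0, 68, by = 2), "+")))
  tr <- list(time_v = tt, V = rep(-50, length(tt)), spike_times = spk)
  expect_equal(classify_window(tr)$state, "bursting")
  # settled reference model is a burster
  cls <- classify_window(ref_trace(), 90, 150)
  expect_equal(cls$state, "bursting")
  expect_gte(cls$n_bursts, 10)
})

test_that("detector agrees with the online compiled detector", {
  tr <- ref_trace()  # 1 ms recording
  st <- detect_spike_peaks(tr$V, tr$time_v)
  online <- tr$spike_times
  # the offline pass sees the 1 ms subsampled trace, the online pass the
  # full dt grid; counts may differ by a spike whose subsampled peak dips
  # under threshold, times by up to one offline sample
  expect_lte(abs(length(st$peak_times) - length(online)),
             ceiling(0.01 * length(online)))
  nearest <- vapply(st$peak_times,
                    function(t) min(abs(online - t)), numeric(1))
  expect_lt(stats::quantile(nearest, 0.95), 1.5e-3)
})

test_that("per-epoch latency and classification tables are consistent", {
  tr <- ci_full_run()
  lat <- perturbation_latencies(tr, model_id = 7)
  expect_equal(nrow(lat), 3)
  expect_equal(lat$model_id, rep(7, 3))
  expect_true(all(is.na(lat$latency_s) |
                    (lat$latency_s >= 0 & lat$latency_s <= 300)))
  cls <- epoch_classifications(tr)
  expect_equal(nrow(cls), nrow(tr$schedule$epochs))
})
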