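test_that("reconfigure_model swaps exactly one parameter set", {
  ref <- reference_model()
  member <- list(id = 1, intrinsic = ref,
                 targets = reference_calibration()$targets)
  fake_final <- intrinsic_state(ref$gmax * 2, ref$half_shifts + 1, ref$leak_g)
  src <- structure(list(final_intrinsic = list("1" = fake_final)),
                   class = "experiment_result")
  kg <- reconfigure_model(member, src, "final_gmax")
  expect_equal(kg$gmax, fake_final$gmax)
  expect_equal(kg$half_shifts, ref$half_shifts)
  kh <- reconfigure_model(member, src, "final_halfshifts")
  expect_equal(kh$gmax, ref$gmax)
  expect_equal(kh$half_shifts, fake_final$half_shifts)
  expect_error(reconfigure_model(list(id = 9, intrinsic = ref), src),
               "no final snapshot")
})

test_that("a frozen-regulation source run reproduces the model exactly", {
  ref <- reference_model()
  member <- list(id = 1, intrinsic = ref,
                 targets = reference_calibration()$targets)
  # with both pathways frozen the final state equals the initial state
  ens <- structure(list(spec = NULL, members = list(member), reference = ref),
                   class = "model_ensemble")
  sch <- build_schedule(lead_s = 10, n_cycles = 1, pert_s = 10, wash_s = 10,
                        tail_s = 0)
  reg_frozen <- make_regulation_config("none")
  tr <- simulate(ref, sch, reg_frozen, dt = 0.05, record_interval = 5,
                 param_interval = 500)
  fin <- final_intrinsic(tr)
  expect_equal(fin$gmax, ref$gmax)
  expect_equal(fin$half_shifts, ref$half_shifts)
})

test_that("experiment results aggregate into consistent report tables", {
  res <- test_ensemble_run()
  expect_length(res$failures, 0)
  rep <- aggregate_and_report(res)[[1]]
  # medians in the report equal direct medians of the latency table
  lat <- res$latency
  med <- tapply(lat$latency_s, lat$perturbation_index, median, na.rm = TRUE)
  expect_equal(unname(unlist(rep$latency_medians)), unname(med))
  expect_equal(unname(rep$counts["n_models"]), length(res$summaries))
  # geometry table has one row per model
  expect_equal(nrow(rep$geometry), length(res$summaries))
  # report bundle writes CSVs
  dir <- tempfile()
  write_report(aggregate_and_report(res), dir)
  expect_true(file.exists(file.path(dir, "full_latency.csv")))
  expect_true(file.exists(file.path(dir, "full_geometry.csv")))
  unlink(dir, recursive = TRUE)
})

test_that("experiment re-run from the same inputs is bit-identical", {
  ens <- test_ensemble()
  one <- structure(list(spec = ens$spec, members = ens$members[1],
                        reference = ens$reference),
                   class = "model_ensemble")
  a <- run_protocol_experiment(one, "half_only", schedule = "ci")
  b <- run_protocol_experiment(one, "half_only", schedule = "ci")
  expect_identical(a$latency, b$latency)
  expect_identical(a$final_intrinsic, b$final_intrinsic)
})

test_that("trace and manifest serialization round-trips", {
  tr <- ci_full_run()
  dir <- tempfile()
  write_trace(tr, dir)
  expect_true(file.exists(file.path(dir, "voltage.csv")))
  p <- read.csv(file.path(dir, "params.csv"), check.names = FALSE)
  expect_equal(nrow(p), length(tr$time_p))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$dt, tr$dt)
  expect_equal(unlist(man$gmax0), unlist(as.list(tr$intrinsic0$gmax)),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
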