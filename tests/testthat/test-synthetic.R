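test_that("modular time series hit the requested correlation structure", {
  spec <- modular_series_spec(n_nodes = 60, n_blocks = 6, rho_within = 0.6,
                              rho_between = 0.1, n_frames = 5000, seed = 11)
  ts <- generate_modular_timeseries(spec)
  expect_equal(dim(ts$values), c(60, 5000))
  r <- cor(t(ts$values))
  block <- attr(ts, "block")
  same <- outer(block, block, `==`) & upper.tri(r)
  diff_blk <- outer(block, block, `!=`) & upper.tri(r)
  expect_lt(abs(mean(r[same]) - 0.6), 0.05)
  expect_lt(abs(mean(r[diff_blk]) - 0.1), 0.05)
})

test_that("uncorrelated spec gives near-zero off-diagonal correlations", {
  spec <- modular_series_spec(n_nodes = 20, n_blocks = 4, rho_within = 0,
                              rho_between = 0, n_frames = 10000, seed = 2)
  r <- cor(t(generate_modular_timeseries(spec)$values))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)
})

test_that("generators are bit-reproducible under a fixed seed", {
  sspec <- modular_series_spec(10, 2, 0.4, 0.1, n_frames = 50, seed = 7)
  expect_identical(generate_modular_timeseries(sspec)$values,
                   generate_modular_timeseries(sspec)$values)
  expect_identical(generate_motion_trace(40, c(5, 20), 1, seed = 7),
                   generate_motion_trace(40, c(5, 20), 1, seed = 7))
  nspec <- nback_session_spec(n_trials = 50, seed = 7)
  expect_identical(generate_nback_session(nspec),
                   generate_nback_session(nspec))
  cspec <- cohort_spec(n_young = 5, n_old = 5, noise_sd = 0.3, seed = 7)
  expect_identical(generate_subject_cohort(cspec),
                   generate_subject_cohort(cspec))
})

test_that("infeasible correlation pairs are rejected", {
  expect_error(modular_series_spec(10, 2, 0.2, 0.5, n_frames = 50),
               "infeasible")
  expect_error(modular_series_spec(10, 20, 0.5, 0.2, n_frames = 50))
  expect_error(modular_series_spec(10, 2, 0.5, 0.2, n_frames = 2))
})

test_that("motion traces are quiet except exactly at the injected spikes", {
  m <- generate_motion_trace(100, spike_frames = c(10, 50), spike_fd = 1,
                             seed = 3)
  fd <- compute_fd(m)
  expect_equal(fd[c(9, 49)], c(1, 1))
  expect_true(all(fd[-c(9, 49)] < 0.1))
  clean <- generate_motion_trace(100, seed = 3)
  expect_true(all(compute_fd(clean) < 0.1))
  expect_error(generate_motion_trace(20, spike_frames = 25), "2..n_frames")
})

test_that("2-back sessions realise the requested target rate", {
  spec <- nback_session_spec(n_trials = 1000, target_rate = 0.3,
                             hit_rate = 1, fa_rate = 0, seed = 5)
  trials <- generate_nback_session(spec)
  scoreable <- trials[3:nrow(trials), ]
  expect_lt(abs(mean(scoreable$is_target) - 0.3), 0.05)
  # targets really are 2-back letter repeats
  lt <- trials$letter
  expect_identical(scoreable$is_target,
                   lt[3:length(lt)] == lt[1:(length(lt) - 2)])
  # perfect responder: no misses, no false alarms
  counts <- classify_trials(trials)
  expect_equal(counts$misses, 0)
  expect_equal(counts$false_alarms, 0)
})

test_that("the first two trials are never scoreable targets", {
  for (seed in 1:5) {
    trials <- generate_nback_session(nback_session_spec(n_trials = 30,
                                                        target_rate = 1,
                                                        seed = seed))
    expect_false(any(trials$is_target[1:2]))
    expect_identical(trials$response[1:2], c("none", "none"))
  }
})

test_that("noise-free cohorts reproduce their generating equations exactly", {
  cohort <- generate_subject_cohort(cohort_spec(n_young = 20, n_old = 20,
                                                noise_sd = 0, seed = 1))
  eq <- default_cohort_equations()
  for (i in seq_len(nrow(cohort))) {
    e <- if (cohort$age_group[i] == 0) eq$young else eq$old
    mu <- e[["intercept"]] + e[["e_local"]] * cohort$e_local_task[i] +
      e[["e_global"]] * cohort$e_global_task[i] + e[["rt"]] * cohort$mean_rt[i]
    expect_equal(cohort$dprime[i], mu)
  }
})

test_that("age contrast at fixed covariates equals the equation difference", {
  eq <- default_cohort_equations()
  cov <- list(e_local = 0.42, e_global = 0.27, rt = 900)
  cohort <- generate_subject_cohort(cohort_spec(
    n_young = 1, n_old = 1, noise_sd = 0,
    covariate_ranges = list(e_local_task = cov$e_local + c(0, 1e-9),
                            e_global_task = cov$e_global + c(0, 1e-9),
                            mean_rt = cov$rt + c(0, 1e-9),
                            n_volumes_removed = c(0, 1))))
  d_diff <- cohort$dprime[cohort$age_group == 1] -
    cohort$dprime[cohort$age_group == 0]
  expected <- (eq$old[["intercept"]] - eq$young[["intercept"]]) +
    (eq$old[["e_global"]] - eq$young[["e_global"]]) * cov$e_global
  expect_equal(d_diff, expected, tolerance = 1e-6)
})

test_that("cohort noise SD is recovered from residuals", {
  set.seed(9)
  reps <- replicate(30, {
    co <- generate_subject_cohort(cohort_spec(n_young = 50, n_old = 50,
                                              noise_sd = 0.3))
    eq <- default_cohort_equations()
    mu <- ifelse(co$age_group == 0,
                 eq$young[["intercept"]] + eq$young[["e_local"]] * co$e_local_task +
                   eq$young[["e_global"]] * co$e_global_task + eq$young[["rt"]] * co$mean_rt,
                 eq$old[["intercept"]] + eq$old[["e_local"]] * co$e_local_task +
                   eq$old[["e_global"]] * co$e_global_task + eq$old[["rt"]] * co$mean_rt)
    sd(co$dprime - mu)
  })
  expect_lt(abs(mean(reps) - 0.3) / 0.3, 0.15)
})

test_that("time-series TSV round-trips", {
  ts <- generate_modular_timeseries(modular_series_spec(5, 2, 0.3, 0.1,
                                                        n_frames = 20, seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries_tsv(ts, path)
  back <- read_timeseries_tsv(path, tr = ts$tr)
  expect_equal(back$values, ts$values, tolerance = 1e-12)
})
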