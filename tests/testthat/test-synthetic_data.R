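# Synthetic generator: trial structure, rate profiles, Poisson statistics,
# behaviour sampling, eye traces, populations.

test_that("generate_trials reproduces the task arithmetic", {
  task <- task_params(isi_set = 400, sequence_range = c(2000, 2000))
  tr <- generate_trials(1, task, p_missing = 1, seed = 3,
                        error_rates = c(missing_early = 0,
                                        missing_miss = 0,
                                        deviant_early = 0,
                                        deviant_miss = 0))
  expect_identical(stimulus_onsets(tr[1, ]),
                   c(0L, 400L, 800L, 1200L, 1600L))
  expect_identical(tr$oddball_time_ms, 2000L)
  # 600 ms ISI sequences are always >= 3000 ms
  task6 <- task_params(isi_set = 600)
  tr6 <- generate_trials(300, task6, p_missing = 1, seed = 4)
  expect_true(all(tr6$oddball_time_ms >= 3000 - 600))
  expect_true(all(attr(tr6, "sequence_length_raw") >= 3000))
})

test_that("sequence lengths are uniform on the stated range (KS)", {
  task <- task_params(isi_set = 400)
  tr <- generate_trials(10000, task, p_missing = 1, seed = 11)
  L <- attr(tr, "sequence_length_raw")
  p <- ks.test(L, "punif", 2000, 4800)$p.value
  expect_gt(p, 0.01)
})

test_that("rate profiles honour their construction", {
  trial <- make_trial()
  # zero repetition gain -> flat baseline (no saccade burst)
  flat <- rate_profile(trial, rate_profile_params("caudate_increase",
                                                  rep_max = 0,
                                                  saccade_burst = 0))
  expect_true(all(flat$rate == flat$rate[1]))
  expect_equal(flat$rate[1], 1)
  # dentate trough 200 ms after each stimulus (isi = 400)
  dp <- rate_profile(trial, rate_profile_params("dentate",
                                                saccade_burst = 0))
  for (on in stimulus_onsets(trial)) {
    seg <- dp$rate[dp$t >= on & dp$t < on + 400]
    expect_lte(abs(which.min(seg) - 1 - 200), 1)
  }
  # missing/deviant peak ratio is exactly the condition gain
  p <- rate_profile_params("caudate_increase", condition_gain = 1.7,
                           saccade_burst = 0)
  t_dev <- trial; t_dev$condition <- "deviant"
  r_miss <- rate_profile(trial, p)
  r_dev <- rate_profile(t_dev, p)
  expect_equal((max(r_miss$rate) - 1) / (max(r_dev$rate) - 1), 1.7)
  # unknown profile kind errors
  expect_error(rate_profile(trial, list(profile_kind = "nope")),
               "profile_kind")
})

test_that("dentate recovery ramp completes at the next stimulus onset for
           every ISI when recovery scales with the ISI", {
  p <- rate_profile_params("dentate", saccade_burst = 0)
  for (isi in c(300L, 400L, 600L)) {
    trial <- make_trial(isi = isi, n_stimuli = 5L)
    rp <- rate_profile(trial, p)
    for (on in stimulus_onsets(trial)) {
      seg <- rp$rate[rp$t >= on & rp$t < on + isi]
      # last ms of the interval is back at baseline (ramp max) within 2 ms
      ramp_top <- max(which(seg == max(seg[201:isi])))
      expect_lte(abs(ramp_top - isi), 2)
    }
  }
})

test_that("sample_spikes is an inhomogeneous Poisson sampler", {
  # zero rate -> empty
  z <- make_trace(rep(0, 1000))
  expect_length(sample_spikes(z, seed = 1), 0)
  # constant 50 spikes/s over 10 s: mean count 500 within 3 SE
  tr <- make_trace(rep(50, 10000))
  counts <- vapply(1:300, function(s) length(sample_spikes(tr, seed = s)),
                   0)
  se <- sqrt(500) / sqrt(300)
  expect_lt(abs(mean(counts) - 500), 3 * se)
  # pooled inter-spike intervals are exponential: the per-ms Bernoulli
  # yields geometric intervals; de-discretized (k - 1 + U(0,1)) they match
  # an exponential with rate -log(1 - p) exactly at every bin edge
  isi <- unlist(lapply(1:10, function(s)
    diff(sample_spikes(tr, seed = 1000 + s))))
  set.seed(99)
  isi_c <- isi - 1 + runif(length(isi))
  expect_gt(ks.test(isi_c, "pexp", -log(1 - 50 / 1000))$p.value, 0.01)
  # thinning agrees with Bernoulli in expectation
  counts_t <- vapply(1:300, function(s)
    length(sample_spikes(tr, seed = s, method = "thinning")), 0)
  expect_lt(abs(mean(counts_t) - 500), 3 * se)
})

test_that("expected spike count equals the rate integral for shaped
           profiles", {
  trial <- make_trial()
  for (kind in c("caudate_increase", "dentate")) {
    rp <- rate_profile(trial, rate_profile_params(kind,
                                                  saccade_burst = 0))
    expected <- sum(rp$rate) / 1000
    counts <- vapply(1:200, function(s)
      length(sample_spikes(rp, seed = s)), 0)
    se <- sd(counts) / sqrt(200)
    expect_lt(abs(mean(counts) - expected), 3 * se)
  }
})

test_that("sample_behavior couples rate to latency inside the stated
           window", {
  trial <- make_trial()
  # zero coupling -> zero perturbation
  b0 <- sample_behavior(trial, covariation_params(), seed = 5)
  expect_identical(b0$delta, 0)
  # omission-locked window placement
  cov <- covariation_params(coupling_strength = 0.2,
                            coupling_lock = "omission_locked",
                            coupling_onset = -400,
                            coupling_offset = -100)
  b <- sample_behavior(trial, cov, seed = 6)
  expect_identical(b$window,
                   c(trial$oddball_time_ms - 400,
                     trial$oddball_time_ms - 100))
  expect_equal(b$delta, 0.2 * (b$latency - 350))
  # saccade-locked window placement
  cov_s <- covariation_params(coupling_strength = 0.2,
                              coupling_lock = "saccade_locked",
                              coupling_onset = -300, coupling_offset = 0)
  bs <- sample_behavior(trial, cov_s, seed = 7)
  expect_identical(bs$window,
                   trial$oddball_time_ms + bs$latency + c(-300, 0))
  # Monte-Carlo latency mean within 2 SE
  lats <- vapply(1:5000, function(s)
    sample_behavior(trial, covariation_params(), seed = s)$latency, 0)
  expect_lt(abs(mean(lats) - 350), 2 * 58 / sqrt(5000))
})

test_that("eye traces close the loop with detect_saccade", {
  trial <- make_trial(latency = 250L)
  # zero noise: pre-saccade velocity exactly 0, amplitude exactly 16 deg
  ey <- generate_eye_trace(trial, 250, noise_sd = 0, seed = 1)
  pre <- ey$x_deg[ey$t_ms < 2100]
  expect_true(all(diff(pre) == 0))
  expect_equal(max(abs(ey$x_deg)), 16)
  ev <- detect_saccade(ey, 2000)
  expect_equal(ev$latency, 250)
  expect_gt(ev$peak_velocity, 60)
  # with noise: recovered within 2 ms, amplitude within 1 deg
  errs <- vapply(1:20, function(s) {
    ey <- generate_eye_trace(trial, 250, noise_sd = 0.1, seed = s)
    detect_saccade(ey, 2000)$latency - 250
  }, 0)
  expect_true(all(abs(errs) <= 2))
})

test_that("generation is bit-identical under a fixed seed", {
  s1 <- simulate_session(30, seed = 42, with_eyes = TRUE)
  s2 <- simulate_session(30, seed = 42, with_eyes = TRUE)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$eyes, s2$eyes)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(s1, d1); write_session(s2, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
})

test_that("build_population respects the mix and records a manifest", {
  expect_length(build_population(0), 0)
  pop <- build_population(5, c(dentate = 1), n_trials = 10, seed = 8)
  man <- attr(pop, "manifest")
  expect_identical(man$kind, rep("dentate", 5))
  expect_identical(man$structure, rep("dentate", 5))
  expect_setequal(vapply(pop, function(s) s$meta$structure, ""),
                  "dentate")
})
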