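# Latency sextiles, ms-wise ANOVA, run-length detection, bootstrap.

test_that("split_latency_sextiles forms ordered equal groups and discards
           the longest-latency remainder", {
  lat <- as.integer(c(310, 250, 420, 199, 333, 287, 401, 376, 222, 268,
                      350, 299))
  tr <- do.call(rbind, lapply(seq_along(lat), function(i)
    make_trial(i, latency = lat[i])))
  s <- make_session(tr)
  g <- split_latency_sextiles(s)
  expect_length(g$groups, 6)
  expect_identical(g$n_per_group, 2L)
  # group 1 holds the two shortest latencies
  expect_setequal(g$groups[[1]], which(rank(lat) <= 2))
  expect_true(all(diff(g$medians) > 0))
  # 62 trials -> 2 discarded (the longest), groups of 10
  set.seed(3)
  lat62 <- as.integer(sample(150:590, 62))
  tr62 <- do.call(rbind, lapply(seq_along(lat62), function(i)
    make_trial(i, latency = lat62[i])))
  g62 <- split_latency_sextiles(make_session(tr62))
  expect_identical(g62$n_per_group, 10L)
  kept <- unlist(g62$groups)
  discarded <- setdiff(seq_along(lat62), kept)
  expect_identical(sort(lat62[discarded]),
                   sort(lat62)[61:62])          # two longest dropped
  # too few trials errors (callers exclude the neuron)
  expect_error(split_latency_sextiles(make_session(make_trial())),
               "fewer than")
})

test_that("mswise_anova agrees with the aov oracle and handles the
           degenerate cases", {
  # all groups identical -> p = 1 everywhere
  set.seed(2)
  base <- matrix(rnorm(50 * 4), 50, 4)      # time x neuron
  arr <- array(0, dim = c(50, 6, 4))
  for (g in 1:6) arr[, g, ] <- base
  out <- mswise_anova(arr)
  expect_true(all(out$p == 1))
  expect_true(all(out$F_stat == 0))
  # strong separation at one ms
  set.seed(4)
  arr2 <- array(rnorm(1 * 6 * 20, sd = 0.01), dim = c(1, 6, 20))
  arr2[1, , ] <- arr2[1, , ] + seq(0.1, 0.6, by = 0.1)
  out2 <- mswise_anova(arr2)
  expect_lt(out2$p, 1e-6)
  # agreement with the textbook oracle at 50 random time points
  set.seed(5)
  arr3 <- array(rnorm(50 * 6 * 8), dim = c(50, 6, 8))
  out3 <- mswise_anova(arr3)
  for (t0 in sample(1:50, 10)) {
    byg <- lapply(1:6, function(g) arr3[t0, g, ])
    expect_equal(out3$p[t0], oracle_anova_p(byg), tolerance = 1e-10)
  }
  expect_error(mswise_anova(array(0, c(5, 6, 1))), ">= 2 neurons")
})

test_that("onset/offset detection follows the run-length rule", {
  tt <- seq(-800, 199)
  # p identically 1 -> undetected
  expect_true(is.na(detect_variation_onset(rep(1, 1000), tt)))
  # step: non-significant before -300, significant after -> onset -300
  p <- ifelse(tt < -300, 1, 0.001)
  expect_equal(detect_variation_onset(p, tt), -300)
  # offset: p = 0.5 everywhere -> window start
  expect_equal(detect_variation_offset(rep(0.5, 1000), tt), -800)
  # step: significant before -200, not after -> offset -200
  p2 <- ifelse(tt < -200, 0.001, 1)
  expect_equal(detect_variation_offset(p2, tt), -200)
  # a significant epoch shorter than the run gap does not stop the onset
  p3 <- rep(1, 1000)
  p3[tt >= -300] <- 0.001
  p3[tt >= -650 & tt < -640] <- 0.001     # isolated early blip
  expect_equal(detect_variation_onset(p3, tt), -300)
  # offset needs a full run of non-significance
  p4 <- rep(0.001, 1000)
  p4[tt >= -100 & tt < -40] <- 1          # 60 ms gap only
  expect_true(is.na(detect_variation_offset(p4, tt)))
})

test_that("group_population_matrix normalizes per neuron and identical
           groups give identical population traces", {
  task <- task_params(isi_set = 400)
  pop <- build_population(4, c(caudate_increase_long = 1), n_trials = 70,
                          task = task, seed = 71, p_missing = 1)
  arr <- suppressMessages(
    group_population_matrix(pop, "oddball", c(-400L, 100L)))
  expect_identical(dim(arr)[2:3], c(6L, 4L))
  for (j in 1:4) expect_equal(max(arr[, , j]), 1)
  # identical groups: feed the same trials to every group
  s <- pop[[1]]
  f <- filter_trials(s)
  ids <- f$trials$trial_id[f$trials$condition == "missing"][1:10]
  fake_groups <- structure(list(groups = rep(list(ids), 6),
                                medians = rep(300, 6), n_per_group = 10L),
                           class = "latency_groups")
  arr2 <- group_population_matrix(list(s, s), "oddball", c(-400L, 100L),
                                  groups = list(fake_groups, fake_groups))
  for (g in 2:6) expect_equal(arr2[, g, ], arr2[, 1, ])
  expect_true(all(mswise_anova(arr2)$p == 1))
})

test_that("injected covariation is recovered at the right time and
           alignment", {
  task <- task_params(isi_set = 400)
  covO <- covariation_params(coupling_strength = 0.15,
                             coupling_lock = "omission_locked",
                             coupling_onset = -400,
                             coupling_offset = 0)
  pop <- build_population(20, c(caudate_increase_long = 1), n_trials = 70,
                          task = task, cov = covO, seed = 72,
                          p_missing = 1,
                          profile_args = list(saccade_burst = 0))
  vt <- suppressMessages(
    variation_timing(pop, omission_window = c(-800, 0),
                     saccade_window = c(-400, 300)))
  sigma <- kernel_spec()$sigma
  expect_false(is.na(vt$onset))
  expect_lte(abs(vt$onset - (-400)), 2 * sigma + 10)
  # saccade-locked coupling ending at the saccade: offset near 0
  covS <- covariation_params(coupling_strength = 0.15,
                             coupling_lock = "saccade_locked",
                             coupling_onset = -600, coupling_offset = 0)
  popS <- build_population(20, c(caudate_increase_long = 1), n_trials = 70,
                           task = task, cov = covS, seed = 73,
                           p_missing = 1,
                           profile_args = list(saccade_burst = 0))
  vtS <- suppressMessages(
    variation_timing(popS, saccade_window = c(-400, 300)))
  expect_false(is.na(vtS$offset))
  expect_lte(abs(vtS$offset - 0), 2 * sigma + 10)
  # ordering mirrors the omission- vs saccade-locked construct
  expect_lt(vt$offset, vtS$offset)
})

test_that("bootstrap_variation_timing: identical neurons give zero-width
           CIs and the point sits inside", {
  task <- task_params(isi_set = 400)
  covO <- covariation_params(coupling_strength = 0.2,
                             coupling_lock = "omission_locked",
                             coupling_onset = -400,
                             coupling_offset = 0)
  one <- simulate_session(70, rate_profile_params("caudate_increase",
                                                  saccade_burst = 0),
                          task = task, cov = covO, seed = 74,
                          p_missing = 1)
  # literally identical neurons have zero across-neuron variance, so every
  # ms gets p = 1 (the committed zero-variance rule) and detection reports
  # undetected in every replicate
  bs <- suppressMessages(
    bootstrap_variation_timing(list(one, one, one), n_boot = 10,
                               seed = 3))
  expect_identical(bs$onset$n_undetected, 10L)
  expect_error(bootstrap_variation_timing(list(one)), ">= 2")
  pop <- build_population(10, c(caudate_increase_long = 1), n_trials = 70,
                          task = task, cov = covO, seed = 75,
                          p_missing = 1,
                          profile_args = list(saccade_burst = 0))
  bs2 <- suppressMessages(
    bootstrap_variation_timing(pop, n_boot = 40, seed = 4,
                               omission_window = c(-800, 0)))
  expect_gte(bs2$point$onset, bs2$onset$ci[1])
  expect_lte(bs2$point$onset, bs2$onset$ci[2])
})
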