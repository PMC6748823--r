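# Seeded synthetic generator: task-structured trials, deterministic rate
# profiles, inhomogeneous Poisson spikes, saccade latencies with optional
# rate covariation, eye traces, and whole populations.
#
# Defaults restate the task and the population statistics of the recorded
# data: ISIs 100-600 ms, 35 ms stimuli, sequences 2000-4800 ms (3000-4800
# for the 600 ms ISI), caudate transients peaking ~160 ms post-stimulus,
# dentate troughs ~200 ms post-stimulus with ISI-scaled recovery, a 1.7x
# missing/deviant gain, a 1.08x contra/ipsi gain, saccade latencies with SD
# 58 ms, and error rates of 11.3%/2.2% (missing) and 2.7%/0.9% (deviant).

#' Task parameters
#'
#' @param isi_set ISIs in ms used for missing-condition trials.
#' @param deviant_isi the single ISI used for deviant-condition trials.
#' @param stimulus_duration stimulus duration, ms.
#' @param sequence_range sequence length range (ms) before the oddball.
#' @param sequence_range_600 range for the 600 ms ISI.
#' @param pre_sequence_delay range of fixation-to-first-stimulus delay, ms.
#' @param fixation required initial fixation, ms.
#' @param response_window max saccade latency, ms.
#' @param target_eccentricity saccade target eccentricity, deg.
#' @return list of class `task_params`.
#' @export
task_params <- function(isi_set = c(100, 200, 300, 400, 600),
                        deviant_isi = 400,
                        stimulus_duration = 35,
                        sequence_range = c(2000, 4800),
                        sequence_range_600 = c(3000, 4800),
                        pre_sequence_delay = c(100, 400),
                        fixation = 2000,
                        response_window = 600,
                        target_eccentricity = 16) {
  structure(as.list(environment()), class = "task_params")
}

#' Rate-profile parameters
#'
#' Deterministic per-trial firing-rate profiles come in three kinds.
#' `caudate_increase`: a raised-cosine transient after every stimulus
#' (total duration `transient_width`, peaking `peak_latency` ms
#' post-stimulus) whose amplitude is
#' `amplitude * g(k) * isi_tuning(isi) * condition_gain * direction_gain`,
#' with the saturating repetition schedule `g(k) = rep_max *
#' (1 - rep_b * exp(-k / rep_a))`. `caudate_decrease`: the same transient
#' with a geometrically decaying schedule (largest for the first stimulus).
#' `dentate`: a linear descent to a trough `trough_latency` ms
#' post-stimulus followed by a linear ramp back to baseline that completes
#' at the next stimulus onset when `recovery_mode = "scales_with_isi"`, or
#' after `recovery_duration` ms when `"fixed_duration"`.
#'
#' @param profile_kind `"caudate_increase"`, `"caudate_decrease"` or
#'   `"dentate"`.
#' @param baseline baseline rate, spikes/s.
#' @param amplitude full-gain transient amplitude (trough depth for
#'   dentate), spikes/s.
#' @param peak_latency transient peak, ms post-stimulus (caudate).
#' @param transient_width raised-cosine total duration, ms (caudate).
#' @param trough_latency trough time, ms post-stimulus (dentate).
#' @param rep_a,rep_b,rep_max repetition schedule parameters.
#' @param isi_tuning named vector of per-ISI gains (names = ISI ms). The
#'   defaults restate the recovered long-tuned population curve for
#'   caudate kinds and a linear-in-ISI gain for dentate.
#' @param condition_gain missing/deviant amplitude ratio.
#' @param direction_gain contra/ipsi amplitude ratio.
#' @param recovery_mode `"scales_with_isi"` or `"fixed_duration"`
#'   (dentate).
#' @param recovery_duration ramp duration in `"fixed_duration"` mode, ms.
#' @param saccade_burst amplitude of a 100 ms raised-cosine burst centred
#'   on the saccade (caudate_increase only; 0 disables).
#' @return list of class `rate_profile_params`.
#' @export
rate_profile_params <- function(profile_kind = c("caudate_increase",
                                                 "caudate_decrease",
                                                 "dentate"),
                                baseline = NULL, amplitude = NULL,
                                peak_latency = 160, transient_width = 140,
                                trough_latency = 200,
                                rep_a = 3, rep_b = 1, rep_max = 1,
                                isi_tuning = NULL,
                                condition_gain = 1.7,
                                direction_gain = 1.08,
                                recovery_mode = c("scales_with_isi",
                                                  "fixed_duration"),
                                recovery_duration = 200,
                                saccade_burst = NULL) {
  profile_kind <- match.arg(profile_kind)
  recovery_mode <- match.arg(recovery_mode)
  baseline <- baseline %||%
    switch(profile_kind, caudate_increase = 1, caudate_decrease = 10,
           dentate = 50)
  amplitude <- amplitude %||%
    switch(profile_kind, caudate_increase = 40, caudate_decrease = 25,
           dentate = 30)
  isi_tuning <- isi_tuning %||% switch(profile_kind,
    caudate_increase = c(`100` = 0.09, `200` = 0.18, `300` = 0.43,
                         `400` = 0.64, `600` = 1.00),
    caudate_decrease = c(`100` = 0.09, `200` = 0.18, `300` = 0.43,
                         `400` = 0.64, `600` = 1.00),
    dentate = c(`100` = 100, `200` = 200, `300` = 300, `400` = 400,
                `600` = 600) / 600)
  saccade_burst <- saccade_burst %||%
    if (profile_kind == "caudate_increase") 15 else 0
  if (baseline < 0 || amplitude < 0 || condition_gain <= 0 ||
      direction_gain <= 0)
    stop("baseline/amplitude must be >= 0 and gains > 0")
  structure(as.list(environment()), class = "rate_profile_params")
}

#' Short-tuned ISI gain vector
#'
#' The recovered normalized modulation of short-tuned neurons
#' (preference at the 300-400 ms ISIs).
#' @export
short_tuned_gains <- function() {
  c(`100` = 0.15, `200` = 0.46, `300` = 0.88, `400` = 0.94, `600` = 0.59)
}

#' Latency / rate-covariation parameters
#'
#' Saccade latencies are Gaussian (mean `latency_mean`, SD `latency_sd`)
#' truncated to `(0, response_window]`. A trial-by-trial rate perturbation
#' of `coupling_strength * (latency - latency_mean)` spikes/s is added
#' inside `[coupling_onset, coupling_offset)` ms relative to the lock event
#' (stimulus omission or saccade initiation).
#'
#' @param latency_mean,latency_sd ms.
#' @param coupling_strength spikes/s per ms of latency deviation (0
#'   disables).
#' @param coupling_lock `"omission_locked"` or `"saccade_locked"`.
#' @param coupling_onset,coupling_offset window relative to the lock
#'   event, ms (`offset > onset`).
#' @param response_window truncation bound, ms.
#' @return list of class `covariation_params`.
#' @export
covariation_params <- function(latency_mean = 350, latency_sd = 58,
                               coupling_strength = 0,
                               coupling_lock = c("saccade_locked",
                                                 "omission_locked"),
                               coupling_onset = -400, coupling_offset = 0,
                               response_window = 600) {
  coupling_lock <- match.arg(coupling_lock)
  if (coupling_offset <= coupling_onset)
    stop("coupling_offset must exceed coupling_onset")
  structure(as.list(environment()), class = "covariation_params")
}

# repetition schedule
rep_gain <- function(k, params) {
  if (params$profile_kind == "caudate_decrease")
    params$rep_max * exp(-(k - 1) / params$rep_a)
  else
    params$rep_max * (1 - params$rep_b * exp(-k / params$rep_a))
}

isi_gain <- function(isi, params) {
  g <- params$isi_tuning[as.character(isi)]
  if (is.na(g)) stop("no isi_tuning entry for ISI ", isi)
  unname(g)
}

#' Generate task-structured trial records
#'
#' Conditions, ISIs and target directions are assigned pseudorandomly;
#' sequence lengths are uniform on the task range (3000-4800 ms for the
#' 600 ms ISI) and rounded down to a whole number of stimuli; outcomes are
#' drawn with the stated error rates and correct trials receive a
#' truncated-Gaussian saccade latency.
#'
#' @param n_trials number of trials.
#' @param task a [task_params()].
#' @param cov a [covariation_params()] (latency distribution only; coupling
#'   is applied by [simulate_session()]).
#' @param p_missing probability of the missing condition (default 0.5).
#' @param error_rates named vector: `missing_early`, `missing_miss`,
#'   `deviant_early`, `deviant_miss`.
#' @param seed integer seed.
#' @return trial data.frame (see [new_session()]) with attribute
#'   `sequence_length_raw` (the continuous lengths drawn before rounding).
#' @export
generate_trials <- function(n_trials, task = task_params(),
                            cov = covariation_params(), p_missing = 0.5,
                            error_rates = c(missing_early = 0.113,
                                            missing_miss = 0.022,
                                            deviant_early = 0.027,
                                            deviant_miss = 0.009),
                            seed = 1) {
  stopifnot(n_trials > 0)
  set.seed(seed)
  condition <- ifelse(runif(n_trials) < p_missing, "missing", "deviant")
  isi <- ifelse(condition == "missing",
                task$isi_set[sample.int(length(task$isi_set), n_trials,
                                        replace = TRUE)],
                task$deviant_isi)
  rng <- function(i) if (i == 600) task$sequence_range_600 else
    task$sequence_range
  L <- vapply(isi, function(i) runif(1, rng(i)[1], rng(i)[2]), 0)
  n_stim <- as.integer(floor(L / isi))
  oddball <- n_stim * as.integer(isi)
  dirn <- sample(c("contra", "ipsi"), n_trials, replace = TRUE)
  outcome <- character(n_trials)
  latency <- rep(NA_integer_, n_trials)
  fixation <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    er <- if (condition[i] == "missing")
      error_rates[c("missing_early", "missing_miss")]
    else error_rates[c("deviant_early", "deviant_miss")]
    u <- runif(1)
    if (u < er[1]) {
      outcome[i] <- "early_error"
      fixation[i] <- as.integer(round(runif(1, 300, oddball[i])))
    } else if (u < er[1] + er[2]) {
      outcome[i] <- "miss"
      fixation[i] <- oddball[i] + cov$response_window
    } else {
      outcome[i] <- "correct"
      latency[i] <- draw_latency(cov)
      fixation[i] <- oddball[i] + latency[i]
    }
  }
  tr <- data.frame(trial_id = seq_len(n_trials), condition = condition,
                   isi_ms = as.integer(isi), n_stimuli = n_stim,
                   oddball_time_ms = oddball, target_direction = dirn,
                   outcome = outcome, saccade_latency_ms = latency,
                   fixation_ms = as.integer(fixation), stimulated = FALSE,
                   stringsAsFactors = FALSE)
  attr(tr, "sequence_length_raw") <- L
  tr
}

draw_latency <- function(cov) {
  repeat {
    l <- rnorm(1, cov$latency_mean, cov$latency_sd)
    if (l > 0 && l <= cov$response_window) return(as.integer(round(l)))
  }
}

#' Deterministic firing-rate profile for one trial
#'
#' Builds the trial's rate on the integer ms grid
#' `[-500, oddball_time + 800)` from the profile parameters (see
#' [rate_profile_params()]); the grid extends past the response window
#' because recording continues through the reward epoch. Rates are
#' clipped at zero.
#'
#' @param trial one-row trial data.frame.
#' @param params a [rate_profile_params()].
#' @return a [rate_trace()] aligned to the first stimulus.
#' @export
rate_profile <- function(trial, params) {
  if (!inherits(params, "rate_profile_params"))
    stop("unknown profile_kind: pass a rate_profile_params()")
  t0 <- -500L
  t1 <- trial$oddball_time_ms + 800L
  tt <- seq.int(t0, t1 - 1L)
  r <- rep(params$baseline, length(tt))
  isi <- trial$isi_ms
  gain_cd <- (if (trial$condition == "missing") params$condition_gain
              else 1) *
    (if (trial$target_direction == "contra") params$direction_gain else 1)
  onsets <- stimulus_onsets(trial)
  n <- length(tt)
  # indices of trial-clock time x on the grid: x - t0 + 1
  if (params$profile_kind == "dentate") {
    tl <- min(params$trough_latency, max(1L, isi %/% 2L))
    ramp_end <- if (params$recovery_mode == "scales_with_isi") isi
      else min(isi, tl + params$recovery_duration)
    rs <- seq.int(0L, isi - 1L)
    dep <- numeric(isi)
    down <- rs < tl
    dep[down] <- rs[down] / tl
    up <- !down & rs < ramp_end
    dep[up] <- 1 - (rs[up] - tl) / (ramp_end - tl)
    for (k in seq_along(onsets)) {
      amp <- params$amplitude * rep_gain(k, params) *
        isi_gain(isi, params) * gain_cd
      if (amp == 0) next
      i0 <- onsets[k] - t0 + 1L
      r[i0:(i0 + isi - 1L)] <- r[i0:(i0 + isi - 1L)] - amp * dep
    }
  } else {
    w <- params$transient_width
    bump <- 0.5 * (1 - cos(2 * pi * seq.int(0L, ceiling(w)) / w))
    for (k in seq_along(onsets)) {
      amp <- params$amplitude * rep_gain(k, params) *
        isi_gain(isi, params) * gain_cd
      if (amp == 0) next
      i0 <- as.integer(round(onsets[k] + params$peak_latency - w / 2)) -
        t0 + 1L
      idx <- i0:(i0 + length(bump) - 1L)
      keep <- idx >= 1L & idx <= n
      r[idx[keep]] <- r[idx[keep]] + amp * bump[keep]
    }
  }
  if (params$saccade_burst > 0 && !is.na(trial$saccade_latency_ms)) {
    sc <- trial$oddball_time_ms + trial$saccade_latency_ms
    burst <- 0.5 * (1 - cos(2 * pi * seq.int(0L, 100L) / 100))
    idx <- (sc - 50L - t0 + 1L):(sc + 50L - t0 + 1L)
    keep <- idx >= 1L & idx <= n
    r[idx[keep]] <- r[idx[keep]] + params$saccade_burst * burst[keep]
  }
  rate_trace(pmax(r, 0), c(t0, t1), "first_stimulus")
}

#' Sample a spike train from a rate trace
#'
#' Inhomogeneous Poisson sampling, either as an independent per-ms
#' Bernoulli with p = rate/1000 (default; exact for rates well below
#' 1000 spikes/s on the 1 ms analysis grid) or by exact thinning of a
#' homogeneous process at the peak rate, with times floored to the ms
#' grid.
#'
#' @param rate a [rate_trace()] (nonnegative everywhere).
#' @param seed integer seed.
#' @param method `"bernoulli"` or `"thinning"`.
#' @return sorted numeric vector of spike times (ms, trial clock).
#' @export
sample_spikes <- function(rate, seed = 1,
                          method = c("bernoulli", "thinning")) {
  method <- match.arg(method)
  set.seed(seed)
  if (method == "bernoulli") {
    p <- pmin(rate$rate / 1000, 1)
    rate$t[runif(length(p)) < p]
  } else {
    lmax <- max(rate$rate)
    if (lmax == 0) return(numeric(0))
    dur <- diff(rate$window)
    n <- rpois(1, lmax * dur / 1000)
    cand <- sort(runif(n, rate$window[1], rate$window[2]))
    lam <- rate$rate[floor(cand) - rate$window[1] + 1L]
    floor(cand[runif(n) < lam / lmax])
  }
}

#' Sample behaviour (latency + rate perturbation) for one trial
#'
#' @param trial one-row correct trial.
#' @param cov a [covariation_params()].
#' @param seed integer seed.
#' @return list: `latency` (ms), `delta` (spikes/s perturbation,
#'   `coupling_strength * (latency - latency_mean)`), `window` (absolute
#'   trial-clock ms window `[on, off)` where the perturbation applies).
#' @export
sample_behavior <- function(trial, cov, seed = 1) {
  stopifnot(trial$outcome == "correct")
  set.seed(seed)
  latency <- draw_latency(cov)
  delta <- cov$coupling_strength * (latency - cov$latency_mean)
  lock <- if (cov$coupling_lock == "omission_locked")
    trial$oddball_time_ms else trial$oddball_time_ms + latency
  list(latency = latency, delta = delta,
       window = c(lock + cov$coupling_onset, lock + cov$coupling_offset))
}

# minimum-jerk position profile on s in [0,1]
minjerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

# time (ms) at which the ideal min-jerk speed crosses `thr` deg/s
minjerk_cross_ms <- function(amplitude, duration, thr = 60) {
  cc <- thr * (duration / 1000) / (30 * amplitude)
  s <- (1 - sqrt(max(0, 1 - 4 * sqrt(cc)))) / 2
  s * duration
}

#' Generate a 1 kHz eye trace for a correct trial
#'
#' Low-pass-filtered fixation noise followed by a minimum-jerk saccade of
#' `target_eccentricity` degrees (duration ~40 ms, peak velocity far above
#' 60 deg/s). The configured latency marks the time at which the ideal eye
#' speed crosses the 60 deg/s detection criterion — the operational
#' definition of saccade onset in this paradigm — so [detect_saccade()]
#' recovers it to within ~2 ms.
#'
#' @param trial one-row correct trial.
#' @param latency saccade latency, ms from the oddball.
#' @param task a [task_params()].
#' @param noise_sd fixation position noise SD, deg (default 0.1; 0 gives
#'   exactly zero pre-saccade velocity).
#' @param duration saccade duration, ms.
#' @param seed integer seed.
#' @return data.frame `t_ms`, `x_deg`, `y_deg` on
#'   `[-200, oddball + 600)`.
#' @export
generate_eye_trace <- function(trial, latency, task = task_params(),
                               noise_sd = 0.1, duration = 40, seed = 1) {
  stopifnot(trial$outcome == "correct")
  set.seed(seed)
  t0 <- -200L
  tt <- seq.int(t0, trial$oddball_time_ms + 600L)
  n <- length(tt)
  noise <- function() {
    if (noise_sd == 0) return(rep(0, n))
    z <- stats::filter(rnorm(n + 50), rep(1 / 51, 51), sides = 2)
    z <- z[!is.na(z)][1:n]
    z * noise_sd / sd(z)
  }
  amp <- task$target_eccentricity *
    (if (trial$target_direction == "contra") 1 else -1)
  move_start <- trial$oddball_time_ms + latency -
    minjerk_cross_ms(abs(amp), duration)
  s <- pmin(pmax((tt - move_start) / duration, 0), 1)
  x <- amp * minjerk(s) + noise()
  y <- noise()
  data.frame(t_ms = tt, x_deg = x, y_deg = y)
}

#' Simulate a full session for one neuron
#'
#' Orchestrates [generate_trials()], [rate_profile()],
#' [sample_behavior()] (replacing the provisional latency so that the rate
#' perturbation and latency are coupled), [sample_spikes()] and optionally
#' [generate_eye_trace()]. Fully deterministic under `seed`.
#'
#' @param n_trials number of trials.
#' @param profile a [rate_profile_params()].
#' @param task a [task_params()].
#' @param cov a [covariation_params()].
#' @param seed integer seed.
#' @param neuron_id,structure,animal session metadata.
#' @param with_eyes also generate eye traces for correct trials?
#' @param spike_method passed to [sample_spikes()].
#' @param p_missing,error_rates passed to [generate_trials()].
#' @return an `oddball_session` with attribute `ground_truth` (the
#'   generating parameters).
#' @export
simulate_session <- function(n_trials = 100,
                             profile = rate_profile_params(),
                             task = task_params(),
                             cov = covariation_params(),
                             seed = 1, neuron_id = "sim-1",
                             structure = if (profile$profile_kind ==
                                             "dentate") "dentate"
                                         else "caudate",
                             animal = "sim",
                             with_eyes = FALSE,
                             spike_method = "bernoulli",
                             p_missing = 0.5,
                             error_rates = c(missing_early = 0.113,
                                             missing_miss = 0.022,
                                             deviant_early = 0.027,
                                             deviant_miss = 0.009)) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L + 3L * n_trials)
  tr <- generate_trials(n_trials, task, cov, p_missing, error_rates,
                        seed = sub_seeds[1])
  spikes <- vector("list", n_trials)
  eyes <- if (with_eyes) list() else NULL
  for (i in seq_len(n_trials)) {
    row <- tr[i, ]
    pert <- NULL
    if (row$outcome == "correct") {
      beh <- sample_behavior(row, cov, seed = sub_seeds[2L + 3L * i - 2L])
      tr$saccade_latency_ms[i] <- beh$latency
      tr$fixation_ms[i] <- row$oddball_time_ms + beh$latency
      row$saccade_latency_ms <- beh$latency
      pert <- beh
    }
    rt <- rate_profile(row, profile)
    if (!is.null(pert) && pert$delta != 0) {
      sel <- rt$t >= pert$window[1] & rt$t < pert$window[2]
      rt$rate[sel] <- pmax(rt$rate[sel] + pert$delta, 0)
    }
    spikes[[i]] <- sample_spikes(rt, seed = sub_seeds[2L + 3L * i - 1L],
                                 method = spike_method)
    if (with_eyes && row$outcome == "correct")
      eyes[[as.character(row$trial_id)]] <-
        generate_eye_trace(row, tr$saccade_latency_ms[i], task,
                           seed = sub_seeds[2L + 3L * i])
  }
  names(spikes) <- as.character(tr$trial_id)
  s <- new_session(tr, spikes, eyes,
                   meta = list(neuron_id = neuron_id,
                               structure = structure, animal = animal))
  attr(s, "ground_truth") <- list(profile = profile, cov = cov,
                                  task = task, seed = seed,
                                  n_correct = sum(tr$outcome == "correct"))
  s
}

#' Simulate a population of neurons
#'
#' @param n_neurons number of neurons (0 gives an empty list).
#' @param mix named proportions (summing to 1) over the kinds
#'   `"caudate_increase_long"`, `"caudate_increase_short"`,
#'   `"caudate_decrease"`, `"dentate"`.
#' @param n_trials trials per neuron.
#' @param task,cov shared task/covariation parameters.
#' @param jitter list: `peak_latency_sd` (ms, default 75, the across-neuron
#'   spread of transient peaks), `amplitude_cv` (lognormal CV, default
#'   0.2), `tuning_sd` (multiplicative ISI-tuning noise, default 0.1).
#' @param profile_args extra arguments passed to every neuron's
#'   [rate_profile_params()] (e.g. `saccade_burst = 0` to isolate injected
#'   latency covariation in recovery experiments).
#' @param seed integer seed.
#' @param ... passed to [simulate_session()].
#' @return list of sessions with attribute `manifest` (data.frame of
#'   ground-truth kind/tuning and jittered parameters per neuron).
#' @export
build_population <- function(n_neurons,
                             mix = c(caudate_increase_long = 1),
                             n_trials = 100, task = task_params(),
                             cov = covariation_params(),
                             jitter = list(), profile_args = list(),
                             seed = 1, ...) {
  stopifnot(abs(sum(mix) - 1) < 1e-8)
  if (n_neurons == 0)
    return(structure(list(), manifest = data.frame()))
  jit <- utils::modifyList(list(peak_latency_sd = 75, amplitude_cv = 0.2,
                                tuning_sd = 0.1), jitter)
  set.seed(seed)
  kinds <- sample(names(mix), n_neurons, replace = TRUE, prob = mix)
  seeds <- sample.int(.Machine$integer.max - 1L, n_neurons)
  sessions <- vector("list", n_neurons)
  man <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    set.seed(seeds[i])
    kind <- kinds[i]
    base_kind <- switch(kind,
      caudate_increase_long = , caudate_increase_short = "caudate_increase",
      kind)
    tun <- if (kind == "caudate_increase_short") short_tuned_gains()
      else rate_profile_params(base_kind)$isi_tuning
    tun <- tun * exp(rnorm(length(tun), 0, jit$tuning_sd))
    prof_base <- list(
      profile_kind = base_kind,
      peak_latency = max(60, min(400,
                                 rnorm(1, 160, jit$peak_latency_sd))),
      amplitude = rate_profile_params(base_kind)$amplitude *
        exp(rnorm(1, 0, jit$amplitude_cv)),
      isi_tuning = tun / max(tun))
    prof <- do.call(rate_profile_params,
                    utils::modifyList(prof_base, as.list(profile_args)))
    sessions[[i]] <- simulate_session(
      n_trials, prof, task, cov, seed = seeds[i],
      neuron_id = sprintf("sim-%03d", i), ...)
    man[[i]] <- data.frame(
      neuron_id = sprintf("sim-%03d", i), kind = kind,
      structure = if (base_kind == "dentate") "dentate" else "caudate",
      tuning_label = if (which.max(tun) == length(tun)) "long_tuned"
        else "short_tuned",
      preferred_isi = as.integer(names(tun)[which.max(tun)]),
      peak_latency = prof$peak_latency, amplitude = prof$amplitude,
      seed = seeds[i])
  }
  structure(sessions, manifest = do.call(rbind, man))
}

#' Simulate microstimulation experiments (behaviour only)
#'
#' Generates `n_sessions` sessions whose trials carry a `stimulated` flag;
#' stimulated trials have their latency mean shifted by the per-cell
#' `effects` (negative = facilitation) and their SD scaled by `sd_scale`.
#' Spike trains are empty (the stimulation analysis is purely behavioural).
#'
#' @param n_sessions number of stimulation sessions (the study ran 29).
#' @param n_per_cell correct trials per condition x direction x stim cell.
#' @param effects named latency shifts (ms): `missing_contra`,
#'   `missing_ipsi`, `deviant_contra`, `deviant_ipsi`.
#' @param sd_scale stimulated-trial latency SD multiplier (default
#'   47.1/58.0, the recovered population ratio).
#' @param cov latency distribution.
#' @param seed integer seed.
#' @return list of `oddball_session`s.
#' @export
generate_stim_experiment <- function(n_sessions = 29, n_per_cell = 15,
                                     effects = c(missing_contra = -40,
                                                 missing_ipsi = -20,
                                                 deviant_contra = 0,
                                                 deviant_ipsi = -5),
                                     sd_scale = 47.1 / 58.0,
                                     cov = covariation_params(),
                                     seed = 1) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  cells <- expand.grid(condition = c("missing", "deviant"),
                       target_direction = c("contra", "ipsi"),
                       stimulated = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  lapply(seq_len(n_sessions), function(s) {
    set.seed(seeds[s])
    rows <- list()
    id <- 0L
    for (j in seq_len(nrow(cells))) {
      for (r in seq_len(n_per_cell)) {
        id <- id + 1L
        shift <- if (cells$stimulated[j])
          effects[paste(cells$condition[j], cells$target_direction[j],
                        sep = "_")] else 0
        sdv <- cov$latency_sd * if (cells$stimulated[j]) sd_scale else 1
        lat <- 0
        while (lat <= 0 || lat > cov$response_window)
          lat <- rnorm(1, cov$latency_mean + shift, sdv)
        isi <- 400L; nst <- sample(5:12, 1)
        rows[[id]] <- data.frame(
          trial_id = id, condition = cells$condition[j], isi_ms = isi,
          n_stimuli = nst, oddball_time_ms = nst * isi,
          target_direction = cells$target_direction[j],
          outcome = "correct",
          saccade_latency_ms = as.integer(round(lat)),
          fixation_ms = nst * isi + as.integer(round(lat)),
          stimulated = cells$stimulated[j], stringsAsFactors = FALSE)
      }
    }
    tr <- do.call(rbind, rows)
    spikes <- stats::setNames(
      rep(list(numeric(0)), nrow(tr)), as.character(tr$trial_id))
    new_session(tr, spikes,
                meta = list(neuron_id = sprintf("stim-%02d", s),
                            structure = "caudate", animal = "sim"))
  })
}
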