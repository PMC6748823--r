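# Neuron classification, condition/direction contrasts and ISI duration
# tuning.

#' Classify a neuron as increase/decrease/flat/other
#'
#' Regresses the per-stimulus firing modulation (from
#' [per_stimulus_series()]) on the stimulus ordinal. `increase` if the
#' slope is positive at `alpha`, `decrease` if negative, `flat` otherwise.
#' Neurons whose mean per-stimulus modulation is below twice the standard
#' error of the mean baseline rate (spike counts in the 100 ms before the
#' first stimulus, across trials) are labelled `other` (no reliable
#' stimulus-locked modulation).
#'
#' @param session an `oddball_session` (correct trials are selected
#'   internally).
#' @param isi,condition analysed ISI (default 400) and condition.
#' @param alpha slope significance level (default 0.05).
#' @param min_trials per-ordinal minimum for the series.
#' @return list of class `type_classification`: `label`, `slope`,
#'   `p_value`, `series`.
#' @export
classify_response_type <- function(session, isi = 400,
                                   condition = "missing", alpha = 0.05,
                                   min_trials = 5) {
  s <- filter_trials(session)
  sel <- s$trials$condition == condition & s$trials$isi_ms == isi
  s <- subset_session(s, s$trials$trial_id[sel])
  if (nrow(s$trials) == 0 || mean(s$trials$n_stimuli) < 4)
    stop("classify_response_type: fewer than 4 stimuli per trial on ",
         "average")
  series <- per_stimulus_series(s, isi = isi, condition = condition,
                                min_trials = min_trials)
  if (nrow(series) < 3)
    stop("classify_response_type: too few stimulus ordinals")
  ras <- align_raster(s, "first_stimulus", c(-100L, 0L))
  base_rates <- rowSums(raster_core(ras)) / 0.1
  base_se <- if (length(base_rates) > 1)
    sd(base_rates) / sqrt(length(base_rates)) else 0
  fit <- lm(modulation ~ ordinal, data = series)
  slope <- unname(coef(fit)[2])
  p <- summary(fit)$coefficients[2, 4]
  label <- if (mean(series$modulation) < 2 * base_se) "other"
    else if (p < alpha && slope > 0) "increase"
    else if (p < alpha && slope < 0) "decrease"
    else "flat"
  structure(list(label = label, slope = slope, p_value = p,
                 series = series),
            class = "type_classification")
}

# per-neuron max 100 ms rate before the oddball for one condition, plus
# per-trial rates at the max window (for the rank-sum test)
neuron_peak_rates <- function(session, condition, isi, window_before = 400,
                              bin = 100) {
  s <- filter_trials(session)
  sel <- s$trials$condition == condition & s$trials$isi_ms == isi
  if (!any(sel)) return(NULL)
  s <- subset_session(s, s$trials$trial_id[sel])
  ras <- align_raster(s, "oddball", c(-window_before, 0L))
  ex <- windowed_rate_extrema(ras, bin = bin)
  core <- raster_core(ras)
  i0 <- ex$max_time - (-window_before) + 1L
  trial_rates <- rowSums(core[, i0:(i0 + bin - 1L), drop = FALSE]) /
    bin * 1000
  list(max_rate = ex$max_rate, max_time = ex$max_time,
       trial_rates = trial_rates)
}

#' Missing vs deviant condition contrast across neurons
#'
#' For each neuron, the maximal 100 ms firing rate in the
#' `window_before` ms preceding the oddball is measured per condition
#' (sliding window); per-neuron significance uses a Wilcoxon rank-sum test
#' on per-trial rates at the peak window (optionally Bonferroni-corrected
#' across neurons); the population is summarised by a paired t-test and the
#' ratio of mean peak rates (missing / deviant).
#'
#' @param sessions list of `oddball_session`s.
#' @param isi analysed ISI (default 400, the ISI shared by both
#'   conditions).
#' @param window_before ms before the oddball (default 400).
#' @param alpha per-neuron significance level.
#' @param bonferroni correct per-neuron p-values across neurons?
#' @return list of class `condition_contrast`: `per_neuron` (data.frame),
#'   `ratio`, `t_statistic`, `df`, `p_value`, `n_significant`.
#' @export
condition_contrast <- function(sessions, isi = 400, window_before = 400,
                               alpha = 0.05, bonferroni = TRUE) {
  rows <- list()
  for (s in sessions) {
    m <- neuron_peak_rates(s, "missing", isi, window_before)
    d <- neuron_peak_rates(s, "deviant", isi, window_before)
    if (is.null(m) || is.null(d)) {
      message("condition_contrast: skipping neuron ", s$meta$neuron_id,
              " (missing a condition)")
      next
    }
    p <- suppressWarnings(
      wilcox.test(m$trial_rates, d$trial_rates)$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      neuron_id = s$meta$neuron_id, missing_max = m$max_rate,
      deviant_max = d$max_rate, p_value = p)
  }
  if (length(rows) < 2) stop("condition_contrast: need >= 2 usable neurons")
  pn <- do.call(rbind, rows)
  p_adj <- if (bonferroni) pmin(pn$p_value * nrow(pn), 1) else pn$p_value
  pn$significant <- !is.na(p_adj) & p_adj < alpha
  tt <- paired_t_safe(pn$missing_max, pn$deviant_max)
  structure(list(per_neuron = pn,
                 ratio = mean(pn$missing_max) / mean(pn$deviant_max),
                 t_statistic = tt$statistic,
                 df = tt$parameter, p_value = tt$p.value,
                 n_significant = sum(pn$significant)),
            class = "condition_contrast")
}

#' Contralateral vs ipsilateral direction bias
#'
#' Per neuron, the maximal 100 ms pre-oddball rate for each saccade-target
#' direction (missing condition); the population bias is the least-squares
#' slope of contra on ipsi constrained through the origin, plus a paired
#' t-test across neurons.
#'
#' @inheritParams condition_contrast
#' @param condition condition analysed (default `"missing"`).
#' @return list of class `direction_bias`: `per_neuron`, `slope`,
#'   `t_statistic`, `df`, `p_value`, `n_significant`.
#' @export
direction_bias <- function(sessions, isi = 400, condition = "missing",
                           window_before = 400, alpha = 0.05,
                           bonferroni = FALSE) {
  rows <- list()
  for (s in sessions) {
    byd <- lapply(c(contra = "contra", ipsi = "ipsi"), function(dirn) {
      f <- filter_trials(s)
      sel <- f$trials$condition == condition & f$trials$isi_ms == isi &
        f$trials$target_direction == dirn
      if (!any(sel)) return(NULL)
      sub <- subset_session(f, f$trials$trial_id[sel])
      ras <- align_raster(sub, "oddball", c(-window_before, 0L))
      ex <- windowed_rate_extrema(ras, bin = 100)
      core <- raster_core(ras)
      i0 <- ex$max_time + window_before + 1L
      list(max = ex$max_rate,
           trial_rates = rowSums(core[, i0:(i0 + 99L), drop = FALSE]) /
             0.1)
    })
    if (is.null(byd$contra) || is.null(byd$ipsi)) next
    p <- suppressWarnings(
      wilcox.test(byd$contra$trial_rates, byd$ipsi$trial_rates)$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      neuron_id = s$meta$neuron_id, contra_max = byd$contra$max,
      ipsi_max = byd$ipsi$max, p_value = p)
  }
  if (length(rows) < 2) stop("direction_bias: need >= 2 usable neurons")
  pn <- do.call(rbind, rows)
  p_adj <- if (bonferroni) pmin(pn$p_value * nrow(pn), 1) else pn$p_value
  pn$significant <- !is.na(p_adj) & p_adj < alpha
  slope <- sum(pn$contra_max * pn$ipsi_max) / sum(pn$ipsi_max^2)
  tt <- paired_t_safe(pn$contra_max, pn$ipsi_max)
  structure(list(per_neuron = pn, slope = slope,
                 t_statistic = tt$statistic,
                 df = tt$parameter, p_value = tt$p.value,
                 n_significant = sum(pn$significant)),
            class = "direction_bias")
}

#' ISI duration tuning of one neuron
#'
#' Firing modulation (kernel-density max - min) over the last complete
#' inter-stimulus period before the oddball, per ISI, normalized to the
#' maximum. `long_tuned` iff the preferred ISI is the longest tested.
#'
#' @param session an `oddball_session`.
#' @param kernel a [kernel_spec()].
#' @param condition condition analysed (default `"missing"`).
#' @param min_trials minimum correct trials per ISI (default 5).
#' @param min_isis minimum number of ISIs (default 3).
#' @return list of class `tuning_result`: `isi_values`, `modulation`,
#'   `normalized`, `preferred_isi`, `label`.
#' @export
duration_tuning <- function(session, kernel = kernel_spec(),
                            condition = "missing", min_trials = 5,
                            min_isis = 3) {
  s <- filter_trials(session)
  sel <- s$trials$condition == condition
  s <- subset_session(s, s$trials$trial_id[sel])
  isis <- sort(unique(s$trials$isi_ms))
  mod <- numeric(0); used <- integer(0)
  for (isi in isis) {
    ids <- s$trials$trial_id[s$trials$isi_ms == isi]
    if (length(ids) < min_trials) next
    sub <- subset_session(s, ids)
    ras <- align_raster(sub, "last_stimulus", c(0L, isi),
                        pad = kernel$half)
    tr <- spike_density(ras, kernel)
    mod <- c(mod, firing_modulation(tr)$modulation)
    used <- c(used, isi)
  }
  if (length(used) < min_isis)
    stop("duration_tuning: fewer than ", min_isis, " ISIs with >= ",
         min_trials, " trials")
  normalized <- mod / max(mod)
  pref <- used[which.max(mod)]
  structure(list(isi_values = used, modulation = mod,
                 normalized = normalized, preferred_isi = pref,
                 label = if (pref == max(used)) "long_tuned"
                   else "short_tuned"),
            class = "tuning_result")
}

#' Population summary of duration tuning
#'
#' Mean normalized modulation per ISI within each tuning label.
#'
#' @param results list of [duration_tuning()] results.
#' @return named list per label: data.frame `isi`, `mean_normalized`, `n`.
#' @export
tuning_population_summary <- function(results) {
  stopifnot(length(results) >= 1)
  labels <- unique(vapply(results, `[[`, "", "label"))
  out <- list()
  for (lb in labels) {
    rs <- Filter(function(r) r$label == lb, results)
    isis <- sort(unique(unlist(lapply(rs, `[[`, "isi_values"))))
    mn <- vapply(isis, function(i) {
      v <- unlist(lapply(rs, function(r) r$normalized[r$isi_values == i]))
      mean(v)
    }, 0)
    nn <- vapply(isis, function(i)
      sum(vapply(rs, function(r) i %in% r$isi_values, TRUE)), 0L)
    out[[lb]] <- data.frame(isi = isis, mean_normalized = mn, n = nn)
  }
  out
}
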