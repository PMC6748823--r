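# Shared fixture builders. Everything is generated in code; no data files.

# minimal hand-built trial table
make_trial <- function(trial_id = 1L, condition = "missing", isi = 400L,
                       n_stimuli = 5L, direction = "contra",
                       outcome = "correct", latency = 300L,
                       oddball = NULL, stimulated = FALSE) {
  oddball <- oddball %||% (n_stimuli * isi)
  data.frame(
    trial_id = trial_id, condition = condition, isi_ms = isi,
    n_stimuli = n_stimuli, oddball_time_ms = as.integer(oddball),
    target_direction = direction, outcome = outcome,
    saccade_latency_ms = if (outcome == "correct") as.integer(latency)
      else NA_integer_,
    fixation_ms = as.integer(oddball +
                               (if (outcome == "correct") latency else 0)),
    stimulated = stimulated, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_session <- function(trials, spikes = NULL, meta = NULL) {
  spikes <- spikes %||% stats::setNames(
    rep(list(numeric(0)), nrow(trials)), as.character(trials$trial_id))
  new_session(trials, spikes, meta = meta %||%
                list(neuron_id = "test", structure = "caudate"))
}

# deterministic rate_trace helper
make_trace <- function(rate, start = 0L, alignment = "last_stimulus") {
  rate_trace(rate, c(start, start + length(rate)), alignment)
}

# independent oracle: spike density as an explicit sum of Gaussians
oracle_density <- function(raster, kernel) {
  win <- attr(raster, "window")
  pad <- attr(raster, "pad")
  tt <- seq.int(win[1], win[2] - 1L)
  grid0 <- win[1] - pad
  out <- numeric(length(tt))
  w <- kernel$weights
  for (i in seq_len(nrow(raster))) {
    cols <- which(raster[i, ] > 0)
    for (ci in cols) {
      st <- grid0 + ci - 1L
      d <- tt - st
      keep <- abs(d) <= kernel$half
      out[keep] <- out[keep] + raster[i, ci] * w[d[keep] + kernel$half + 1]
    }
  }
  out / nrow(raster) * 1000
}

# independent oracle: one-way ANOVA p at a single time point via stats::aov
oracle_anova_p <- function(y_by_group) {
  vals <- unlist(y_by_group)
  grp <- factor(rep(seq_along(y_by_group), lengths(y_by_group)))
  summary(stats::aov(vals ~ grp))[[1]][["Pr(>F)"]][1]
}
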