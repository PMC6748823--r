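# Threshold-crossing decoder of next-stimulus timing from population
# activity: normalize the population trace between its pre-oddball trough
# and peak, predict the next stimulus at the first crossing of a %
# threshold, and search the 1-100% grid for the threshold minimizing the
# summed squared prediction error across ISIs.

#' Decoder configuration
#'
#' @param theta_grid thresholds in %, default `1:100` (1% steps).
#' @param isi_subset ISIs decoded (default 300, 400, 600 ms — the longer
#'   intervals where temporal prediction is informative).
#' @param extra ms past the expected next stimulus kept in the trace
#'   (default 100).
#' @param summary `"mean_abs"` (mean |dt|) or `"rms"`.
#' @return list of class `decoder_config`.
#' @export
decoder_config <- function(theta_grid = 1:100,
                           isi_subset = c(300, 400, 600), extra = 100,
                           summary = c("mean_abs", "rms")) {
  summary <- match.arg(summary)
  stopifnot(length(isi_subset) > 0)
  structure(list(theta_grid = theta_grid, isi_subset = isi_subset,
                 extra = extra, summary = summary),
            class = "decoder_config")
}

#' Per-ISI population traces aligned to the last stimulus
#'
#' For each ISI in the configuration, computes every neuron's spike density
#' on `[0, isi + extra]` ms after the last stimulus before the oddball
#' (missing condition, correct trials) and the population mean (optionally
#' after per-neuron max normalization).
#'
#' @param sessions list of `oddball_session`s.
#' @param config a [decoder_config()].
#' @param kernel a [kernel_spec()].
#' @param condition trial condition (default `"missing"`).
#' @param normalization `"none"` or `"per_neuron_max"`.
#' @return named list (by ISI) with elements `trace` (population
#'   [rate_trace()]) and `neuron_matrix` (neurons x ms, used by
#'   [bootstrap_decoder()]).
#' @export
population_prediction_traces <- function(sessions,
                                         config = decoder_config(),
                                         kernel = kernel_spec(),
                                         condition = "missing",
                                         normalization = c(
                                           "none", "per_neuron_max")) {
  normalization <- match.arg(normalization)
  out <- list()
  for (isi in config$isi_subset) {
    win <- c(0L, as.integer(isi + config$extra + 1L))
    traces <- list()
    for (s in sessions) {
      f <- filter_trials(s)
      sel <- f$trials$condition == condition & f$trials$isi_ms == isi
      if (!any(sel)) next
      sub <- subset_session(f, f$trials$trial_id[sel])
      ras <- align_raster(sub, "last_stimulus", win, pad = kernel$half)
      traces[[length(traces) + 1L]] <- spike_density(ras, kernel)
    }
    if (length(traces) == 0)
      stop("population_prediction_traces: no usable neuron at ISI ", isi)
    pop <- population_average(traces, normalization)
    out[[as.character(isi)]] <- list(
      trace = pop,
      neuron_matrix = do.call(rbind, lapply(traces, function(tr) {
        r <- tr$rate
        if (normalization == "per_neuron_max" && max(r) > 0) r / max(r)
        else r
      })))
  }
  out
}

#' Normalize a population trace between trough and peak
#'
#' Trough and peak are the min and max over `[0, isi]` (ties: earliest);
#' the normalized trace `m(t) = (r(t) - trough) / (peak - trough)` is
#' returned from the trough time to the end of the trace.
#'
#' @param trace a [rate_trace()] on `[0, isi + extra]` aligned to the last
#'   stimulus.
#' @param isi the ISI (= actual next-stimulus time), ms.
#' @return list of class `prediction_trace`: `m`, `t`, `trough_time`,
#'   `peak_time`, `isi`.
#' @export
extract_prediction_trace <- function(trace, isi) {
  sel <- trace$t >= 0 & trace$t <= isi
  r <- trace$rate[sel]; tt <- trace$t[sel]
  trough <- min(r); peak <- max(r)
  if (peak - trough <= 1e-12)
    stop("extract_prediction_trace: degenerate (flat) trace")
  trough_time <- tt[which.min(r)]
  peak_time <- tt[which.max(r)]
  keep <- trace$t >= trough_time
  structure(list(m = (trace$rate[keep] - trough) / (peak - trough),
                 t = trace$t[keep], trough_time = trough_time,
                 peak_time = peak_time, isi = isi),
            class = "prediction_trace")
}

#' Predicted next-stimulus time at a % threshold
#'
#' First ms at or after the trough where the normalized trace reaches
#' `theta/100`; if no crossing occurs within the trace the peak time is
#' returned (the theta = 100% boundary case).
#'
#' @param pt an [extract_prediction_trace()] result.
#' @param theta threshold in %.
#' @return predicted time, ms after the last stimulus.
#' @export
threshold_crossing <- function(pt, theta) {
  hit <- which(pt$m >= theta / 100)
  if (length(hit) == 0) pt$peak_time else pt$t[hit[1]]
}

#' Optimal-threshold search
#'
#' Evaluates every threshold on the grid, summing the squared prediction
#' error `dt = predicted - isi` across ISIs; returns the minimizing
#' threshold (ties: smallest), the per-ISI errors at the optimum and the
#' configured error summary.
#'
#' @param traces named list (by ISI) of [rate_trace()]s (or the result of
#'   [population_prediction_traces()]).
#' @param config a [decoder_config()].
#' @return list of class `decoder_result`: `theta_star`, `predicted`,
#'   `delta_t`, `objective`, `mean_delta`, `objective_grid`.
#' @export
optimal_threshold_search <- function(traces, config = decoder_config()) {
  pts <- lapply(as.character(config$isi_subset), function(ik) {
    el <- traces[[ik]]
    tr <- if (!is.null(el$trace)) el$trace else el
    extract_prediction_trace(tr, as.integer(ik))
  })
  names(pts) <- as.character(config$isi_subset)
  obj <- vapply(config$theta_grid, function(th)
    sum(vapply(pts, function(pt)
      (threshold_crossing(pt, th) - pt$isi)^2, 0)), 0)
  theta_star <- config$theta_grid[which.min(obj)]
  pred <- vapply(pts, threshold_crossing, 0, theta = theta_star)
  delta <- pred - config$isi_subset
  mean_delta <- if (config$summary == "mean_abs") mean(abs(delta))
    else sqrt(mean(delta^2))
  structure(list(theta_star = theta_star, predicted = pred,
                 delta_t = delta, objective = min(obj),
                 mean_delta = mean_delta, objective_grid = obj),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat("<decoder_result> theta* =", x$theta_star, "%",
      "| mean delta =", round(x$mean_delta, 1), "ms\n")
  cat("  per-ISI dt (ms):",
      paste(names(x$delta_t), round(x$delta_t, 1), sep = ":",
            collapse = "  "), "\n")
  invisible(x)
}

#' Neuron-resampling bootstrap of the decoder error
#'
#' Resamples neurons with replacement `n_boot` times, rebuilding the
#' population trace and re-running the full threshold search each time;
#' returns the percentile 95% CI of the error summary.
#'
#' @param sessions list of at least two `oddball_session`s.
#' @param config a [decoder_config()].
#' @param kernel a [kernel_spec()].
#' @param n_boot bootstrap replicates (the study used 1000).
#' @param seed integer seed.
#' @param ... passed to [population_prediction_traces()].
#' @return list of class `decoder_bootstrap`: `point` (full-sample
#'   [optimal_threshold_search()] result), `ci` (2.5/97.5 percentiles of
#'   `mean_delta`), `boot_mean_delta`.
#' @export
bootstrap_decoder <- function(sessions, config = decoder_config(),
                              kernel = kernel_spec(), n_boot = 1000,
                              seed = 1, ...) {
  if (length(sessions) < 2) stop("bootstrap_decoder: need >= 2 neurons")
  traces <- population_prediction_traces(sessions, config, kernel, ...)
  point <- optimal_threshold_search(traces, config)
  n <- nrow(traces[[1]]$neuron_matrix)
  win1 <- traces[[1]]$trace$window
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_traces <- lapply(traces, function(el)
      rate_trace(colMeans(el$neuron_matrix[idx, , drop = FALSE]),
                 el$trace$window, el$trace$alignment, length(idx)))
    optimal_threshold_search(rep_traces, config)$mean_delta
  }, 0)
  structure(list(point = point,
                 ci = unname(quantile(boot, c(0.025, 0.975))),
                 boot_mean_delta = boot),
            class = "decoder_bootstrap")
}
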