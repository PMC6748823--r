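# Millisecond-resolution localization of trial-by-trial saccade-latency
# covariation: latency sextiles, normalized per-group population traces,
# one-way ANOVA at every ms (neurons as replicates), and run-length
# onset/offset detection with a neuron bootstrap.

#' Split a neuron's trials into latency sextiles
#'
#' Correct missing-condition trials at the analysed ISI are stably sorted
#' by saccade latency; the `n %% 6` longest-latency trials are discarded so
#' that the six consecutive blocks have equal size.
#'
#' @param session an `oddball_session`.
#' @param isi analysed ISI (default 400).
#' @param condition condition (default `"missing"`).
#' @param n_groups number of groups (default 6).
#' @param min_trials minimum trials (default 12; fewer is an error so the
#'   caller can exclude the neuron with a log entry).
#' @return list of class `latency_groups`: `groups` (list of trial-id
#'   vectors, shortest latencies first), `medians`, `n_per_group`.
#' @export
split_latency_sextiles <- function(session, isi = 400,
                                   condition = "missing", n_groups = 6,
                                   min_trials = 2 * n_groups) {
  f <- filter_trials(session)
  sel <- f$trials$condition == condition & f$trials$isi_ms == isi
  tr <- f$trials[sel, , drop = FALSE]
  if (nrow(tr) < min_trials)
    stop("split_latency_sextiles: fewer than ", min_trials,
         " usable trials for neuron ", session$meta$neuron_id)
  ord <- order(tr$saccade_latency_ms)      # stable
  n_keep <- as.integer(nrow(tr) - nrow(tr) %% n_groups)
  kept <- tr[ord[seq_len(n_keep)], ]
  per <- n_keep %/% as.integer(n_groups)
  groups <- split(kept$trial_id, rep(seq_len(n_groups), each = per))
  structure(list(
    groups = unname(groups),
    medians = vapply(groups, function(ids)
      median(kept$saccade_latency_ms[kept$trial_id %in% ids]), 0),
    n_per_group = per),
    class = "latency_groups")
}

#' Per-group, per-neuron normalized density matrices
#'
#' For every neuron and latency group, the spike density on `window`
#' relative to `alignment`; each neuron is normalized by `neuron_max`
#' (default: its maximum across its own groups within this alignment; pass
#' the joint max across alignments for the paper-style normalization, see
#' [variation_timing()]).
#'
#' @param sessions list of `oddball_session`s.
#' @param alignment `"oddball"` (stimulus omission) or `"saccade"`.
#' @param window half-open ms window relative to the alignment event.
#' @param kernel a [kernel_spec()].
#' @param isi,condition trial selection.
#' @param groups optional precomputed list of [split_latency_sextiles()]
#'   results (one per session).
#' @param neuron_max optional numeric vector of per-neuron normalization
#'   bases.
#' @return array `[time, group, neuron]` with attributes `t` (ms grid) and
#'   `raw_max` (per-neuron pre-normalization maxima); neurons with too few
#'   trials are dropped with a message.
#' @export
group_population_matrix <- function(sessions,
                                    alignment = c("oddball", "saccade"),
                                    window, kernel = kernel_spec(),
                                    isi = 400, condition = "missing",
                                    groups = NULL, neuron_max = NULL) {
  alignment <- match.arg(alignment)
  window <- as.integer(window)
  len <- window[2] - window[1]
  slabs <- list(); raw_max <- numeric(0); used <- character(0)
  for (j in seq_along(sessions)) {
    s <- sessions[[j]]
    g <- if (!is.null(groups)) groups[[j]] else
      tryCatch(split_latency_sextiles(s, isi, condition),
               error = function(e) {
                 message("group_population_matrix: excluding neuron ",
                         s$meta$neuron_id, ": ", conditionMessage(e))
                 NULL
               })
    if (is.null(g)) next
    mat <- vapply(g$groups, function(ids) {
      sub <- subset_session(s, ids)
      ras <- align_raster(sub, alignment, window, pad = kernel$half)
      spike_density(ras, kernel)$rate
    }, numeric(len))
    slabs[[length(slabs) + 1L]] <- mat
    raw_max <- c(raw_max, max(mat))
    used <- c(used, s$meta$neuron_id)
  }
  if (length(slabs) == 0)
    stop("group_population_matrix: no usable neuron")
  arr <- array(unlist(slabs), dim = c(len, ncol(slabs[[1]]),
                                      length(slabs)))
  nm <- neuron_max %||% raw_max
  for (j in seq_along(slabs))
    if (nm[j] > 0) arr[, , j] <- arr[, , j] / nm[j]
  structure(arr, t = seq.int(window[1], window[2] - 1L),
            raw_max = raw_max, neuron_ids = used)
}

#' One-way ANOVA at every millisecond
#'
#' At each ms, a fixed-effects one-way ANOVA with factor latency group
#' (6 levels) on the per-neuron normalized density values (neurons as
#' replicates). Time points with zero within-group variance get p = 1.
#'
#' @param arr a `[time, group, neuron]` array from
#'   [group_population_matrix()] (>= 2 neurons).
#' @return list: `t` (ms grid), `p`, `F_stat`.
#' @export
mswise_anova <- function(arr) {
  d <- dim(arr)
  if (d[3] < 2) stop("mswise_anova: need >= 2 neurons")
  k <- d[2]; n <- d[3]
  gm <- apply(arr, c(1, 2), mean)              # time x group means
  grand <- rowMeans(gm)
  ssb <- n * rowSums((gm - grand)^2)
  ssw <- numeric(d[1])
  for (j in seq_len(n)) {
    slab <- matrix(arr[, , j], d[1], k)
    ssw <- ssw + rowSums((slab - gm)^2)
  }
  dfb <- k - 1; dfw <- k * (n - 1)
  f <- rep(0, d[1]); p <- rep(1, d[1])
  ok <- ssw > 1e-300
  f[ok] <- (ssb[ok] / dfb) / (ssw[ok] / dfw)
  p[ok] <- pf(f[ok], dfb, dfw, lower.tail = FALSE)
  list(t = attr(arr, "t") %||% seq_len(d[1]), p = p, F_stat = f)
}

#' Onset of consistent group divergence (backward search)
#'
#' Scanning backward from the end of the window, the onset is the latest
#' time `t` such that `p > alpha` at every ms of the `run` ms immediately
#' before `t` and some ms at or after `t` is significant. `NA` (undetected)
#' if no such time exists.
#'
#' @param p p-value per ms.
#' @param t ms grid (same length as `p`).
#' @param alpha significance level (default 0.05).
#' @param run required run of non-significant ms before the onset
#'   (default 100).
#' @return onset time in ms, or `NA` if undetected.
#' @export
detect_variation_onset <- function(p, t = seq_along(p), alpha = 0.05,
                                   run = 100) {
  ok <- p > alpha
  n <- length(p)
  if (n <= run) return(NA_real_)
  sig_after <- rev(cumsum(rev(!ok))) > 0     # any significance at/after i
  for (i in seq.int(n, run + 1L)) {
    if (sig_after[i] && all(ok[(i - run):(i - 1L)])) return(t[i])
  }
  NA_real_
}

#' Offset of consistent group divergence (forward search)
#'
#' The earliest time `t` with `p > alpha` at every ms of `[t, t + run)`.
#' `NA` if no such run exists.
#'
#' @inheritParams detect_variation_onset
#' @return offset time in ms, or `NA` if undetected.
#' @export
detect_variation_offset <- function(p, t = seq_along(p), alpha = 0.05,
                                    run = 100) {
  ok <- p > alpha
  n <- length(p)
  if (n < run) return(NA_real_)
  for (i in seq_len(n - run + 1L)) {
    if (all(ok[i:(i + run - 1L)])) return(t[i])
  }
  NA_real_
}

#' Localize neuronal correlates of latency variation
#'
#' Full pipeline: latency sextiles per neuron, normalized group densities
#' aligned to both the stimulus omission and the saccade (per-neuron
#' normalization by the joint maximum across both alignments), ms-wise
#' ANOVA, and run-length onset (omission-aligned, backward) and offset
#' (saccade-aligned, forward) detection.
#'
#' @param sessions list of `oddball_session`s.
#' @param isi,condition trial selection (defaults 400 ms, missing).
#' @param kernel a [kernel_spec()].
#' @param omission_window,saccade_window analysis windows, ms.
#' @param alpha,run detection parameters.
#' @return list of class `variation_timing`: `onset`, `offset`,
#'   `p_omission`, `p_saccade` (each with `t`), `arrays` (the two
#'   normalized group arrays).
#' @export
variation_timing <- function(sessions, isi = 400, condition = "missing",
                             kernel = kernel_spec(),
                             omission_window = c(-800, 200),
                             saccade_window = c(-600, 200),
                             alpha = 0.05, run = 100) {
  groups <- lapply(sessions, function(s)
    tryCatch(split_latency_sextiles(s, isi, condition),
             error = function(e) NULL))
  keep <- !vapply(groups, is.null, TRUE)
  if (sum(keep) < 2)
    stop("variation_timing: fewer than 2 usable neurons")
  sessions <- sessions[keep]; groups <- groups[keep]
  a_om <- group_population_matrix(sessions, "oddball", omission_window,
                                  kernel, isi, condition, groups)
  a_sa <- group_population_matrix(sessions, "saccade", saccade_window,
                                  kernel, isi, condition, groups)
  joint <- pmax(attr(a_om, "raw_max"), attr(a_sa, "raw_max"))
  a_om <- group_population_matrix(sessions, "oddball", omission_window,
                                  kernel, isi, condition, groups, joint)
  a_sa <- group_population_matrix(sessions, "saccade", saccade_window,
                                  kernel, isi, condition, groups, joint)
  an_om <- mswise_anova(a_om)
  an_sa <- mswise_anova(a_sa)
  structure(list(
    onset = detect_variation_onset(an_om$p, an_om$t, alpha, run),
    offset = detect_variation_offset(an_sa$p, an_sa$t, alpha, run),
    p_omission = an_om, p_saccade = an_sa,
    arrays = list(omission = a_om, saccade = a_sa),
    alpha = alpha, run = run),
    class = "variation_timing")
}

#' @export
print.variation_timing <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undetected" else paste0(v, " ms")
  cat("<variation_timing> onset (re omission):", fmt(x$onset),
      "| offset (re saccade):", fmt(x$offset), "\n")
  invisible(x)
}

#' Neuron bootstrap of variation onset/offset
#'
#' Resamples neurons with replacement, re-running the ms-wise ANOVA and
#' detection on each replicate (the per-neuron group densities are
#' computed once; resampling only re-indexes the arrays, which is exact
#' because normalization is per neuron).
#'
#' @param sessions list of >= 2 `oddball_session`s.
#' @param n_boot replicates (the study used 1000).
#' @param seed integer seed.
#' @param ... passed to [variation_timing()].
#' @return list of class `variation_bootstrap`: `point` (full-sample
#'   [variation_timing()]), `onset`/`offset` each with `quartiles`
#'   (25/50/75%), `ci` (2.5/97.5%), `n_undetected`, `values`.
#' @export
bootstrap_variation_timing <- function(sessions, n_boot = 1000, seed = 1,
                                       ...) {
  if (length(sessions) < 2)
    stop("bootstrap_variation_timing: need >= 2 neurons")
  point <- variation_timing(sessions, ...)
  a_om <- point$arrays$omission; a_sa <- point$arrays$saccade
  n <- dim(a_om)[3]
  set.seed(seed)
  onsets <- offsets <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    po <- mswise_anova(a_om[, , idx, drop = FALSE])
    ps <- mswise_anova(a_sa[, , idx, drop = FALSE])
    onsets[b] <- detect_variation_onset(po$p, attr(a_om, "t"),
                                        point$alpha, point$run)
    offsets[b] <- detect_variation_offset(ps$p, attr(a_sa, "t"),
                                          point$alpha, point$run)
  }
  summ <- function(v) list(
    quartiles = unname(quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)),
    ci = unname(quantile(v, c(0.025, 0.975), na.rm = TRUE)),
    n_undetected = sum(is.na(v)), values = v)
  structure(list(point = point, onset = summ(onsets),
                 offset = summ(offsets)),
            class = "variation_bootstrap")
}
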