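# Saccade detection from eye velocity, stimulation latency tables, and the
# two-way ANOVA on latency-change scores.

#' Detect a saccade after the oddball from an eye trace
#'
#' Angular eye velocity is estimated by central differences at 1 kHz,
#' smoothed with a 5 ms boxcar; the saccade onset is the first ms after the
#' oddball at which speed exceeds `threshold` for at least `sustain`
#' consecutive ms.
#'
#' @param eye data.frame `t_ms`, `x_deg`, `y_deg` covering
#'   `[oddball_time, oddball_time + response_window]`.
#' @param oddball_time ms on the trial clock.
#' @param threshold deg/s (default 60).
#' @param sustain consecutive ms above threshold required (default 5).
#' @param response_window search horizon, ms (default 600).
#' @return list of class `saccade_event` (`onset`, `latency`,
#'   `peak_velocity`, `amplitude`, `direction`) or `NULL` if no saccade.
#' @export
detect_saccade <- function(eye, oddball_time, threshold = 60,
                           sustain = 5, response_window = 600) {
  need <- seq.int(oddball_time, oddball_time + response_window)
  if (!all(need %in% eye$t_ms))
    stop("detect_saccade: eye trace does not cover the search window")
  n <- nrow(eye)
  cd <- function(z) c(0, (z[3:n] - z[1:(n - 2)]) / 2, 0) * 1000
  vx <- cd(eye$x_deg); vy <- cd(eye$y_deg)
  sm <- function(v) {
    f <- stats::filter(v, rep(1 / 5, 5), sides = 2)
    f[is.na(f)] <- 0
    as.numeric(f)
  }
  speed <- sqrt(sm(vx)^2 + sm(vy)^2)
  idx <- which(eye$t_ms > oddball_time &
               eye$t_ms <= oddball_time + response_window)
  above <- speed[idx] > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= sustain)
  if (length(hit) == 0) return(NULL)
  i0 <- idx[ends[hit[1]] - runs$lengths[hit[1]] + 1L]
  onset <- eye$t_ms[i0]
  post <- i0:min(n, i0 + 100L)
  pre <- max(1L, i0 - 10L)
  land <- min(n, i0 + 80L)
  dx <- eye$x_deg[land] - eye$x_deg[pre]
  dy <- eye$y_deg[land] - eye$y_deg[pre]
  structure(list(onset = onset, latency = onset - oddball_time,
                 peak_velocity = max(speed[post]),
                 amplitude = sqrt(dx^2 + dy^2),
                 direction = if (dx >= 0) "contra" else "ipsi"),
            class = "saccade_event")
}

#' Stimulation latency-effect table
#'
#' Per session and condition x direction cell (correct trials only):
#' median and SD of saccade latency with and without stimulation, a
#' Wilcoxon rank-sum test (Bonferroni-corrected by the number of sessions
#' in the family), an F-test comparing variances, and the latency-change
#' score `median(stim) - median(control)`. Population tests per cell:
#' paired t on session medians and on session SDs. Cells with fewer than 3
#' trials on either side are flagged and excluded from population tests.
#'
#' @param sessions list of `oddball_session`s with stimulated trials.
#' @param alpha per-session significance level (default 0.05).
#' @return list of class `stim_effect_table`: `cells` (long data.frame)
#'   and `population` (per condition x direction).
#' @export
latency_table <- function(sessions, alpha = 0.05) {
  rows <- list()
  for (s in sessions) {
    tr <- filter_trials(s)$trials
    for (cond in unique(tr$condition)) for (dirn in c("contra", "ipsi")) {
      cell <- tr[tr$condition == cond & tr$target_direction == dirn, ]
      lat_s <- cell$saccade_latency_ms[cell$stimulated]
      lat_c <- cell$saccade_latency_ms[!cell$stimulated]
      ok <- length(lat_s) >= 3 && length(lat_c) >= 3
      p_w <- p_f <- NA_real_
      if (ok) {
        p_w <- suppressWarnings(wilcox.test(lat_s, lat_c)$p.value)
        p_f <- var.test(lat_s, lat_c)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        session = s$meta$neuron_id, condition = cond, direction = dirn,
        n_stim = length(lat_s), n_control = length(lat_c),
        median_stim = if (length(lat_s)) median(lat_s) else NA_real_,
        median_control = if (length(lat_c)) median(lat_c) else NA_real_,
        sd_stim = if (length(lat_s) > 1) sd(lat_s) else NA_real_,
        sd_control = if (length(lat_c) > 1) sd(lat_c) else NA_real_,
        p_wilcoxon = p_w, p_ftest = p_f, usable = ok,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  cells$change <- cells$median_stim - cells$median_control
  pop <- list()
  for (cond in unique(cells$condition)) for (dirn in c("contra", "ipsi")) {
    cc <- cells[cells$condition == cond & cells$direction == dirn &
                cells$usable, ]
    if (nrow(cc) < 2) next
    n_fam <- nrow(cc)
    tt <- paired_t_safe(cc$median_stim, cc$median_control)
    ts <- paired_t_safe(cc$sd_stim, cc$sd_control)
    pop[[length(pop) + 1L]] <- data.frame(
      condition = cond, direction = dirn, n_sessions = n_fam,
      mean_change = mean(cc$change),
      n_sig_sessions = sum(pmin(cc$p_wilcoxon * n_fam, 1) < alpha),
      n_sig_ftest = sum(pmin(cc$p_ftest * n_fam, 1) < alpha),
      t_median = tt$statistic, p_median = tt$p.value,
      t_sd = ts$statistic, p_sd = ts$p.value,
      stringsAsFactors = FALSE)
  }
  structure(list(cells = cells,
                 population = do.call(rbind, pop)),
            class = "stim_effect_table")
}

#' Two-way ANOVA on latency-change scores
#'
#' Fixed-effects two-way ANOVA (oddball condition x saccade direction,
#' with interaction) on the per-session latency-change scores from
#' [latency_table()], plus post-hoc paired t-tests between directions
#' within each condition. The design must be balanced (every session
#' contributes every cell).
#'
#' @param table a [latency_table()] result.
#' @return list of class `stim_anova_result`: `anova` (data.frame with
#'   term, df, F, p), `posthoc` (per condition), `scores`.
#' @export
stim_anova <- function(table) {
  sc <- table$cells[table$cells$usable,
                    c("session", "condition", "direction", "change")]
  if (length(unique(sc$condition)) < 2 ||
      length(unique(sc$direction)) < 2)
    stop("stim_anova: need both conditions and both directions ",
         "(did the sessions include stimulated and control trials?)")
  tab <- with(sc, table(session, condition, direction))
  if (any(tab != 1))
    stop("stim_anova: unbalanced design (a session is missing a cell)")
  sc$condition <- factor(sc$condition)
  sc$direction <- factor(sc$direction)
  fit <- lm(change ~ condition * direction, data = sc)
  an <- anova(fit)
  out <- data.frame(term = rownames(an)[1:3], df = an$Df[1:3],
                    df_error = an$Df[4], F_value = an$`F value`[1:3],
                    p_value = an$`Pr(>F)`[1:3], stringsAsFactors = FALSE)
  post <- lapply(levels(sc$condition), function(cond) {
    a <- sc[sc$condition == cond & sc$direction == "contra", ]
    b <- sc[sc$condition == cond & sc$direction == "ipsi", ]
    b <- b[match(a$session, b$session), ]
    tt <- t.test(a$change, b$change, paired = TRUE)
    data.frame(condition = cond, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  structure(list(anova = out, posthoc = do.call(rbind, post),
                 scores = sc),
            class = "stim_anova_result")
}
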