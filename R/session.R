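# Session container: trial events + spike trains (+ optional eye traces) for
# one neuron/recording site. All times are integer milliseconds on the trial
# clock, zero at the first stimulus onset; grids are half-open [start, end).

TRIAL_COLUMNS <- c(
  "trial_id", "condition", "isi_ms", "n_stimuli", "oddball_time_ms",
  "target_direction", "outcome", "saccade_latency_ms", "fixation_ms",
  "stimulated"
)
ISI_SET <- c(100L, 200L, 300L, 400L, 600L)

#' Construct a recording session
#'
#' A session bundles the trial table, one spike train per trial and optional
#' 1 kHz eye-position traces, together with neuron metadata. Trials in the
#' oddball-detection task present a brief visual stimulus at a fixed
#' inter-stimulus interval (ISI); the oddball is either the omission of a
#' stimulus (missing condition) or a colour/filling change (deviant
#' condition), and the subject reports it with a saccade.
#'
#' @param trials data.frame with columns `trial_id`, `condition`
#'   (`"missing"`/`"deviant"`), `isi_ms` (one of 100, 200, 300, 400, 600),
#'   `n_stimuli`, `oddball_time_ms`, `target_direction` (`"contra"`/
#'   `"ipsi"`), `outcome` (`"correct"`/`"early_error"`/`"miss"`),
#'   `saccade_latency_ms` (NA unless correct), `fixation_ms`, `stimulated`
#'   (logical). Stimulus onsets are implicit: `(0:(n_stimuli-1)) * isi_ms`.
#' @param spikes named list (names = trial ids) of non-decreasing spike time
#'   vectors in ms on the trial clock.
#' @param eyes optional named list of data.frames with columns `t_ms`,
#'   `x_deg`, `y_deg` sampled at 1 kHz.
#' @param meta list with at least `neuron_id` and `structure`
#'   (`"caudate"` or `"dentate"`); `animal`/`hemisphere` optional.
#' @param validate run [validate_session()]? Default TRUE.
#' @return object of class `oddball_session`.
#' @export
new_session <- function(trials, spikes, eyes = NULL, meta = list(),
                        validate = TRUE) {
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  s <- structure(
    list(trials = trials, spikes = spikes, eyes = eyes, meta = meta),
    class = "oddball_session"
  )
  if (validate) validate_session(s)
  s
}

#' Stimulus onset times of a trial
#'
#' @param trial one-row data.frame (a row of `session$trials`).
#' @return integer vector `(0:(n_stimuli-1)) * isi_ms`.
#' @export
stimulus_onsets <- function(trial) {
  (seq_len(trial$n_stimuli) - 1L) * trial$isi_ms
}

#' Validate a session against the data-model invariants
#'
#' Checks enum membership, uniqueness of trial ids, the one-spike-train-per-
#' trial pairing, the reconstruction `oddball_time = last onset + isi` for
#' missing trials, presence of saccade latency exactly on correct trials,
#' ordering and bounds of spike times, and eye-trace sampling.
#'
#' @param session an `oddball_session`.
#' @return the session, invisibly; stops with a validation error naming the
#'   offending trial otherwise.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  fail <- function(...) stop("session validation: ", ..., call. = FALSE)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing_cols) > 0)
    fail("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tr$trial_id))
    fail("duplicated trial_id: ", tr$trial_id[duplicated(tr$trial_id)][1])
  if (!all(tr$condition %in% c("missing", "deviant")))
    fail("unknown condition in trial ",
         tr$trial_id[!tr$condition %in% c("missing", "deviant")][1])
  if (!all(tr$isi_ms %in% ISI_SET))
    fail("isi_ms outside {100,200,300,400,600} in trial ",
         tr$trial_id[!tr$isi_ms %in% ISI_SET][1])
  if (!all(tr$target_direction %in% c("contra", "ipsi")))
    fail("unknown target_direction in trial ",
         tr$trial_id[!tr$target_direction %in% c("contra", "ipsi")][1])
  if (!all(tr$outcome %in% c("correct", "early_error", "miss")))
    fail("unknown outcome in trial ",
         tr$trial_id[!tr$outcome %in% c("correct", "early_error", "miss")][1])
  if (any(tr$n_stimuli < 1))
    fail("n_stimuli < 1 in trial ", tr$trial_id[tr$n_stimuli < 1][1])
  miss <- tr$condition == "missing"
  bad <- miss & tr$oddball_time_ms != tr$n_stimuli * tr$isi_ms
  if (any(bad))
    fail("oddball_time_ms != last onset + isi for missing trial ",
         tr$trial_id[bad][1])
  bad <- tr$oddball_time_ms <= (tr$n_stimuli - 1L) * tr$isi_ms
  if (any(bad))
    fail("oddball_time_ms not after last stimulus onset in trial ",
         tr$trial_id[bad][1])
  has_lat <- !is.na(tr$saccade_latency_ms)
  bad <- has_lat != (tr$outcome == "correct")
  if (any(bad))
    fail("saccade_latency_ms present iff outcome == correct violated in ",
         "trial ", tr$trial_id[bad][1])
  if (any(has_lat & tr$saccade_latency_ms <= 0))
    fail("non-positive saccade latency in trial ",
         tr$trial_id[has_lat & tr$saccade_latency_ms <= 0][1])
  ids <- as.character(tr$trial_id)
  if (!setequal(names(session$spikes), ids) ||
      length(session$spikes) != nrow(tr))
    fail("spike trains do not pair one-to-one with trials")
  for (id in ids) {
    st <- session$spikes[[id]]
    if (is.unsorted(st)) fail("spike times not sorted in trial ", id)
    ob <- tr$oddball_time_ms[match(as.integer(id), tr$trial_id)]
    if (length(st) > 0 && (st[1] < -2000 || st[length(st)] > ob + 1000))
      fail("spike time outside trial bounds in trial ", id)
  }
  if (!is.null(session$eyes)) {
    if (!all(names(session$eyes) %in% ids))
      fail("eye trace for unknown trial ",
           setdiff(names(session$eyes), ids)[1])
    for (id in names(session$eyes)) {
      ey <- session$eyes[[id]]
      if (!all(c("t_ms", "x_deg", "y_deg") %in% names(ey)))
        fail("eye trace columns wrong in trial ", id)
      if (nrow(ey) > 1 && any(diff(ey$t_ms) != 1L))
        fail("eye trace not contiguous 1 kHz in trial ", id)
    }
  }
  if (is.null(session$meta$neuron_id)) fail("meta$neuron_id missing")
  st <- session$meta$structure
  if (!is.null(st) && !st %in% c("caudate", "dentate"))
    fail("meta$structure must be 'caudate' or 'dentate'")
  invisible(session)
}

#' @export
print.oddball_session <- function(x, ...) {
  cat("<oddball_session> neuron", x$meta$neuron_id %||% "?",
      paste0("(", x$meta$structure %||% "?", ")"), "\n")
  cat("  trials:", nrow(x$trials),
      "| correct:", sum(x$trials$outcome == "correct"),
      "| conditions:", paste(unique(x$trials$condition), collapse = "/"),
      "| ISIs:", paste(sort(unique(x$trials$isi_ms)), collapse = ","), "\n")
  cat("  spikes:", sum(lengths(x$spikes)),
      "| eye traces:", length(x$eyes %||% list()), "\n")
  invisible(x)
}

#' Write a session to a directory
#'
#' Writes `trials.csv`, `spikes.csv`, `meta.json` and (when present)
#' `eye.csv` in the plain-text container read by [read_session()]. Spike
#' times must be whole milliseconds; the round trip is lossless and a
#' read-then-rewrite is byte-identical.
#'
#' @param session an `oddball_session`.
#' @param path directory to create/populate.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create directory: ", path)
  tr <- session$trials
  out <- data.frame(
    trial_id = as.integer(tr$trial_id),
    condition = tr$condition,
    isi_ms = as.integer(tr$isi_ms),
    n_stimuli = as.integer(tr$n_stimuli),
    oddball_time_ms = as.integer(tr$oddball_time_ms),
    target_direction = tr$target_direction,
    outcome = tr$outcome,
    saccade_latency_ms = as.integer(tr$saccade_latency_ms),
    fixation_ms = as.integer(tr$fixation_ms),
    stimulated = as.integer(tr$stimulated),
    stringsAsFactors = FALSE
  )
  write.csv(out, file.path(path, "trials.csv"), row.names = FALSE,
            quote = FALSE, na = "")
  all_spk <- unlist(session$spikes[as.character(out$trial_id)],
                    use.names = FALSE)
  if (length(all_spk) > 0 && any(all_spk != round(all_spk)))
    stop("spike times must be whole milliseconds for a lossless container")
  spk <- data.frame(
    trial_id = rep(out$trial_id,
                   lengths(session$spikes[as.character(out$trial_id)])),
    spike_time_ms = as.integer(round(all_spk %||% integer()))
  )
  write.csv(spk, file.path(path, "spikes.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(session$eyes) && length(session$eyes) > 0) {
    ids <- as.character(out$trial_id)
    ids <- ids[ids %in% names(session$eyes)]
    ey <- do.call(rbind, lapply(ids, function(id) {
      e <- session$eyes[[id]]
      data.frame(trial_id = as.integer(id), t_ms = as.integer(e$t_ms),
                 x_deg = e$x_deg, y_deg = e$y_deg)
    }))
    write.csv(ey, file.path(path, "eye.csv"), row.names = FALSE,
              quote = FALSE)
  }
  jsonlite::write_json(session$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a session from a directory
#'
#' @param path directory containing `trials.csv`, `spikes.csv`, `meta.json`
#'   and optionally `eye.csv` (see [write_session()] for the layout).
#' @return a validated `oddball_session`.
#' @export
read_session <- function(path) {
  tfile <- file.path(path, "trials.csv")
  if (!file.exists(tfile)) stop("not a session container (no trials.csv): ",
                                path)
  tr <- tryCatch(
    read.csv(tfile, stringsAsFactors = FALSE,
             colClasses = c(
               trial_id = "integer", condition = "character",
               isi_ms = "integer", n_stimuli = "integer",
               oddball_time_ms = "integer", target_direction = "character",
               outcome = "character", saccade_latency_ms = "integer",
               fixation_ms = "integer", stimulated = "integer"
             )),
    error = function(e) stop("parse error in ", tfile, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!all(TRIAL_COLUMNS %in% names(tr)))
    stop("parse error in ", tfile, ": missing columns ",
         paste(setdiff(TRIAL_COLUMNS, names(tr)), collapse = ", "),
         call. = FALSE)
  tr$stimulated <- as.logical(tr$stimulated)
  spk <- tryCatch(
    read.csv(file.path(path, "spikes.csv"), stringsAsFactors = FALSE,
             colClasses = c(trial_id = "integer",
                            spike_time_ms = "integer")),
    error = function(e) stop("parse error in spikes.csv: ",
                             conditionMessage(e), call. = FALSE)
  )
  spikes <- lapply(
    stats::setNames(tr$trial_id, as.character(tr$trial_id)),
    function(id) sort(spk$spike_time_ms[spk$trial_id == id])
  )
  eyes <- NULL
  efile <- file.path(path, "eye.csv")
  if (file.exists(efile)) {
    ey <- read.csv(efile, stringsAsFactors = FALSE)
    eyes <- lapply(split(ey[c("t_ms", "x_deg", "y_deg")], ey$trial_id),
                   function(d) { rownames(d) <- NULL; d })
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  new_session(tr, spikes, eyes, meta)
}

#' Keep a subset of trials (and their spikes/eyes)
#'
#' @param session an `oddball_session`.
#' @param trial_ids trial ids to keep.
#' @return subset session (not re-validated; subsetting preserves validity).
#' @export
subset_session <- function(session, trial_ids) {
  keep <- session$trials$trial_id %in% trial_ids
  ids <- as.character(session$trials$trial_id[keep])
  tr <- session$trials[keep, , drop = FALSE]
  rownames(tr) <- NULL
  new_session(tr, session$spikes[ids],
              if (!is.null(session$eyes))
                session$eyes[intersect(names(session$eyes), ids)],
              session$meta, validate = FALSE)
}

#' Filter trials by outcome and fixation duration
#'
#' Default rules follow the study's inclusion criteria: only correct trials,
#' and only trials where fixation was maintained more than 1500 ms from the
#' first stimulus. Filtering is idempotent.
#'
#' @param session an `oddball_session`.
#' @param correct_only keep only `outcome == "correct"` (default TRUE).
#' @param min_fixation keep only `fixation_ms > min_fixation` (default 1500;
#'   `NULL` disables the rule).
#' @return filtered session; warns (does not error) if nothing survives.
#' @export
filter_trials <- function(session, correct_only = TRUE,
                          min_fixation = 1500) {
  keep <- rep(TRUE, nrow(session$trials))
  if (correct_only) keep <- keep & session$trials$outcome == "correct"
  if (!is.null(min_fixation))
    keep <- keep & session$trials$fixation_ms > min_fixation
  if (!any(keep)) warning("filter_trials: no trials pass the filter")
  subset_session(session, session$trials$trial_id[keep])
}

#' Align spikes on a common millisecond grid
#'
#' Builds a trials x time matrix of per-ms spike counts on the half-open
#' window `[window[1], window[2])` relative to the chosen alignment event.
#' The indicator is 0/1 for any point process with at most one spike per ms
#' (always true for the per-ms Bernoulli simulator); exact-thinning spike
#' trains may occasionally place two spikes in a bin, and counts are kept so
#' that in-window spikes are conserved exactly. Trials lacking the alignment
#' event (e.g. saccade alignment on error trials) are dropped with a
#' message. Spikes at exactly `window[2]` are excluded (half-open grid).
#'
#' @param session an `oddball_session`.
#' @param alignment one of `"first_stimulus"`, `"oddball"`,
#'   `"last_stimulus"`, `"saccade"`.
#' @param window integer `c(start, end)`, end exclusive, relative to the
#'   alignment event; must have positive length.
#' @param pad extra ms kept on each side (attribute `pad`); used by
#'   [spike_density()] so convolution edges see real spikes.
#' @return matrix of class `aligned_raster` with attributes `alignment`,
#'   `window`, `pad`, `trial_ids`.
#' @export
align_raster <- function(session,
                         alignment = c("first_stimulus", "oddball",
                                       "last_stimulus", "saccade"),
                         window, pad = 0) {
  alignment <- match.arg(alignment)
  window <- as.integer(window)
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(start, end) with end > start")
  pad <- as.integer(pad)
  tr <- session$trials
  event <- switch(alignment,
    first_stimulus = rep(0L, nrow(tr)),
    oddball = tr$oddball_time_ms,
    last_stimulus = (tr$n_stimuli - 1L) * tr$isi_ms,
    saccade = tr$oddball_time_ms + tr$saccade_latency_ms
  )
  drop <- is.na(event)
  if (any(drop))
    message("align_raster: dropping ", sum(drop), " trial(s) lacking the ",
            alignment, " event")
  keep <- which(!drop)
  g0 <- window[1] - pad
  len <- (window[2] + pad) - g0
  mat <- matrix(0L, nrow = length(keep), ncol = len)
  if (length(keep) == 0)
    warning("align_raster: empty raster (no trial has the ", alignment,
            " event)")
  for (i in seq_along(keep)) {
    k <- keep[i]
    rel <- floor(session$spikes[[as.character(tr$trial_id[k])]] - event[k])
    rel <- rel[rel >= g0 & rel < window[2] + pad]
    if (length(rel) > 0) {
      cnt <- tabulate(rel - g0 + 1L, nbins = len)
      mat[i, ] <- cnt
    }
  }
  structure(mat, class = "aligned_raster", alignment = alignment,
            window = window, pad = pad,
            trial_ids = tr$trial_id[keep])
}

#' @export
print.aligned_raster <- function(x, ...) {
  cat("<aligned_raster>", nrow(x), "trials, window [",
      attr(x, "window")[1], ",", attr(x, "window")[2], ") ms re",
      attr(x, "alignment"), "| spikes:", sum(x), "\n")
  invisible(x)
}

# Crop the pad columns, returning the plain counts matrix on [start, end).
raster_core <- function(raster) {
  pad <- attr(raster, "pad")
  if (pad == 0) return(unclass(raster))
  n <- ncol(raster)
  unclass(raster)[, (pad + 1L):(n - pad), drop = FALSE]
}
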