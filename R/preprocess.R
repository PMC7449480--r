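#' Band-pass filter specification
#'
#' The EEG analysis band is 0.5 Hz up to a variable low-pass cutoff `high_cut`
#' (`f_high`), studied at 30, 49 and 90 Hz; AEP sweeps additionally get a
#' 25 Hz high-pass before averaging.
#'
#' @param low_cut high-pass edge in Hz.
#' @param high_cut low-pass edge in Hz (`f_high`).
#' @param aep_highpass pre-average AEP high-pass in Hz.
#' @param order Butterworth order of the low-pass stage (the high-pass stage
#'   uses order 2); filtering is applied forward-backward, so effective
#'   attenuation is doubled.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 49, aep_highpass = 25, order = 4) {
  if (low_cut <= 0 || high_cut <= low_cut) stop("need 0 < low_cut < high_cut")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 aep_highpass = aep_highpass, order = order),
            class = "filter_spec")
}

#' Automatic artifact detection
#'
#' Flags an epoch when any of three rules fires:
#' \describe{
#'   \item{constant_amplitude}{a run of >= `flat_run` identical consecutive
#'     samples (flat line; default 0.1 s at 1 kHz);}
#'   \item{range_exceeded}{any sample beyond the +/-`range_limit` uV
#'     measuring range;}
#'   \item{slope_exceeded}{peak-to-peak amplitude change within any sliding
#'     window of `slope_window_s` seconds exceeding
#'     `slope_limit * slope_window_s` uV (rate criterion `slope_limit` uV/s).}
#' }
#' A flagged epoch is excluded downstream together with its companion data
#' point.
#'
#' @param epoch an [epoched_signal()] (or numeric vector with `sampling_rate`).
#' @param range_limit peak limit in uV.
#' @param slope_limit rate limit in uV/s.
#' @param flat_run run length of identical samples counting as flat line.
#' @param slope_window_s window for the slope rule in seconds.
#' @param sampling_rate required if `epoch` is a bare numeric vector.
#' @return an `artifact_report`: list with `flagged` and `reasons`.
#' @export
detect_artifacts <- function(epoch, range_limit = 250, slope_limit = 140,
                             flat_run = 100, slope_window_s = 1,
                             sampling_rate = NULL) {
  if (inherits(epoch, "epoched_signal")) {
    x <- epoch$samples
    fs <- epoch$sampling_rate
  } else {
    x <- as.numeric(epoch)
    fs <- sampling_rate
  }
  if (is.null(fs) || is.na(fs)) stop("sampling rate is required for artifact detection")
  if (length(x) < 2) stop("epoch must have at least 2 samples")
  reasons <- character(0)
  runs <- rle(x)
  if (any(runs$lengths >= flat_run)) reasons <- c(reasons, "constant_amplitude")
  if (any(abs(x) > range_limit)) reasons <- c(reasons, "range_exceeded")
  w <- min(length(x), max(2, round(fs * slope_window_s)))
  if (roll_ptp_max_cpp(x, w) > slope_limit * slope_window_s)
    reasons <- c(reasons, "slope_exceeded")
  structure(list(flagged = length(reasons) > 0, reasons = reasons),
            class = "artifact_report")
}

#' Zero-phase band-pass filtering of an epoch
#'
#' Cascades a 2nd-order Butterworth high-pass at `low_cut` with an
#' `order`-order Butterworth low-pass at `high_cut`, each applied
#' forward-backward (`signal::filtfilt`) so the pass band is phase-neutral
#' and entropy/latency features are not distorted.
#'
#' @param epoch an [epoched_signal()].
#' @param spec a [filter_spec()].
#' @return the filtered epoch (same length and metadata).
#' @export
apply_filter <- function(epoch, spec) {
  stopifnot(inherits(epoch, "epoched_signal"), inherits(spec, "filter_spec"))
  fs <- epoch$sampling_rate
  if (spec$high_cut >= fs / 2)
    stop(sprintf("high_cut %g Hz is at or above Nyquist (%g Hz)", spec$high_cut, fs / 2))
  hp <- signal::butter(2, spec$low_cut / (fs / 2), type = "high")
  lp <- signal::butter(spec$order, spec$high_cut / (fs / 2), type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, epoch$samples))
  out <- epoch
  out$samples <- as.numeric(y)
  out
}

#' Cut conscious/unconscious epochs around transition events
#'
#' For each annotated transition the conscious epoch is the
#' `epoch_duration`-second segment adjacent to the last (LOC) or first (ROC)
#' successful hand-squeeze request, on the conscious side; the unconscious
#' epoch sits on the other side of the transition, adjacent to the failed
#' request. The uncertain interval between the two request times contributes
#' no samples.
#'
#' @param recording list with `samples` (uV), `sampling_rate` (Hz) and
#'   `patient_id`.
#' @param annotations data frame with columns `patient_id`, `event`
#'   (LOCk/ROCk), `last_response_time_s`, `first_no_response_time_s`; either
#'   side may be `NA` (a warning is emitted and one epoch extracted). For LOC
#'   events the response time precedes the no-response time; for ROC the
#'   order is reversed.
#' @param epoch_duration epoch length in seconds.
#' @return list of [epoched_signal()], at most two per annotation row.
#' @export
cut_transition_epochs <- function(recording, annotations, epoch_duration = 10) {
  fs <- recording$sampling_rate
  n <- length(recording$samples)
  d <- round(epoch_duration * fs)
  grab <- function(from_s, backwards) {
    i0 <- round(from_s * fs)
    idx <- if (backwards) (i0 - d + 1):i0 else (i0 + 1):(i0 + d)
    if (min(idx) < 1 || max(idx) > n) return(NULL)
    recording$samples[idx]
  }
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    is_loc <- grepl("^LOC", a$event)
    t_resp <- a$last_response_time_s
    t_noresp <- a$first_no_response_time_s
    if (!is.na(t_resp) && !is.na(t_noresp)) {
      if (is_loc && t_resp >= t_noresp)
        stop(sprintf("event %s: response time must precede no-response time", a$event))
      if (!is_loc && t_noresp >= t_resp)
        stop(sprintf("event %s: no-response time must precede response time", a$event))
    } else {
      warning(sprintf("event %s: only one side annotated", a$event))
    }
    # conscious epoch points away from the gray zone, ending/starting at the
    # conscious-side request; mirrored for the unconscious side.
    if (!is.na(t_resp)) {
      s <- grab(t_resp, backwards = is_loc)
      if (!is.null(s))
        out[[length(out) + 1]] <- epoched_signal(s, fs, recording$patient_id,
                                                 a$event, "conscious")
    }
    if (!is.na(t_noresp)) {
      s <- grab(t_noresp, backwards = !is_loc)
      if (!is.null(s))
        out[[length(out) + 1]] <- epoched_signal(s, fs, recording$patient_id,
                                                 a$event, "unconscious")
    }
  }
  out
}
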