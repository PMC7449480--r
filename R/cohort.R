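#' Configuration of a synthetic transition-protocol cohort
#'
#' Describes a cohort emulating an anesthesia induction/emergence protocol in
#' which consciousness is probed by repeated requests to squeeze the
#' investigator's hand. Each patient contributes `events_per_patient`
#' transition events (the LOC1, ROC1, LOC2, ROC2 sequence by default), and
#' each event yields one "conscious" and one "unconscious" data point: a 10 s
#' EEG epoch plus an AEP sweep set recorded adjacent to the transition.
#'
#' The defaults encode the emulated study conditions: 40 patients, 4 events,
#' 10 s epochs sampled at 1 kHz, and state effects on both modalities —
#' conscious EEG carries more beta/gamma-band power, the unconscious
#' mid-latency AEP is attenuated and delayed.
#'
#' @param n_patients number of patients (>= 1).
#' @param sampling_rate EEG/AEP sampling rate in Hz.
#' @param epoch_duration EEG epoch length in seconds; `epoch_duration *
#'   sampling_rate` must be an integer.
#' @param events_per_patient transition events per patient.
#' @param sweeps_per_aep stimulus-locked sweeps per AEP data point (>= 1).
#' @param stimulus_rate auditory click rate in Hz (spacing of sweeps).
#' @param eeg_effect state effect size: shift (in logit units) of the
#'   fast-band mixture weight between conscious and unconscious EEG.
#' @param gamma_band_effect optional additional state effect confined to the
#'   gamma band (30-90 Hz): RMS weight of an extra gamma-noise component
#'   present at full strength when conscious and strongly attenuated when
#'   unconscious. Default 0; used to emulate cohorts whose discriminative
#'   information sits above a 30 Hz low-pass.
#' @param aep_amplitude_effect fractional attenuation of the mid-latency AEP
#'   deflections when unconscious (0 = none, 1 = abolished).
#' @param aep_latency_effect latency increase in ms of the mid-latency
#'   deflections when unconscious.
#' @param between_patient_sd SD of per-patient Gaussian offsets applied to
#'   the EEG mixture logit and the log AEP amplitude.
#' @param within_patient_sd SD of per-epoch Gaussian jitter on the EEG
#'   mixture logit (and, scaled down, on the log AEP amplitude and latency):
#'   epoch-to-epoch fluctuation of arousal within a state, without which
#'   repeated epochs of one patient/state would be statistically identical.
#' @param artifact_rate probability in `[0,1]` that an epoch is corrupted by
#'   [inject_artifacts()].
#' @param seed integer master seed; expands to per-patient substreams so any
#'   patient subset is reproducible on its own.
#' @param aep_window_ms post-stimulus analysis window `(from, to)` in ms;
#'   must cover the mid-latency range 20-120 ms.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 40L, sampling_rate = 1000, epoch_duration = 10,
                          events_per_patient = 4L, sweeps_per_aep = 512L,
                          stimulus_rate = 7, eeg_effect = 1.5,
                          gamma_band_effect = 0,
                          aep_amplitude_effect = 0.4, aep_latency_effect = 10,
                          between_patient_sd = 0.5, within_patient_sd = 0.6,
                          artifact_rate = 0, seed = 1L, aep_window_ms = c(0, 128)) {
  n_samples <- sampling_rate * epoch_duration
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("epoch_duration x sampling_rate must be an integer sample count")
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (sweeps_per_aep < 1) stop("at least one sweep per AEP is required")
  if (eeg_effect < 0 || gamma_band_effect < 0 || aep_amplitude_effect < 0 ||
      aep_latency_effect < 0 || between_patient_sd < 0 || within_patient_sd < 0)
    stop("effect sizes must be non-negative")
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must be in [0,1]")
  if (aep_window_ms[1] > 20 || aep_window_ms[2] < 120)
    stop("AEP window must cover the mid-latency range 20-120 ms")
  structure(list(
    n_patients = as.integer(n_patients), sampling_rate = sampling_rate,
    epoch_duration = epoch_duration, events_per_patient = as.integer(events_per_patient),
    sweeps_per_aep = as.integer(sweeps_per_aep), stimulus_rate = stimulus_rate,
    eeg_effect = eeg_effect, gamma_band_effect = gamma_band_effect,
    aep_amplitude_effect = aep_amplitude_effect,
    aep_latency_effect = aep_latency_effect, between_patient_sd = between_patient_sd,
    within_patient_sd = within_patient_sd,
    artifact_rate = artifact_rate, seed = as.integer(seed),
    aep_window_ms = aep_window_ms, n_samples = as.integer(round(n_samples))
  ), class = "cohort_config")
}

#' Construct an epoched signal segment
#'
#' @param samples numeric vector in microvolts.
#' @param sampling_rate Hz.
#' @param patient_id,event_label,state,channel_label provenance metadata;
#'   `event_label` is one of LOC1/ROC1/LOC2/ROC2 (or LOCk/ROCk), `state` is
#'   `"conscious"` or `"unconscious"`.
#' @return an `epoched_signal` object.
#' @export
epoched_signal <- function(samples, sampling_rate, patient_id = NA,
                           event_label = NA, state = NA, channel_label = "AT1-Fpz") {
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 patient_id = patient_id, event_label = event_label,
                 state = state, channel_label = channel_label),
            class = "epoched_signal")
}

#' @export
print.epoched_signal <- function(x, ...) {
  cat(sprintf("<epoched_signal> %d samples @ %g Hz | patient %s | %s | %s\n",
              length(x$samples), x$sampling_rate, x$patient_id,
              x$event_label, x$state))
  invisible(x)
}

#' Construct an AEP sweep set
#'
#' @param sweeps numeric matrix, one row per stimulus-locked sweep (microvolts).
#' @param sampling_rate Hz.
#' @param window post-stimulus window `(from, to)` in ms.
#' @param patient_id,event_label,state provenance metadata.
#' @return an `aep_sweep_set` object.
#' @export
aep_sweep_set <- function(sweeps, sampling_rate, window,
                          patient_id = NA, event_label = NA, state = NA) {
  sweeps <- as.matrix(sweeps)
  structure(list(sweeps = sweeps, sampling_rate = sampling_rate, window = window,
                 patient_id = patient_id, event_label = event_label, state = state),
            class = "aep_sweep_set")
}

# Gaussian noise spectrally shaped by gain(f) via FFT filtering, unit RMS.
shaped_noise <- function(n, fs, gain) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * fs / n
  Xs <- X * gain(f)
  y <- Re(stats::fft(Xs, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

# Spectral shapes of the two EEG regimes. Slow: delta/theta-dominant with a
# 1/f-like tail. Fast: broad beta/gamma bump (15-90 Hz) so state information
# extends into the gamma band.
.gain_slow <- function(f) ifelse(f < 0.3, 0, 1 / (1 + (f / 4)^2))
.gain_fast <- function(f) exp(-((f - 40)^2) / (2 * 24^2)) * as.numeric(f > 8)
.gain_gamma <- function(f) as.numeric(f >= 30 & f <= 90)

# Mid-latency AEP template in microvolts on a ms time axis: a positive
# deflection near 30 ms (Pa analogue) and a negative one near 45 ms (Nb
# analogue). `amp` scales both; `shift` delays both (ms).
aep_template <- function(t_ms, amp = 1, shift = 0) {
  amp * (exp(-((t_ms - 30 - shift)^2) / (2 * 6^2)) -
         0.8 * exp(-((t_ms - 45 - shift)^2) / (2 * 8^2)))
}

per_patient_seed <- function(seed, i) as.integer((as.numeric(seed) + 48271 * i) %% 2147483647)

#' Generate a synthetic EEG/AEP cohort
#'
#' Simulates, per patient and transition event, one conscious and one
#' unconscious data point. The EEG is a state-weighted mixture of a slow
#' (delta/theta) and a fast (beta/gamma) filtered-noise regime: the fast-band
#' mixture weight is `plogis(offset + eeg_effect/2)` when conscious and
#' `plogis(offset - eeg_effect/2)` when unconscious, so conscious epochs have
#' a higher spectral edge and lower regularity. The AEP sweep is a mid-latency
#' two-deflection template (30/45 ms) buried in background noise; when
#' unconscious the template is attenuated by `aep_amplitude_effect` and
#' delayed by `aep_latency_effect` ms. Per-patient Gaussian offsets
#' (`between_patient_sd`) act on the mixture logit and log template amplitude.
#'
#' @param config a [cohort_config()].
#' @return a list with `epochs` (list of [epoched_signal()]), `sweep_sets`
#'   (list of [aep_sweep_set()]) and `manifest` (data frame: patient_id,
#'   event, state, index). Counts equal
#'   `n_patients * events_per_patient * 2`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  fs <- config$sampling_rate
  n <- config$n_samples
  win <- config$aep_window_ms
  n_aep <- round((win[2] - win[1]) * fs / 1000)
  t_ms <- (seq_len(n_aep) - 0.5) * 1000 / fs + win[1]
  events <- paste0(rep(c("LOC", "ROC"), length.out = config$events_per_patient),
                   rep(seq_len(ceiling(config$events_per_patient / 2)), each = 2))
  epochs <- list(); sweep_sets <- list(); rows <- list(); idx <- 0L
  for (p in seq_len(config$n_patients)) {
    set.seed(per_patient_seed(config$seed, p))
    pid <- sprintf("P%02d", p)
    off_eeg <- stats::rnorm(1, 0, config$between_patient_sd)
    off_aep <- stats::rnorm(1, 0, config$between_patient_sd * 0.5)
    lat_jit <- stats::rnorm(1, 0, 2)
    for (ev in events) {
      for (state in c("conscious", "unconscious")) {
        sgn <- if (state == "conscious") 0.5 else -0.5
        w <- stats::plogis(off_eeg + sgn * config$eeg_effect +
                           stats::rnorm(1, 0, config$within_patient_sd))
        amp_scale <- 10 * (1 + 0.4 * (1 - w))   # unconscious slow waves are larger
        eeg <- amp_scale * (sqrt(1 - w) * shaped_noise(n, fs, .gain_slow) +
                            sqrt(w) * shaped_noise(n, fs, .gain_fast))
        if (config$gamma_band_effect > 0) {
          g <- config$gamma_band_effect * (if (state == "conscious") 1 else 0.3) *
            exp(stats::rnorm(1, 0, config$within_patient_sd * 0.5))
          eeg <- eeg + 10 * sqrt(g) * shaped_noise(n, fs, .gain_gamma)
        }
        amp <- exp(off_aep + stats::rnorm(1, 0, config$within_patient_sd * 0.4)) *
          (if (state == "unconscious") 1 - config$aep_amplitude_effect else 1)
        shift <- lat_jit + stats::rnorm(1, 0, 1.5) +
          (if (state == "unconscious") config$aep_latency_effect else 0)
        tmpl <- aep_template(t_ms, amp = amp, shift = shift)
        # ~1 uV evoked response against ~20 uV RMS EEG/EMG background: the
        # classic mid-latency AEP regime where averaging does the work
        sweeps <- matrix(stats::rnorm(config$sweeps_per_aep * n_aep, sd = 20),
                         nrow = config$sweeps_per_aep)
        sweeps <- sweep(sweeps, 2, tmpl, "+")
        idx <- idx + 1L
        epochs[[idx]] <- epoched_signal(eeg, fs, pid, ev, state)
        sweep_sets[[idx]] <- aep_sweep_set(sweeps, fs, win, pid, ev, state)
        rows[[idx]] <- data.frame(patient_id = pid, event = ev, state = state,
                                  index = idx, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (config$artifact_rate > 0) {
    epochs <- inject_artifacts(epochs, config)
  }
  list(epochs = epochs, sweep_sets = sweep_sets, manifest = manifest)
}

#' Corrupt a fraction of epochs with detector-triggering artifacts
#'
#' Each selected epoch receives exactly one of three corruption classes that
#' the automatic artifact rules are designed to catch: a flat-line segment
#' (constant amplitude), an amplitude excursion beyond the +/-250 uV
#' measuring range, or a fast ramp exceeding 140 uV/s. The true corruption
#' class is recorded in the epoch's `artifact_truth` attribute so detector
#' tests can measure completeness.
#'
#' @param epochs list of [epoched_signal()].
#' @param config a [cohort_config()]; uses `artifact_rate` and `seed`.
#' @return the epoch list with a fraction `artifact_rate` corrupted.
#' @export
inject_artifacts <- function(epochs, config) {
  stopifnot(config$artifact_rate >= 0, config$artifact_rate <= 1)
  if (config$artifact_rate == 0) return(epochs)
  set.seed(per_patient_seed(config$seed, 0L))
  for (i in seq_along(epochs)) {
    if (stats::runif(1) >= config$artifact_rate) next
    e <- epochs[[i]]
    fs <- e$sampling_rate
    n <- length(e$samples)
    type <- sample(c("flat", "range", "ramp"), 1)
    x <- e$samples
    if (type == "flat") {
      seg <- seq(floor(n / 3), min(n, floor(n / 3) + 2 * fs))
      x[seg] <- x[seg[1]]
    } else if (type == "range") {
      at <- sample(n, 3)
      x[at] <- sample(c(-300, 300), 3, replace = TRUE)
    } else {
      ramp_len <- min(round(fs), n - 1)           # 160 uV rise over <= 1 s
      at <- sample(max(1, n - ramp_len), 1)
      seg <- at:(at + ramp_len - 1)
      x[seg] <- x[seg] + seq(0, 160, length.out = ramp_len)
      if (at + ramp_len <= n) x[(at + ramp_len):n] <- x[(at + ramp_len):n] + 160
    }
    e$samples <- x
    attr(e, "artifact_truth") <- type
    epochs[[i]] <- e
  }
  epochs
}

#' Write / read epochs as delimited text
#'
#' Layout: a tab-separated file per epoch with a `#`-comment header carrying
#' sampling rate and labels, then one sample (uV) per row; plus a manifest
#' table (patient_id, event, state, file).
#'
#' @param epochs list of [epoched_signal()].
#' @param dir output directory (created if missing).
#' @return (invisibly) the manifest data frame, also written to
#'   `manifest.tsv` in `dir`.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(epochs), function(i) {
    e <- epochs[[i]]
    file <- sprintf("epoch_%04d.tsv", i)
    con <- file(file.path(dir, file), "w")
    writeLines(sprintf("# sampling_rate=%g patient_id=%s event=%s state=%s channel=%s",
                       e$sampling_rate, e$patient_id, e$event_label, e$state,
                       e$channel_label), con)
    utils::write.table(data.frame(uV = e$samples), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    close(con)
    data.frame(patient_id = e$patient_id, event = e$event_label,
               state = e$state, file = file, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    path <- file.path(dir, manifest$file[i])
    hdr <- readLines(path, n = 1)
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
    kv <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
    samples <- utils::read.table(path, sep = "\t", comment.char = "#")[[1]]
    epoched_signal(samples, as.numeric(kv[["sampling_rate"]]),
                   kv[["patient_id"]], kv[["event"]], kv[["state"]],
                   kv[["channel"]])
  })
}
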