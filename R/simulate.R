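# Synthetic MMG generator.
#
# Emulates the acquisition protocol the pipeline is designed for: a
# metronome-paced tapping session (default 30 beats/min; 5 gestures x 5
# consecutive repetitions x 5 rounds = 125 taps) recorded on two
# accelerometer channels at 1 kHz. Each tap is a raised-cosine-shaped
# burst of band-limited (10-22 Hz) noise on top of Gaussian baseline
# noise; gesture identity is imprinted through per-channel amplitude
# gains and per-gesture carrier sub-bands. The generator returns the
# exact ground-truth event table alongside the recording.

#' Tapping protocol specification
#'
#' @param metronome_bpm Metronome rate in beats per minute (default 30,
#'   i.e. one tap every 2 s).
#' @param gestures Number of distinct finger gestures (5).
#' @param reps_per_round Consecutive repetitions of each gesture within
#'   a round (default 5).
#' @param rounds Number of rounds (default 5); total events =
#'   `gestures * reps_per_round * rounds` = 125 by default.
#' @param inter_round_rest_s Rest between rounds in seconds (default 5;
#'   long enough that rounds can never merge at the detector, short
#'   enough to keep simulated recordings desk-sized — fatigue modelling
#'   is out of scope).
#' @param leading_rest_s Initial rest period in seconds (default 5,
#'   minimum 5): this interval supplies the detector's threshold
#'   baseline.
#' @param sampling_rate Hz (default 1000).
#' @param channels Channel count (default 2).
#' @return A list of class `sim_protocol`.
#' @export
sim_protocol <- function(metronome_bpm = 30, gestures = 5L,
                         reps_per_round = 5L, rounds = 5L,
                         inter_round_rest_s = 5, leading_rest_s = 5,
                         sampling_rate = 1000, channels = 2L) {
  if (leading_rest_s < 5) stop_("`leading_rest_s` must be >= 5 (threshold baseline)")
  if (gestures < 1 || gestures > length(GESTURES))
    stop_("`gestures` must be in 1..", length(GESTURES))
  structure(list(metronome_bpm = metronome_bpm, gestures = as.integer(gestures),
                 reps_per_round = as.integer(reps_per_round),
                 rounds = as.integer(rounds),
                 inter_round_rest_s = inter_round_rest_s,
                 leading_rest_s = leading_rest_s,
                 sampling_rate = sampling_rate, channels = as.integer(channels)),
            class = "sim_protocol")
}

#' Tap-burst signal model
#'
#' @param gains Matrix `gestures x channels` of per-gesture, per-channel
#'   burst amplitude gains. The default gain pattern is opposite-ordered
#'   across the two channels (a tap "closer" to one sensor), so the
#'   gain ratio identifies the gesture.
#' @param carrier_bands Matrix `gestures x 2` of per-gesture burst bands
#'   (Hz); defaults are overlapping sub-bands of the 10-22 Hz dominant
#'   MMG band.
#' @param duration_ms Length-2 range of burst durations in ms (default
#'   300-500).
#' @param amplitude_cv Coefficient of variation of the per-event
#'   (log-normal) amplitude jitter (default 0.1).
#' @param envelope_taper Fraction of the burst covered by the
#'   raised-cosine ramps of the flat-top (Tukey) amplitude envelope
#'   (default 0.5: cosine attack/release over the first and last
#'   quarter; 1 gives a full raised-cosine with no flat top).
#' @param timing_jitter_ms SD of the Gaussian tap-timing jitter around
#'   the metronome tick (default 50 ms).
#' @param snr_db Burst RMS (at unit gain) over baseline noise SD, in dB
#'   (default 15). Used when `baseline_noise_sd` is `NULL`.
#' @param baseline_noise_sd Baseline (raw, broadband) noise SD; if
#'   `NULL`, derived from `snr_db` with unit burst RMS.
#' @param artifact_rate Low-frequency drift artifacts per minute
#'   (default 0: the protocol asks subjects to keep the forearm
#'   motionless).
#' @return A list of class `burst_model`.
#' @export
burst_model <- function(gains = NULL, carrier_bands = NULL,
                        duration_ms = c(300, 500), amplitude_cv = 0.1,
                        envelope_taper = 0.5, timing_jitter_ms = 50,
                        snr_db = 15, baseline_noise_sd = NULL,
                        artifact_rate = 0) {
  if (envelope_taper <= 0 || envelope_taper > 1)
    stop_("`envelope_taper` must be in (0, 1]")
  if (is.null(gains))
    gains <- cbind(ch1 = c(1.5, 1.25, 1.0, 0.8, 0.65),
                   ch2 = c(0.65, 0.8, 1.0, 1.25, 1.5))
  if (is.null(carrier_bands))
    carrier_bands <- cbind(low = c(10, 11, 13, 15, 16),
                           high = c(16, 17, 19, 21, 22))
  if (any(duplicated(apply(gains, 1, paste, collapse = "/"))))
    stop_("per-gesture gain rows must be distinct (class identity is constructed)")
  if (is.null(baseline_noise_sd)) baseline_noise_sd <- 10^(-snr_db / 20)
  structure(list(gains = gains, carrier_bands = carrier_bands,
                 duration_ms = duration_ms, amplitude_cv = amplitude_cv,
                 envelope_taper = envelope_taper,
                 timing_jitter_ms = timing_jitter_ms, snr_db = snr_db,
                 baseline_noise_sd = baseline_noise_sd,
                 artifact_rate = artifact_rate),
            class = "burst_model")
}

# Instantaneous amplitude of a real signal via the analytic signal.
analytic_amplitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Band-limited unit-RMS burst: white noise filtered into `band`,
# amplitude-flattened, then shaped by a flat-top raised-cosine (Tukey)
# envelope. Flattening divides out the carrier's own slow Rayleigh
# amplitude modulation (its instantaneous analytic-signal amplitude) so
# the realised amplitude envelope is exactly the prescribed raised
# cosine — narrow-band noise would otherwise wander quiet for ~100 ms
# stretches inside the burst's annotated support. A finger tap is an
# impact-like contraction: the cosine ramps cover only the taper
# fraction of the burst (taper 1 degenerates to a full raised cosine).
make_burst <- function(dur, band, fs, taper = 0.5) {
  pad <- 400L
  raw <- rnorm(dur + 2L * pad)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(bf, raw)
  amp <- analytic_amplitude(filtered)
  shaped <- (filtered / pmax(amp, 1e-3 * stats::median(amp)))[(pad + 1):(pad + dur)]
  u <- (seq_len(dur) - 0.5) / dur
  r <- taper / 2
  env <- rep(1, dur)
  env[u < r] <- 0.5 * (1 - cos(pi * u[u < r] / r))
  env[u > 1 - r] <- 0.5 * (1 - cos(pi * (1 - u[u > 1 - r]) / r))
  b <- shaped * env
  b / sqrt(mean(b^2))
}

#' Simulate an annotated MMG recording
#'
#' Generates Gaussian baseline noise plus one band-limited burst per
#' metronome tick, following the tapping protocol (rounds of consecutive
#' gesture repetitions, thumb to little finger). Gesture identity is
#' carried by the per-channel gain pattern and carrier sub-band of the
#' burst; each event's burst waveform is drawn independently and shared
#' across channels (one mechanical source, two sensors). The returned
#' event table is exact ground truth. Fully reproducible from `seed`.
#'
#' @param protocol A [sim_protocol()].
#' @param model A [burst_model()].
#' @param seed Integer seed.
#' @return List with `recording` (a [recording()], baseline interval set
#'   to the leading rest) and `events` (a labelled [event_table()]).
#' @export
#' @examples
#' sim <- simulate_recording(seed = 1)
#' nrow(sim$events)  # 125
simulate_recording <- function(protocol = sim_protocol(),
                               model = burst_model(), seed = 1L) {
  fs <- protocol$sampling_rate
  period <- round(60 / protocol$metronome_bpm * fs)
  max_dur <- round(max(model$duration_ms) / 1000 * fs)
  if (max_dur >= period)
    stop_("burst duration (", max_dur, " samples) must be shorter than the ",
          "metronome period (", period, " samples): events would overlap")
  ticks_per_round <- protocol$gestures * protocol$reps_per_round
  lead <- round(protocol$leading_rest_s * fs)
  rest <- round(protocol$inter_round_rest_s * fs)
  round_len <- ticks_per_round * period
  n <- lead + protocol$rounds * round_len +
    (protocol$rounds - 1) * rest + fs  # 1 s trailing pad
  C <- protocol$channels
  with_seed(seed, {
    samples <- matrix(rnorm(n * C, sd = model$baseline_noise_sd), ncol = C)
    starts <- integer(); ends <- integer(); labs <- character()
    for (r in seq_len(protocol$rounds)) {
      round0 <- lead + (r - 1) * (round_len + rest)
      tick_i <- 0L
      for (g in seq_len(protocol$gestures)) {
        for (rep_i in seq_len(protocol$reps_per_round)) {
          tick <- round0 + tick_i * period
          tick_i <- tick_i + 1L
          jitter <- round(rnorm(1, 0, model$timing_jitter_ms / 1000 * fs))
          dur <- round(runif(1, model$duration_ms[1], model$duration_ms[2]) / 1000 * fs)
          s <- max(tick + jitter, 0L)
          if (s + dur > n) s <- n - dur
          burst <- make_burst(dur, model$carrier_bands[g, ], fs,
                              taper = model$envelope_taper)
          amp <- if (model$amplitude_cv > 0) {
            sdlog <- sqrt(log(1 + model$amplitude_cv^2))
            rlnorm(1, -sdlog^2 / 2, sdlog)
          } else 1
          for (ch in seq_len(C)) {
            gain <- model$gains[g, min(ch, ncol(model$gains))]
            idx <- (s + 1):(s + dur)
            samples[idx, ch] <- samples[idx, ch] + amp * gain * burst
          }
          starts <- c(starts, s); ends <- c(ends, s + dur)
          labs <- c(labs, GESTURES[g])
        }
      }
    }
    if (model$artifact_rate > 0) {
      n_art <- stats::rpois(1, model$artifact_rate * n / fs / 60)
      for (a in seq_len(n_art)) {
        adur <- round(runif(1, 1, 3) * fs)
        a0 <- sample.int(n - adur, 1)
        drift <- runif(1, 1, 3) * model$baseline_noise_sd *
          sin(pi * seq_len(adur) / adur)
        for (ch in seq_len(C)) samples[(a0 + 1):(a0 + adur), ch] <-
          samples[(a0 + 1):(a0 + adur), ch] + drift
      }
    }
    rec <- recording(samples, sampling_rate = fs, subject_id = paste0("sim", seed),
                     baseline_interval = c(0L, lead))
    list(recording = rec,
         events = event_table(starts, ends, labs))
  })
}

#' Simulate labelled feature vectors
#'
#' A unit-test-scale fixture for the ranking and classification stages:
#' `informative_k` features carry class information (adjacent class
#' means `separation` within-class SDs apart, unit within-class SD), the
#' remaining features are pure standard-normal noise. The informative
#' features are columns `1..informative_k`.
#'
#' @param n_per_class Samples per class (>= 2).
#' @param n_features Total feature count.
#' @param informative_k Number of informative features
#'   (<= `n_features`).
#' @param separation Distance between adjacent class means, in
#'   within-class SD units.
#' @param seed Integer seed.
#' @param n_classes Number of classes (default 5, labelled with
#'   [gesture_labels()]).
#' @return List with `features`, `labels`, and `informative` (the
#'   informative column indices).
#' @export
simulate_labeled_features <- function(n_per_class, n_features,
                                      informative_k, separation, seed = 1L,
                                      n_classes = 5L) {
  if (n_per_class < 2) stop_("`n_per_class` must be >= 2")
  if (informative_k > n_features) stop_("`informative_k` must be <= `n_features`")
  if (n_classes > length(GESTURES)) stop_("`n_classes` must be <= ", length(GESTURES))
  n <- n_per_class * n_classes
  labels <- factor(rep(GESTURES[seq_len(n_classes)], each = n_per_class),
                   levels = GESTURES[seq_len(n_classes)])
  with_seed(seed, {
    x <- matrix(rnorm(n * n_features), nrow = n)
    if (informative_k > 0) {
      shift <- (as.integer(labels) - 1) * separation
      for (i in seq_len(informative_k)) x[, i] <- x[, i] + shift
    }
    colnames(x) <- paste0("f", seq_len(n_features))
    list(features = x, labels = labels,
         informative = seq_len(informative_k))
  })
}
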