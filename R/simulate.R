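# Synthetic SSVEP generator. The signal model: a steady-state response at the
# stimulus frequency and its first four harmonics, delayed by the visual
# latency, projected onto the occipito-parietal montage by a fixed topography,
# on top of 1/f Gaussian background noise with a small channel-shared
# component.

#' Standard 8-channel occipito-parietal montage
#'
#' Channel names in dataset order.
#' @return Character vector of 8 channel labels.
#' @export
ssvep_channels <- function() {
  c("POz", "PO3", "PO4", "PO5", "PO6", "Oz", "O1", "O2")
}

#' Default channel topography of the SSVEP response
#'
#' Fixed relative per-channel gain of the evoked response, strongest over
#' Oz/O1/O2 where SSVEP amplitude peaks, weaker at the parieto-occipital
#' ring. Unit gain at Oz so profile amplitudes are in Oz microvolts.
#' @return Named numeric vector over the 8 channels.
#' @export
default_topography <- function() {
  c(POz = 0.80, PO3 = 0.55, PO4 = 0.55, PO5 = 0.45, PO6 = 0.45,
    Oz = 1.00, O1 = 0.85, O2 = 0.85)
}

#' Per-subject response profile for the simulator
#'
#' Holds the subject-level parameters of the synthetic SSVEP model: harmonic
#' response amplitudes for the wet- and dry-electrode sessions (Oz microvolts
#' at the 11.25 Hz reference frequency), visual latency, background-noise RMS
#' per electrode type, trial-to-trial amplitude jitter, and the exponent of
#' the amplitude decay with stimulus frequency.
#'
#' Default harmonic amplitudes are the group-average values reported for the
#' 11.25 Hz target: wet 2.597, 1.262, 0.746, 0.316 and dry 2.444, 1.119,
#' 0.706, 0.305 microvolts for harmonics 1-4. Dry recordings carry more
#' broadband noise, which is what degrades their single-trial decoding.
#'
#' @param subject_seed Integer seed identifying the subject; all of the
#'   subject's randomness derives from it.
#' @param amplitudes_wet,amplitudes_dry Harmonic amplitudes (microvolts),
#'   non-negative, one per harmonic.
#' @param latency Visual response latency in seconds (default 0.14).
#' @param noise_scale Named numeric `c(wet=, dry=)`: background noise RMS in
#'   microvolts per channel.
#' @param amplitude_jitter Fractional SD of multiplicative trial-to-trial
#'   amplitude variation.
#' @param alpha_scale RMS (microvolts, at Oz) of the spontaneous alpha-band
#'   background: a drifting ~10.5 Hz oscillation sharing the occipital
#'   topography of the evoked response. Because it overlaps the 9.25-14.75 Hz
#'   stimulus band it is the main confuser limiting single-trial decoding.
#' @param freq_decay Exponent of the amplitude decay with stimulus frequency,
#'   relative to 11.25 Hz: amplitudes scale by (f / 11.25)^(-freq_decay).
#' @param topography Named per-channel gain vector.
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(subject_seed = 1,
                            amplitudes_wet = c(2.597, 1.262, 0.746, 0.316),
                            amplitudes_dry = c(2.444, 1.119, 0.706, 0.305),
                            latency = 0.14,
                            noise_scale = c(wet = 4, dry = 6),
                            amplitude_jitter = 0.10,
                            alpha_scale = 5,
                            freq_decay = 1.0,
                            topography = default_topography()) {
  stopifnot(length(amplitudes_wet) == length(amplitudes_dry))
  if (any(amplitudes_wet < 0) || any(amplitudes_dry < 0))
    stop("harmonic amplitudes must be non-negative", call. = FALSE)
  if (latency < 0) stop("`latency` must be >= 0", call. = FALSE)
  if (!all(c("wet", "dry") %in% names(noise_scale)))
    stop("`noise_scale` must be named c(wet=, dry=)", call. = FALSE)
  if (any(noise_scale < 0)) stop("`noise_scale` must be >= 0", call. = FALSE)
  structure(list(
    subject_seed = as.integer(subject_seed),
    amplitudes = list(wet = amplitudes_wet, dry = amplitudes_dry),
    latency = latency,
    noise_scale = noise_scale[c("wet", "dry")],
    amplitude_jitter = amplitude_jitter,
    alpha_scale = alpha_scale,
    freq_decay = freq_decay,
    topography = topography
  ), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile> seed", x$subject_seed,
      "| latency", x$latency, "s | noise RMS wet/dry",
      paste(x$noise_scale, collapse = "/"), "uV\n")
  invisible(x)
}

# Run code with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s)
}

# Gaussian 1/f^alpha noise, one column per channel, via FFT shaping.
# Scaled so each channel has RMS `scale`. A fraction `shared` of the
# variance is a component common to all channels.
pink_noise <- function(n_samples, n_channels, sampling_rate, scale,
                       alpha = 1, shared = 0.2) {
  shape_one <- function() {
    w <- stats::rnorm(n_samples)
    W <- stats::fft(w)
    f <- seq(0, n_samples - 1) * (sampling_rate / n_samples)
    f <- pmin(f, sampling_rate - f)      # two-sided frequency magnitude
    g <- ifelse(f < sampling_rate / n_samples, 0, f^(-alpha / 2))
    x <- Re(stats::fft(W * g, inverse = TRUE)) / n_samples
    x / stats::sd(x)
  }
  common <- shape_one()
  out <- matrix(0, nrow = n_channels, ncol = n_samples)
  for (ch in seq_len(n_channels)) {
    own <- shape_one()
    out[ch, ] <- scale * (sqrt(1 - shared) * own + sqrt(shared) * common)
  }
  out
}

# Spontaneous alpha-band oscillation: instantaneous frequency performing a
# slow random walk around `base_freq`, with a slowly varying non-negative
# amplitude envelope, scaled to RMS `scale`. Consumes RNG state.
alpha_background <- function(n_samples, sampling_rate, scale,
                             base_freq = NULL) {
  if (scale <= 0) return(numeric(n_samples))
  if (is.null(base_freq)) base_freq <- stats::rnorm(1, 10.5, 1.0)
  drift <- cumsum(stats::rnorm(n_samples, sd = 0.5 / sqrt(sampling_rate)))
  inst_f <- base_freq + drift
  phase <- 2 * pi * cumsum(inst_f) / sampling_rate + stats::runif(1, 0, 2 * pi)
  env_raw <- stats::filter(stats::rnorm(n_samples),
                           rep(1 / sampling_rate, sampling_rate),
                           sides = 2, circular = TRUE)
  env <- 1 + as.numeric(env_raw) / max(stats::sd(env_raw), 1e-12)
  env <- pmax(env, 0)
  x <- env * sin(phase)
  scale * x / max(stats::sd(x), 1e-12)
}

# Harmonic SSVEP waveform of length n starting at response onset; harmonic h
# carries phase h * phi (periodic nonlinear response model).
ssvep_waveform <- function(t, frequency, phase, amplitudes) {
  y <- numeric(length(t))
  for (h in seq_along(amplitudes)) {
    if (amplitudes[h] > 0)
      y <- y + amplitudes[h] * sin(2 * pi * h * frequency * t + h * phase)
  }
  y
}

# Effective harmonic amplitudes for a target: electrode defaults, frequency
# decay relative to the 11.25 Hz reference, and optional trial jitter.
effective_amplitudes <- function(profile, electrode, frequency, jitter_mult = 1) {
  amps <- profile$amplitudes[[electrode]]
  amps * (frequency / 11.25)^(-profile$freq_decay) * jitter_mult
}

#' Simulate one event-locked SSVEP epoch
#'
#' Generates a channels x samples epoch for one stimulus target: background
#' noise throughout, plus (from the visual latency onward) the harmonic
#' steady-state response at the target frequency mixed across channels by the
#' profile topography. Identical arguments and seed give identical output.
#'
#' @param frequency Stimulus frequency in Hz.
#' @param phase Stimulus phase in radians.
#' @param profile A [subject_profile()].
#' @param electrode `"wet"` or `"dry"`.
#' @param duration Epoch length in seconds (>= the profile latency).
#' @param sampling_rate Sampling rate in Hz; must exceed twice the highest
#'   simulated harmonic.
#' @param seed Integer seed.
#' @param jitter Logical: apply trial-level amplitude jitter (default TRUE).
#' @return Numeric matrix channels x samples with channel names as rownames
#'   and attributes `sampling_rate` and `latency`.
#' @export
simulate_epoch <- function(frequency, phase, profile,
                           electrode = c("wet", "dry"),
                           duration = 2.34, sampling_rate = 250,
                           seed = profile$subject_seed, jitter = TRUE) {
  electrode <- match.arg(electrode)
  if (duration < profile$latency)
    stop("`duration` must be >= the profile latency", call. = FALSE)
  n_harm <- length(profile$amplitudes[[electrode]])
  if (sampling_rate <= 2 * n_harm * frequency)
    stop("`sampling_rate` must exceed twice the highest harmonic frequency",
         call. = FALSE)
  n <- round(duration * sampling_rate)
  topo <- profile$topography
  n_ch <- length(topo)
  with_seed(seed, {
    jm <- if (jitter && profile$amplitude_jitter > 0)
      max(0, 1 + stats::rnorm(1, sd = profile$amplitude_jitter)) else 1
    amps <- effective_amplitudes(profile, electrode, frequency, jm)
    noise <- if (profile$noise_scale[[electrode]] > 0)
      pink_noise(n, n_ch, sampling_rate, profile$noise_scale[[electrode]])
    else matrix(0, n_ch, n)
    if (profile$alpha_scale > 0)
      noise <- noise + outer(unname(profile$topography),
                             alpha_background(n, sampling_rate,
                                              profile$alpha_scale))
    lat_n <- round(profile$latency * sampling_rate)
    sig <- numeric(n)
    if (n > lat_n) {
      t_resp <- (seq_len(n - lat_n) - 1) / sampling_rate
      sig[(lat_n + 1):n] <- ssvep_waveform(t_resp, frequency, phase, amps)
    }
    out <- noise + outer(unname(topo), sig)
    rownames(out) <- names(topo)
    attr(out, "sampling_rate") <- sampling_rate
    attr(out, "latency") <- profile$latency
    out
  })
}

#' Simulate a full subject session as continuous recordings
#'
#' Emulates the study protocol: for each electrode type, `n_blocks`
#' consecutive blocks, each containing exactly one trial per target in a
#' per-block random order. Each trial is 1 s cue, 2 s flicker (with the
#' steady-state response starting after the visual latency), and 1 s rest, so
#' epoch windows (0.5 s pre to 2.34 s post onset) never overlap.
#'
#' @param layout A [speller_layout()].
#' @param profile A [subject_profile()].
#' @param n_blocks Number of blocks per electrode session (>= 1).
#' @param electrodes Character subset of `c("wet", "dry")`.
#' @param sampling_rate Acquisition rate in Hz (default 1000, as recorded).
#' @param seed Integer master seed; per-block sub-seeds are derived from it.
#' @return Object of class `subject_session`: list with `recordings` (a list
#'   of `continuous_recording` objects named `<electrode>_block<k>`), `trials`
#'   (a tibble of electrode, block, trial, target_index, onset_sample), and
#'   the profile/layout metadata.
#' @export
simulate_subject <- function(layout, profile, n_blocks = 10,
                             electrodes = c("wet", "dry"),
                             sampling_rate = 1000,
                             seed = profile$subject_seed) {
  stopifnot(inherits(layout, "speller_layout"), inherits(profile, "subject_profile"))
  if (n_blocks < 1) stop("`n_blocks` must be >= 1", call. = FALSE)
  electrodes <- match.arg(electrodes, several.ok = TRUE)
  stim <- layout$stimuli
  cue_s <- 1; stim_s <- 2; rest_s <- 1; lead_s <- 1; tail_s <- 0.5
  trial_s <- cue_s + stim_s + rest_s
  n_total <- round((lead_s + 12 * trial_s + tail_s) * sampling_rate)
  recordings <- list()
  trials <- list()
  for (ei in seq_along(electrodes)) {
    el <- electrodes[ei]
    for (b in seq_len(n_blocks)) {
      bseed <- derive_seed(seed, match(el, c("wet", "dry")), b)
      rec <- with_seed(bseed, {
        order_k <- sample.int(12)
        noise <- if (profile$noise_scale[[el]] > 0)
          pink_noise(n_total, length(profile$topography), sampling_rate,
                     profile$noise_scale[[el]])
        else matrix(0, length(profile$topography), n_total)
        if (profile$alpha_scale > 0)
          noise <- noise + outer(unname(profile$topography),
                                 alpha_background(n_total, sampling_rate,
                                                  profile$alpha_scale))
        onsets <- integer(12)
        lat_n <- round(profile$latency * sampling_rate)
        resp_n <- round(stim_s * sampling_rate)
        for (tr in seq_len(12)) {
          k <- order_k[tr]
          onset <- round((lead_s + (tr - 1) * trial_s + cue_s) * sampling_rate)
          onsets[tr] <- onset
          jm <- if (profile$amplitude_jitter > 0)
            max(0, 1 + stats::rnorm(1, sd = profile$amplitude_jitter)) else 1
          amps <- effective_amplitudes(profile, el, stim$frequency[k], jm)
          t_resp <- (seq_len(resp_n) - 1) / sampling_rate
          wave <- ssvep_waveform(t_resp, stim$frequency[k], stim$phase[k], amps)
          idx <- onset + lat_n + seq_len(resp_n)   # 1-based sample indices
          noise[, idx] <- noise[, idx] + outer(unname(profile$topography), wave)
        }
        list(signal = noise, onsets = onsets, targets = order_k)
      })
      rownames(rec$signal) <- names(profile$topography)
      recordings[[paste0(el, "_block", b)]] <- structure(list(
        signal = rec$signal,
        sampling_rate = sampling_rate,
        channel_names = names(profile$topography),
        events = tibble::tibble(sample_index = rec$onsets,
                                target_index = rec$targets)
      ), class = "continuous_recording")
      trials[[length(trials) + 1]] <- tibble::tibble(
        electrode = el, block = b, trial = seq_len(12),
        target_index = rec$targets, onset_sample = rec$onsets
      )
    }
  }
  structure(list(
    recordings = recordings,
    trials = dplyr::bind_rows(trials),
    layout = layout, profile = profile,
    sampling_rate = sampling_rate,
    electrodes = electrodes, n_blocks = n_blocks, seed = seed
  ), class = "subject_session")
}

#' @export
print.subject_session <- function(x, ...) {
  cat("<subject_session>", length(x$recordings), "recordings (",
      paste(x$electrodes, collapse = "+"), "x", x$n_blocks, "blocks ),",
      nrow(x$trials), "trials at", x$sampling_rate, "Hz\n")
  invisible(x)
}

#' Simulate electrode impedance records
#'
#' Draws per-(type, channel, block, subject) contact impedances from
#' log-normal distributions whose scales mirror typical wet-gel (~20 kOhm)
#' and dry multi-pin (~260 kOhm) electrode contacts.
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks Blocks per session (default 10).
#' @param n_channels Channels (default 8).
#' @param seed Integer seed.
#' @return Object of class `impedance_record`: list with `values`, a 4-D
#'   array \[type(2), channel, block, subject\] in kOhm (type 1 = wet,
#'   2 = dry).
#' @export
simulate_impedance <- function(n_subjects, n_blocks = 10, n_channels = 8,
                               seed = 1) {
  vals <- with_seed(seed, {
    a <- array(0, dim = c(2, n_channels, n_blocks, n_subjects))
    n <- n_channels * n_blocks * n_subjects
    a[1, , , ] <- stats::rlnorm(n, meanlog = log(18), sdlog = 0.45)
    a[2, , , ] <- stats::rlnorm(n, meanlog = log(230), sdlog = 0.55)
    a
  })
  structure(list(values = vals), class = "impedance_record")
}
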