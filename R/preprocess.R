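# Event-locked preprocessing: epoch extraction around stimulus onsets,
# anti-aliased downsampling, and extraction of the classification segment
# (latency-shifted stimulation window). Sample indexing is 0-based with
# half-open windows throughout; the stimulus onset sits at 0-based sample
# round(pre * rate) inside each epoch.

#' Epoch container
#'
#' @param data Numeric array channels x samples x trials.
#' @param sampling_rate Hz.
#' @param window `c(pre=, post=)` seconds around onset.
#' @param info Tibble with one row per trial (columns such as `target_index`,
#'   `block`, `electrode`).
#' @return Object of class `ssvep_epochs`. `onset_index` is the 0-based
#'   sample of stimulus onset within each epoch.
#' @export
ssvep_epochs <- function(data, sampling_rate, window = c(pre = 0.5, post = 2.34),
                         info = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(info))
    info <- tibble::tibble(trial = seq_len(dim(data)[3]))
  stopifnot(nrow(info) == dim(data)[3])
  structure(list(data = data, sampling_rate = sampling_rate,
                 window = window,
                 onset_index = round(window[["pre"]] * sampling_rate),
                 info = info),
            class = "ssvep_epochs")
}

#' @export
print.ssvep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<ssvep_epochs>", d[3], "trials x", d[1], "channels x", d[2],
      "samples at", x$sampling_rate, "Hz\n")
  invisible(x)
}

#' Extract event-locked epochs from a continuous recording
#'
#' Cuts one epoch per stimulus-onset event, spanning `window["pre"]` seconds
#' before to `window["post"]` seconds after onset (default 0.5 s + 2.34 s =
#' 2.84 s: pre-stimulus baseline, visual latency, 2 s stimulation, 0.2 s
#' post-stimulus).
#'
#' @param recording A `continuous_recording` (see [simulate_subject()]) with
#'   0-based `sample_index` events.
#' @param window `c(pre=, post=)` seconds.
#' @return An [ssvep_epochs()] object; trial order follows the event order.
#' @export
extract_epochs <- function(recording, window = c(pre = 0.5, post = 2.34)) {
  stopifnot(inherits(recording, "continuous_recording"))
  rate <- recording$sampling_rate
  pre_n <- round(window[["pre"]] * rate)
  post_n <- round(window[["post"]] * rate)
  n_total <- ncol(recording$signal)
  ev <- recording$events
  if (is.unsorted(ev$sample_index, strictly = TRUE))
    stop("event sample indices must be strictly increasing", call. = FALSE)
  bad <- which(ev$sample_index - pre_n < 0 | ev$sample_index + post_n > n_total)
  if (length(bad) > 0)
    stop("event(s) too close to the recording edge for the epoch window: event ",
         paste(bad, collapse = ", "), " (onset sample ",
         paste(ev$sample_index[bad], collapse = ", "), ")", call. = FALSE)
  n_ep <- pre_n + post_n
  out <- array(0, dim = c(nrow(recording$signal), n_ep, nrow(ev)))
  for (i in seq_len(nrow(ev))) {
    s0 <- ev$sample_index[i]                       # 0-based onset
    out[, , i] <- recording$signal[, (s0 - pre_n + 1):(s0 + post_n)]
  }
  dimnames(out)[[1]] <- recording$channel_names
  ssvep_epochs(out, rate, window,
               info = tibble::tibble(trial = seq_len(nrow(ev)),
                                     target_index = ev$target_index,
                                     onset_sample = ev$sample_index))
}

#' Downsample epochs with anti-alias filtering
#'
#' Zero-phase FIR low-pass (cutoff at the target Nyquist) followed by
#' decimation. The original rate must be an integer multiple of
#' `target_rate`; a 2.84 s epoch at 1000 Hz becomes 710 samples at 250 Hz.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param target_rate Target sampling rate in Hz (default 250).
#' @param fir_order Anti-alias FIR order (default 64).
#' @return Downsampled [ssvep_epochs()].
#' @export
downsample_epochs <- function(epochs, target_rate = 250, fir_order = 64) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  rate <- epochs$sampling_rate
  if (rate == target_rate) return(epochs)
  q <- rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop("sampling rate ", rate, " is not an integer multiple of ",
         target_rate, call. = FALSE)
  q <- round(q)
  h <- as.numeric(signal::fir1(fir_order, 1 / q))
  h <- h / sum(h)               # unit DC gain exactly
  d <- dim(epochs$data)
  keep <- seq(1, d[2], by = q)
  pad <- 3 * fir_order          # odd-reflection padding tames edge transients
  out <- array(0, dim = c(d[1], length(keep), d[3]))
  for (tr in seq_len(d[3])) for (ch in seq_len(d[1])) {
    x <- epochs$data[ch, , tr]
    n <- length(x)
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    filtered <- signal::filtfilt(h, 1, xp)[(pad + 1):(pad + n)]
    out[ch, , tr] <- filtered[keep]
  }
  dimnames(out)[[1]] <- dimnames(epochs$data)[[1]]
  ssvep_epochs(out, target_rate, epochs$window, info = epochs$info)
}

#' 0-based start index of the classification segment
#'
#' The decoded segment starts at onset + visual latency; at 250 Hz with the
#' default 0.5 s pre-window and 0.14 s latency this is sample 160.
#'
#' @param sampling_rate Hz.
#' @param pre Pre-onset window seconds.
#' @param latency Visual latency seconds.
#' @return Integer 0-based sample index.
#' @export
segment_start_index <- function(sampling_rate, pre = 0.5, latency = 0.14) {
  round((pre + latency) * sampling_rate)
}

#' Extract the latency-shifted classification segment
#'
#' Returns, per trial, the samples covering the half-open window
#' \[onset + latency, onset + latency + data_length) used for decoding.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param data_length Segment length in seconds, in (0, 2].
#' @param latency Visual latency in seconds (default 0.14).
#' @return An [ssvep_epochs()] object whose samples are the decoded segment
#'   (the onset no longer lies inside the window).
#' @export
classification_segment <- function(epochs, data_length, latency = 0.14) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  if (data_length <= 0 || data_length > 2)
    stop("`data_length` must be in (0, 2] seconds", call. = FALSE)
  rate <- epochs$sampling_rate
  start0 <- epochs$onset_index + round(latency * rate)  # 0-based
  n <- round(data_length * rate)
  if (start0 + n > dim(epochs$data)[2])
    stop("segment [", start0, ", ", start0 + n,
         ") exceeds the epoch length ", dim(epochs$data)[2], call. = FALSE)
  seg <- epochs$data[, (start0 + 1):(start0 + n), , drop = FALSE]
  dimnames(seg)[[1]] <- dimnames(epochs$data)[[1]]
  out <- ssvep_epochs(seg, rate, window = c(pre = 0, post = n / rate),
                      info = epochs$info)
  out$onset_index <- NA_integer_
  out
}

#' Assemble a subject session into the 5-D record layout
#'
#' Runs the preprocessing chain on a simulated session: extract 2.84 s
#' epochs from each continuous block recording, downsample to `target_rate`,
#' and place each trial into the channel x time x electrode x block x target
#' array (electrode axis 1 = wet, 2 = dry).
#'
#' @param session A `subject_session` from [simulate_subject()].
#' @param target_rate Stored sampling rate (default 250 Hz).
#' @param window Epoch window `c(pre=, post=)` seconds.
#' @return A [subject_record()].
#' @export
session_to_record <- function(session, target_rate = 250,
                              window = c(pre = 0.5, post = 2.34)) {
  stopifnot(inherits(session, "subject_session"))
  n_t <- round(sum(window) * target_rate)
  electrodes <- session$electrodes
  arr <- array(NA_real_, dim = c(8, n_t, length(electrodes),
                                 session$n_blocks, 12))
  for (e in seq_along(electrodes)) {
    for (b in seq_len(session$n_blocks)) {
      rec <- session$recordings[[paste0(electrodes[e], "_block", b)]]
      ep <- downsample_epochs(extract_epochs(rec, window), target_rate)
      for (i in seq_len(nrow(ep$info)))
        arr[, , e, b, ep$info$target_index[i]] <- ep$data[, , i]
    }
  }
  subject_record(arr, sampling_rate = target_rate, epoch_window = window,
                 electrodes = electrodes)
}

#' Epochs of one electrode session from a 5-D record
#'
#' Flattens the block x target grid of one electrode session into an epoch
#' stack with trial metadata.
#'
#' @param record A [subject_record()].
#' @param electrode `"wet"` or `"dry"` (must be present in the record).
#' @return An [ssvep_epochs()] object with `block` and `target_index` info.
#' @export
record_to_epochs <- function(record, electrode = "wet") {
  stopifnot(inherits(record, "subject_record"))
  e <- match(electrode, record$electrodes)
  if (is.na(e))
    stop("electrode '", electrode, "' not present in record (has: ",
         paste(record$electrodes, collapse = ", "), ")", call. = FALSE)
  d <- dim(record$data)
  n_trials <- d[4] * d[5]
  out <- array(0, dim = c(d[1], d[2], n_trials))
  info <- tibble::tibble(trial = seq_len(n_trials),
                         block = rep(seq_len(d[4]), each = d[5]),
                         target_index = rep(seq_len(d[5]), times = d[4]),
                         electrode = electrode)
  i <- 0
  for (b in seq_len(d[4])) for (k in seq_len(d[5])) {
    i <- i + 1
    out[, , i] <- record$data[, , e, b, k]
  }
  dimnames(out)[[1]] <- record$channel_names
  ssvep_epochs(out, record$sampling_rate, record$epoch_window, info = info)
}
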