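#' Speller layout: 12 joint frequency-phase coded targets
#'
#' The 12-target virtual phone keypad encodes each key by a unique
#' (frequency, phase) pair: frequencies 9.25 to 14.75 Hz in 0.5 Hz steps,
#' with a 0.5*pi phase increment between targets adjacent in frequency.
#' Flicker is rendered by frame-wise sampled sinusoidal modulation on a
#' display refreshing at `refresh_rate` frames per second.
#'
#' @param refresh_rate Display refresh rate in frames/s. Must exceed twice
#'   the highest stimulus frequency.
#' @return An object of class `speller_layout`: a list with a `stimuli`
#'   tibble (`target_index`, `label`, `frequency`, `phase`) and
#'   `refresh_rate`.
#' @examples
#' layout <- speller_layout()
#' layout$stimuli
#' @export
speller_layout <- function(refresh_rate = 60) {
  freqs <- seq(9.25, 14.75, by = 0.5)
  if (!is.numeric(refresh_rate) || length(refresh_rate) != 1 || refresh_rate <= 0)
    stop("`refresh_rate` must be a positive scalar", call. = FALSE)
  if (refresh_rate <= 2 * max(freqs))
    stop("`refresh_rate` must exceed twice the maximum stimulus frequency (",
         2 * max(freqs), " Hz)", call. = FALSE)
  labels <- c("1", "2", "3", "4", "5", "6", "7", "8", "9", "*", "0", "#")
  stimuli <- tibble::tibble(
    target_index = 1:12,
    label = labels,
    frequency = freqs,
    phase = ((0:11) * 0.5 * pi) %% (2 * pi)
  )
  structure(list(stimuli = stimuli, refresh_rate = refresh_rate),
            class = "speller_layout")
}

#' @export
print.speller_layout <- function(x, ...) {
  cat("<speller_layout> 12 targets,", x$refresh_rate, "Hz refresh\n")
  print(x$stimuli, n = 12)
  invisible(x)
}

#' Frame-wise stimulus luminance sequence
#'
#' Luminance of frame i (counted from 0) for a target flickering at
#' frequency f with phase phi on a display refreshing at R frames/s:
#' s(i) = 0.5 * (1 + sin(2*pi*f*(i/R) + phi)), bounded in \[0, 1\] with 0
#' the lowest and 1 the highest luminance.
#'
#' @param frequency Flicker frequency in Hz (scalar > 0).
#' @param phase Flicker phase in radians.
#' @param n_frames Number of frames to generate (>= 1).
#' @param refresh_rate Display refresh rate in frames/s.
#' @return Numeric vector of `n_frames` luminance values in \[0, 1\].
#' @examples
#' generate_stimulus_sequence(9.25, 0.5 * pi, n_frames = 60)
#' @export
generate_stimulus_sequence <- function(frequency, phase, n_frames,
                                       refresh_rate = 60) {
  if (!is.numeric(refresh_rate) || length(refresh_rate) != 1 ||
      !is.finite(refresh_rate) || refresh_rate <= 0)
    stop("invalid configuration: `refresh_rate` must be a positive number",
         call. = FALSE)
  if (!is.numeric(n_frames) || length(n_frames) != 1 || n_frames < 1)
    stop("`n_frames` must be >= 1", call. = FALSE)
  if (!is.numeric(frequency) || frequency <= 0)
    stop("`frequency` must be positive", call. = FALSE)
  i <- seq_len(n_frames) - 1
  0.5 * (1 + sin(2 * pi * frequency * (i / refresh_rate) + phase))
}
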