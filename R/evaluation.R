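# Performance evaluation: information transfer rate, single-sided amplitude
# spectra and narrowband SNR, filter-bank parameter grid search, harmonic-
# count sweep, group-level paired statistics, and block-wise accuracy trends.

#' Information transfer rate (bits/min)
#'
#' ITR = (log2 N + P log2 P + (1-P) log2((1-P)/(N-1))) * 60 / T, with
#' P log2 P := 0 at P = 0 and the (1-P) term := 0 at P = 1. Zero exactly at
#' chance (P = 1/N) and strictly increasing in P above chance.
#'
#' @param n_targets N, number of selectable targets (>= 2).
#' @param p Mean classification accuracy in \[0, 1\] (vectorized).
#' @param t_select T, seconds per selection (> 0).
#' @return ITR in bits/min.
#' @examples
#' itr(12, 1, 2)      # 30 * log2(12)
#' itr(12, 1/12, 2)   # 0 at chance
#' @export
itr <- function(n_targets, p, t_select) {
  if (n_targets < 2) stop("`n_targets` must be >= 2", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  if (any(t_select <= 0)) stop("`t_select` must be > 0", call. = FALSE)
  term_p <- ifelse(p == 0, 0, p * log2(p))
  term_q <- ifelse(p == 1, 0, (1 - p) * log2((1 - p) / (n_targets - 1)))
  (log2(n_targets) + term_p + term_q) * 60 / t_select
}

#' Single-sided amplitude spectrum
#'
#' FFT amplitude spectrum scaled so a full-bin sinusoid of amplitude A peaks
#' at A. The frequency resolution is 1 / window length: a 2 s window gives
#' 0.5 Hz bins; the x.25 / x.75 Hz stimulus frequencies need a 4 s window
#' (0.25 Hz bins) to fall exactly on-bin (see [epoch_snr()] for the
#' off-bin-safe SNR evaluation).
#'
#' @param x Numeric vector (one channel of one segment).
#' @param sampling_rate Hz.
#' @return Object of class `spectrum_estimate`: tibble-backed list with
#'   `frequency`, `amplitude`, and `delta_f`.
#' @export
amplitude_spectrum <- function(x, sampling_rate) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  n <- length(x)
  A <- abs(stats::fft(x)) / n
  nf <- floor(n / 2) + 1
  amp <- A[seq_len(nf)]
  if (n %% 2 == 0) amp[2:(nf - 1)] <- 2 * amp[2:(nf - 1)]
  else if (nf > 1) amp[2:nf] <- 2 * amp[2:nf]
  structure(list(
    frequency = (seq_len(nf) - 1) * sampling_rate / n,
    amplitude = amp,
    delta_f = sampling_rate / n,
    n_samples = n, sampling_rate = sampling_rate
  ), class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat("<spectrum_estimate>", length(x$frequency), "bins, delta_f =",
      x$delta_f, "Hz up to", max(x$frequency), "Hz\n")
  invisible(x)
}

#' Narrowband SNR in dB
#'
#' SNR(f) = 20 log10( y(f) / sum_{k=1..K} (y(f - k df) + y(f + k df)) ): the
#' spectral amplitude at f against the summed amplitude of its K nearest
#' neighbours on each side. A flat spectrum gives -20 log10(2K) dB
#' (-20 dB for the default K = 5). `variant = "mean"` divides the
#' denominator by 2K (a constant +20 log10(2K) dB offset).
#'
#' @param spectrum A [amplitude_spectrum()].
#' @param f Target frequency in Hz (must fall on a bin within the range
#'   admitting all 2K neighbours).
#' @param k Neighbours per side (default 5).
#' @param variant `"sum"` (default) or `"mean"` neighbour aggregation.
#' @return SNR in dB.
#' @export
snr_db <- function(spectrum, f, k = 5, variant = c("sum", "mean")) {
  variant <- match.arg(variant)
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  i <- which.min(abs(spectrum$frequency - f))
  if (abs(spectrum$frequency[i] - f) > spectrum$delta_f / 2 + 1e-9)
    stop("frequency ", f, " Hz is outside the spectrum range", call. = FALSE)
  idx <- c(i - (k:1), i + (1:k))   # the K bins on each side of f
  if (any(idx < 1 | idx > length(spectrum$frequency)))
    stop("neighbour bins of ", f, " Hz fall outside the spectrum",
         call. = FALSE)
  denom <- sum(spectrum$amplitude[idx])
  if (variant == "mean") denom <- denom / (2 * k)
  20 * log10(spectrum$amplitude[i] / denom)
}

#' Trial-averaged narrowband SNR of an epoch set
#'
#' Takes the 2 s stimulation window (starting one visual latency after
#' onset) of one channel, averages it across trials, and returns the
#' narrowband SNR of the averaged waveform at `frequency`. Because the
#' steady-state response is time-locked to stimulus onset, the coherent
#' average suppresses the background-noise floor while preserving the
#' evoked peaks — the same grand-average construction behind group-level
#' SSVEP spectra. Set `coherent = FALSE` to average single-trial amplitude
#' spectra instead (keeps the single-trial noise floor).
#'
#' @param epochs An [ssvep_epochs()] object (full epochs; all trials should
#'   share one stimulus target).
#' @param frequency Hz.
#' @param channel Channel name or index (default `"Oz"`).
#' @param latency Visual latency (default 0.14 s).
#' @param window_length Spectrum window in seconds (default 2).
#' @param coherent Average waveforms (TRUE, default) or single-trial
#'   amplitudes (FALSE).
#' @param k Neighbours per side in the SNR denominator (default 5).
#' @return SNR in dB.
#' @details The stimulus frequencies (x.25 / x.75 Hz) fall between the FFT
#'   bins of a 2 s window, so the SNR is computed from the DFT amplitude
#'   evaluated exactly at `frequency` and at `frequency + j / T` for
#'   j = -k..-1, 1..k: offsets at integer multiples of the 1/T resolution
#'   are orthogonal to the stimulus component over the window, which keeps
#'   the neighbour amplitudes leakage-free.
#' @export
epoch_snr <- function(epochs, frequency, channel = "Oz", latency = 0.14,
                      window_length = 2, coherent = TRUE, k = 5) {
  seg <- classification_segment(epochs, window_length, latency)
  ch <- if (is.character(channel))
    match(channel, dimnames(seg$data)[[1]]) else channel
  if (is.na(ch)) stop("channel not found: ", channel, call. = FALSE)
  rate <- seg$sampling_rate
  n <- dim(seg$data)[2]
  delta_f <- 1 / window_length
  freqs <- frequency + delta_f * c(0, -(k:1), 1:k)
  amp_of <- function(x) dft_amplitude(x, rate, freqs)
  waves <- matrix(seg$data[ch, , ], nrow = n)
  amps <- if (coherent) amp_of(rowMeans(waves))
  else rowMeans(apply(waves, 2, amp_of))
  20 * log10(amps[1] / sum(amps[-1]))
}

# Single-sided DFT amplitude of `x` evaluated at arbitrary frequencies.
dft_amplitude <- function(x, sampling_rate, freqs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / sampling_rate
  vapply(freqs, function(f)
    2 * Mod(sum(x * exp(-2i * pi * f * t))) / n, numeric(1))
}

# --- grid search ------------------------------------------------------------

# Per-trial FBCCA sub-band correlations over the maximal sub-band set.
fbcca_rho_array <- function(seg, layout, n_subbands_max, n_harmonics,
                            base_config) {
  rate <- seg$sampling_rate
  refs <- make_references(layout, n_harmonics, rate, dim(seg$data)[2])
  cfg <- filter_bank_config(n_subbands_max, base_config$a, base_config$b,
                            filter_order = base_config$filter_order,
                            ripple_db = base_config$ripple_db)
  subbands <- fb_decompose_trials(seg$data, cfg, rate)
  n_tr <- dim(seg$data)[3]
  K <- length(refs$references)
  rho <- array(0, dim = c(n_subbands_max, K, n_tr))
  for (n in seq_len(n_subbands_max))
    for (i in seq_len(n_tr))
      rho[n, , i] <- cca_correlations(subbands[[n]][, , i], refs)
  rho
}

# Per-trial FBTRCA features over the maximal sub-band set, computed with
# leave-one-block-out training (training is independent of a, b, N).
fbtrca_feature_array <- function(seg, n_subbands_max, base_config, ensemble) {
  rate <- seg$sampling_rate
  cfg <- filter_bank_config(n_subbands_max, base_config$a, base_config$b,
                            filter_order = base_config$filter_order,
                            ripple_db = base_config$ripple_db)
  subbands <- fb_decompose_trials(seg$data, cfg, rate)
  info <- seg$info
  K <- max(info$target_index)
  n_tr <- nrow(info)
  feats <- array(0, dim = c(n_subbands_max, K, n_tr))
  for (b in sort(unique(info$block))) {
    train_idx <- which(info$block != b)
    test_idx <- which(info$block == b)
    for (n in seq_len(n_subbands_max)) {
      model <- train_trca(subbands[[n]][, , train_idx, drop = FALSE],
                          info$target_index[train_idx], n_classes = K)
      for (i in test_idx)
        for (k in seq_len(K))
          feats[n, k, i] <- trca_feature(subbands[[n]][, , i], model, k,
                                         ensemble = ensemble)
    }
  }
  feats
}

# Per-trial ET fused features p over the maximal sub-band set.
et_feature_array <- function(train_seg, test_seg, layout, projection,
                             n_subbands_max, base_config, n_harmonics) {
  rate <- test_seg$sampling_rate
  cfg <- filter_bank_config(n_subbands_max, base_config$a, base_config$b,
                            filter_order = base_config$filter_order,
                            ripple_db = base_config$ripple_db)
  model <- build_et_model(train_seg$data, train_seg$info$target_index,
                          projection, cfg, layout, rate, n_harmonics)
  refs <- make_references(layout, n_harmonics, rate, dim(test_seg$data)[2])
  subbands <- fb_decompose_trials(test_seg$data, cfg, rate)
  K <- model$n_classes
  n_tr <- dim(test_seg$data)[3]
  p <- array(0, dim = c(n_subbands_max, K, n_tr))
  for (i in seq_len(n_tr)) {
    for (n in seq_len(n_subbands_max)) {
      X <- subbands[[n]][, , i]
      Xc <- X - rowMeans(X)
      for (k in seq_len(K)) {
        tau <- model$templates[[n]][, k]
        v <- ls_spatial_filter(X, tau)
        proj <- as.vector(crossprod(v, Xc))
        r1 <- if (stats::sd(proj) < 1e-12) 0 else stats::cor(proj, tau)
        r2 <- cca_first_correlation(X, refs$references[[k]])
        p[n, k, i] <- sign(r1) * r1^2 + sign(r2) * r2^2
      }
    }
  }
  p
}

# Accuracy at one grid cell from a feature array [N_max, K, trials]:
# FBCCA combines rho^2, FBTRCA sign(r)*r^2, ET the fused p directly.
cell_accuracy <- function(feat, truth, a, b, n_sub, transform) {
  w <- fb_weights(a, b, n_sub)
  ft <- transform(feat[seq_len(n_sub), , , drop = FALSE])
  n_tr <- dim(ft)[3]
  correct <- vapply(seq_len(n_tr), function(i) {
    s <- as.numeric(crossprod(matrix(ft[, , i], nrow = n_sub), w))
    which.max(s) == truth[i]
  }, logical(1))
  mean(correct)
}

#' Grid search over the filter-bank weight parameters
#'
#' Evaluates mean classification accuracy over the full (a, b, N) grid —
#' a in 0.25..2 by 0.25, b in 0..1 by 0.25, N in 1..6 (240 cells) — and
#' returns the accuracy surface and its maximum. Supervised methods are
#' scored by leave-one-block-out cross-validation; sub-band features are
#' computed once per subject and reweighted per cell. Ties are broken by
#' smaller N, then smaller a, then smaller b.
#'
#' @param data A list of subject inputs: for `"fbcca"`/`"fbtrca"`, each an
#'   [ssvep_epochs()] object (full epochs with `block`/`target_index`); for
#'   `"et-avg"`/`"et-cca"`/`"et-trca"`, each a list
#'   `list(train = epochs, test = epochs)`. A bare epochs object is treated
#'   as one subject.
#' @param layout A [speller_layout()].
#' @param method One of `"fbcca"`, `"fbtrca"`, `"et-avg"`, `"et-cca"`,
#'   `"et-trca"`.
#' @param data_length Segment length in seconds (default 1).
#' @param a_grid,b_grid,n_grid Grid values.
#' @param latency Visual latency (default 0.14 s).
#' @param n_harmonics Reference harmonics (default 5).
#' @param ensemble FBTRCA ensemble variant (default TRUE).
#' @param base_config Filter design metadata (order/ripple) reused across
#'   cells.
#' @return Object of class `grid_search_result`: `surface` tibble
#'   (a, b, n_subbands, accuracy), `optimum` (one-row tibble), `method`.
#' @export
grid_search <- function(data, layout, method = c("fbcca", "fbtrca", "et-avg",
                                                 "et-cca", "et-trca"),
                        data_length = 1,
                        a_grid = seq(0.25, 2, by = 0.25),
                        b_grid = seq(0, 1, by = 0.25),
                        n_grid = 1:6,
                        latency = 0.14, n_harmonics = 5, ensemble = TRUE,
                        base_config = filter_bank_config()) {
  method <- match.arg(method)
  if (inherits(data, "ssvep_epochs")) data <- list(data)
  n_max <- max(n_grid)
  per_subject <- lapply(data, function(d) {
    if (startsWith(method, "et-")) {
      stopifnot(is.list(d), !is.null(d$train), !is.null(d$test))
      tr_seg <- classification_segment(d$train, data_length, latency)
      te_seg <- classification_segment(d$test, data_length, latency)
      feat <- et_feature_array(tr_seg, te_seg, layout,
                               sub("et-", "", method), n_max, base_config,
                               n_harmonics)
      list(feat = feat, truth = te_seg$info$target_index)
    } else {
      seg <- classification_segment(d, data_length, latency)
      feat <- if (method == "fbcca")
        fbcca_rho_array(seg, layout, n_max, n_harmonics, base_config)
      else fbtrca_feature_array(seg, n_max, base_config, ensemble)
      list(feat = feat, truth = seg$info$target_index)
    }
  })
  transform <- switch(method,
    fbcca = function(x) x^2,
    fbtrca = function(x) sign(x) * x^2,
    function(x) x)   # ET: fused p enters the weighted sum directly
  grid <- expand.grid(a = a_grid, b = b_grid, n_subbands = n_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(per_subject, function(s)
      cell_accuracy(s$feat, s$truth, grid$a[i], grid$b[i],
                    grid$n_subbands[i], transform), numeric(1)))
  }, numeric(1))
  surface <- tibble::as_tibble(grid)
  ord <- order(-surface$accuracy, surface$n_subbands, surface$a, surface$b)
  optimum <- surface[ord[1], ]
  structure(list(surface = surface, optimum = optimum, method = method,
                 data_length = data_length, n_subjects = length(per_subject)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("<grid_search_result>", toupper(x$method), "over", nrow(x$surface),
      "cells (", x$n_subjects, "subject[s] ):\n  optimum a =", x$optimum$a,
      ", b =", x$optimum$b, ", N =", x$optimum$n_subbands, "at accuracy",
      sprintf("%.3f", x$optimum$accuracy), "\n")
  invisible(x)
}

#' Accuracy of standard CCA as a function of the harmonic count
#'
#' @param epochs An [ssvep_epochs()] object (full epochs with
#'   `target_index`).
#' @param layout A [speller_layout()].
#' @param nh_range Harmonic counts to evaluate (default 1:6).
#' @param data_length Segment length in seconds (default 1).
#' @param latency Visual latency (default 0.14 s).
#' @return Tibble with `n_harmonics` and `accuracy`.
#' @export
harmonic_sweep <- function(epochs, layout, nh_range = 1:6, data_length = 1,
                           latency = 0.14) {
  seg <- classification_segment(epochs, data_length, latency)
  rate <- seg$sampling_rate
  n_tr <- dim(seg$data)[3]
  acc <- vapply(nh_range, function(nh) {
    refs <- make_references(layout, nh, rate, dim(seg$data)[2])
    correct <- vapply(seq_len(n_tr), function(i)
      cca_classify(seg$data[, , i], refs)$predicted ==
        seg$info$target_index[i], logical(1))
    mean(correct)
  }, numeric(1))
  tibble::tibble(n_harmonics = nh_range, accuracy = acc)
}

# --- group-level statistics -------------------------------------------------

#' Paired wet-vs-dry group statistics
#'
#' Takes a per-subject performance table with paired wet and dry
#' observations and (optionally) a per-subject impedance table, and computes
#' the study's group-level analyses: two-sided paired t-tests per metric,
#' the Pearson correlation between wet and dry accuracies, accuracy vs.
#' impedance correlations per electrode, the correlation between the
#' wet-dry accuracy difference and impedance difference, and the three-way
#' split of subjects by a +/-10 percentage-point accuracy difference.
#'
#' @param performance Tibble with columns `subject`, `electrode`
#'   (`"wet"`/`"dry"`), `accuracy`, and optionally further numeric metrics
#'   (e.g. `itr`, `snr`) that will also be paired-tested.
#' @param impedance Optional tibble with `subject`, `electrode`,
#'   `impedance` (kOhm).
#' @return Object of class `group_stats`: tibbles `paired_tests`,
#'   `correlations`, and `difference_groups`.
#' @export
group_stats <- function(performance, impedance = NULL) {
  need <- c("subject", "electrode", "accuracy")
  if (!all(need %in% names(performance)))
    stop("`performance` must have columns subject, electrode, accuracy",
         call. = FALSE)
  metrics <- setdiff(names(performance)[vapply(performance, is.numeric,
                                               logical(1))], "subject")
  wide <- function(metric, tbl = performance) {
    w <- tidyr::pivot_wider(tbl[c("subject", "electrode", metric)],
                            names_from = "electrode",
                            values_from = dplyr::all_of(metric))
    if (!all(c("wet", "dry") %in% names(w)) || anyNA(w$wet) || anyNA(w$dry))
      stop("unpaired input: every subject needs one wet and one dry value for ",
           metric, call. = FALSE)
    w
  }
  paired_tests <- dplyr::bind_rows(lapply(metrics, function(m) {
    w <- wide(m)
    d <- w$wet - w$dry
    if (stats::sd(d) < 1e-12) {
      # degenerate paired sample (constant differences)
      tstat <- if (abs(mean(d)) < 1e-12) 0 else sign(mean(d)) * Inf
      tibble::tibble(metric = m, mean_wet = mean(w$wet),
                     mean_dry = mean(w$dry), t = tstat,
                     df = length(d) - 1,
                     p_value = if (tstat == 0) 1 else 0)
    } else {
      tt <- stats::t.test(w$wet, w$dry, paired = TRUE)
      tibble::tibble(metric = m, mean_wet = mean(w$wet), mean_dry = mean(w$dry),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value)
    }
  }))
  # Pearson r with NA (not a warning) on zero-variance input
  safe_cor <- function(x, y) {
    if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15)
      return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, y)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  acc <- wide("accuracy")
  rw <- safe_cor(acc$wet, acc$dry)
  cors <- list(tibble::tibble(comparison = "accuracy_wet_vs_dry",
                              r = rw[["r"]], p_value = rw[["p"]]))
  if (!is.null(impedance)) {
    imp <- wide("impedance", impedance)
    for (el in c("wet", "dry")) {
      ri <- safe_cor(acc[[el]], imp[[el]])
      cors[[length(cors) + 1]] <- tibble::tibble(
        comparison = paste0("accuracy_vs_impedance_", el),
        r = ri[["r"]], p_value = ri[["p"]])
    }
    rd <- safe_cor(acc$wet - acc$dry, imp$wet - imp$dry)
    cors[[length(cors) + 1]] <- tibble::tibble(
      comparison = "accuracy_diff_vs_impedance_diff",
      r = rd[["r"]], p_value = rd[["p"]])
  }
  diff <- acc$wet - acc$dry
  difference_groups <- tibble::tibble(
    group = c("wet_better_10pct", "within_10pct", "dry_better_10pct"),
    n_subjects = c(sum(diff >= 0.10), sum(abs(diff) < 0.10),
                   sum(diff <= -0.10)),
    proportion = c(mean(diff >= 0.10), mean(abs(diff) < 0.10),
                   mean(diff <= -0.10)))
  structure(list(paired_tests = paired_tests,
                 correlations = dplyr::bind_rows(cors),
                 difference_groups = difference_groups,
                 n_subjects = nrow(acc)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("<group_stats>", x$n_subjects, "paired subjects\n")
  print(x$paired_tests)
  print(x$correlations)
  invisible(x)
}

#' Block-wise accuracy trend
#'
#' Per-block mean accuracy and the least-squares slope of accuracy against
#' block index — the check that performance stays stable over the session.
#'
#' @param block_accuracy Tibble with columns `block` and `accuracy`
#'   (several rows per block, e.g. subjects, are averaged).
#' @return Object of class `block_trend`: `per_block` tibble, `slope`,
#'   `intercept`, `slope_p_value`.
#' @export
block_trend <- function(block_accuracy) {
  stopifnot(all(c("block", "accuracy") %in% names(block_accuracy)))
  if (length(unique(block_accuracy$block)) < 2)
    stop("need >= 2 blocks", call. = FALSE)
  per_block <- block_accuracy |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  fit <- stats::lm(accuracy ~ block, data = per_block)
  # constant accuracy is legitimate input; the perfect-fit caveat is expected
  coefs <- suppressWarnings(summary(fit)$coefficients)
  structure(list(per_block = per_block,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_p_value = if (nrow(coefs) > 1 && ncol(coefs) >= 4)
                   coefs[2, 4] else NA_real_),
            class = "block_trend")
}

#' @export
print.block_trend <- function(x, ...) {
  cat("<block_trend>", nrow(x$per_block), "blocks; slope",
      sprintf("%.4f", x$slope), "per block\n")
  invisible(x)
}
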