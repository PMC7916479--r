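# Frequency decoders: standard CCA, filter-bank CCA (FBCCA), task-related
# component analysis (TRCA) with its filter-bank ensemble variant (FBTRCA),
# and block-wise leave-one-out cross-validation.

# --- feature extraction -----------------------------------------------------

# Decompose every trial of a 3-D segment stack into sub-bands once.
# Returns a list over sub-bands of channels x samples x trials arrays.
fb_decompose_trials <- function(segments, config, sampling_rate) {
  stopifnot(length(dim(segments)) == 3)
  lapply(config$passbands, function(p) {
    out <- segments
    for (tr in seq_len(dim(segments)[3]))
      out[, , tr] <- bandpass_matrix(segments[, , tr], p[1], p[2],
                                     sampling_rate, config$filter_order,
                                     config$ripple_db)
    out
  })
}

# CCA correlations of one segment against every reference: length-K vector.
cca_correlations <- function(segment, references) {
  vapply(references$references, function(ref)
    cca_first_correlation(segment, ref), numeric(1))
}

#' Classify one segment with standard CCA
#'
#' Picks the target whose sinusoidal reference attains the highest first
#' canonical correlation with the (unfiltered) segment.
#'
#' @param segment Channels x samples matrix.
#' @param references A [make_references()] set with matching sample count.
#' @return List with `predicted` (target index, ties broken by the lowest
#'   index) and `scores` (per-target correlations).
#' @export
cca_classify <- function(segment, references) {
  rho <- cca_correlations(segment, references)
  list(predicted = which.max(rho), scores = rho)
}

#' Classify one segment with FBCCA
#'
#' Scores target k as the weighted sum over sub-bands n of the squared first
#' canonical correlation between the band-passed segment and reference k:
#' score_k = sum_n w(n) * rho_{n,k}^2 with w(n) = n^(-a) + b.
#'
#' @param segment Channels x samples matrix.
#' @param references A [make_references()] set.
#' @param config A [filter_bank_config()].
#' @param sampling_rate Hz.
#' @return List with `predicted`, `scores` (length-K weighted sums), and
#'   `rho` (N x K sub-band correlation matrix).
#' @export
fbcca_classify <- function(segment, references, config, sampling_rate) {
  subbands <- fb_decompose(segment, config, sampling_rate)
  rho <- t(vapply(subbands, function(sb) cca_correlations(sb, references),
                  numeric(length(references$references))))
  w <- fb_weights(config$a, config$b, config$n_subbands)
  scores <- as.numeric(crossprod(rho^2, w))
  list(predicted = which.max(scores), scores = scores, rho = rho)
}

# --- TRCA -------------------------------------------------------------------

# TRCA spatial filter from a channels x samples x trials stack: top
# generalized eigenvector of (summed inter-trial cross-covariance) against
# (covariance of the concatenated trials).
trca_filter <- function(trials, ridge = 1e-8) {
  d <- dim(trials)
  if (d[3] < 2) stop("TRCA needs >= 2 training trials per class", call. = FALSE)
  centered <- trials
  for (tr in seq_len(d[3]))
    centered[, , tr] <- trials[, , tr] - rowMeans(trials[, , tr])
  Q <- matrix(0, d[1], d[1])
  total <- matrix(0, d[1], d[2])
  for (tr in seq_len(d[3])) {
    Q <- Q + tcrossprod(centered[, , tr])
    total <- total + centered[, , tr]
  }
  S <- tcrossprod(total) - Q
  Qs <- ridge_stabilise(Q, ridge)
  ev <- eigen(solve(Qs, S))
  w <- Re(ev$vectors[, 1])
  w * sign(w[which.max(abs(w))])   # largest-magnitude entry positive
}

#' Train TRCA models for one sub-band
#'
#' For every class: the TRCA spatial filter (maximizing inter-trial
#' reproducibility of the projected component) and the class template (mean
#' of the training trials).
#'
#' @param segments Channels x samples x trials array (already band-passed
#'   for the sub-band being trained).
#' @param targets Integer class label per trial.
#' @param n_classes Number of classes (default `max(targets)`).
#' @return Object of class `trca_model`: `filters` (channels x classes
#'   matrix) and `templates` (channels x samples x classes array).
#' @export
train_trca <- function(segments, targets, n_classes = max(targets)) {
  d <- dim(segments)
  stopifnot(length(targets) == d[3])
  filters <- matrix(0, d[1], n_classes)
  templates <- array(0, dim = c(d[1], d[2], n_classes))
  for (k in seq_len(n_classes)) {
    idx <- which(targets == k)
    if (length(idx) < 2)
      stop("TRCA needs >= 2 training trials for class ", k, call. = FALSE)
    filters[, k] <- trca_filter(segments[, , idx, drop = FALSE])
    templates[, , k] <- apply(segments[, , idx, drop = FALSE], c(1, 2), mean)
  }
  structure(list(filters = filters, templates = templates,
                 n_classes = n_classes, n_samples = d[2],
                 channel_names = dimnames(segments)[[1]]),
            class = "trca_model")
}

#' @export
print.trca_model <- function(x, ...) {
  cat("<trca_model>", x$n_classes, "classes,", nrow(x$filters), "channels,",
      x$n_samples, "samples\n")
  invisible(x)
}

# Correlation feature of one test segment against class k in one sub-band.
trca_feature <- function(segment, model, k, ensemble = TRUE) {
  if (ensemble) {
    W <- model$filters
    a <- as.vector(crossprod(W, segment))
    b <- as.vector(crossprod(W, model$templates[, , k]))
  } else {
    w <- model$filters[, k]
    a <- as.vector(crossprod(w, segment))
    b <- as.vector(crossprod(w, model$templates[, , k]))
  }
  stats::cor(a, b)
}

#' Train a filter-bank TRCA model bank
#'
#' Decomposes the training trials into sub-bands and trains one
#' [train_trca()] model per sub-band.
#'
#' @param segments Channels x samples x trials array of classification
#'   segments.
#' @param targets Integer class label per trial.
#' @param config A [filter_bank_config()].
#' @param sampling_rate Hz.
#' @return Object of class `fbtrca_model`: list of per-sub-band
#'   `trca_model`s plus the configuration.
#' @export
fbtrca_train <- function(segments, targets, config, sampling_rate) {
  subbands <- fb_decompose_trials(segments, config, sampling_rate)
  models <- lapply(subbands, train_trca, targets = targets,
                   n_classes = max(targets))
  structure(list(models = models, config = config,
                 sampling_rate = sampling_rate,
                 n_samples = dim(segments)[2]),
            class = "fbtrca_model")
}

#' Classify one segment with FBTRCA
#'
#' Feature of class k in sub-band n: correlation between the spatially
#' filtered test segment and the equally filtered class template (ensemble:
#' all classes' filters stacked). Combined score
#' sum_n w(n) * sign(r) * r^2; prediction is the argmax (ties broken by the
#' lowest class index).
#'
#' @param segment Channels x samples matrix.
#' @param model An [fbtrca_train()] model bank.
#' @param ensemble Use the ensemble variant (default TRUE).
#' @return List with `predicted`, `scores`, and `features` (N x K matrix of
#'   correlations).
#' @export
fbtrca_classify <- function(segment, model, ensemble = TRUE) {
  stopifnot(inherits(model, "fbtrca_model"))
  if (ncol(segment) != model$n_samples)
    stop("segment length ", ncol(segment),
         " does not match the trained model (", model$n_samples,
         " samples); train and test must use the same data length",
         call. = FALSE)
  config <- model$config
  subbands <- fb_decompose(segment, config, model$sampling_rate)
  K <- model$models[[1]]$n_classes
  feats <- matrix(0, config$n_subbands, K)
  for (n in seq_len(config$n_subbands))
    for (k in seq_len(K))
      feats[n, k] <- trca_feature(subbands[[n]], model$models[[n]], k,
                                  ensemble = ensemble)
  w <- fb_weights(config$a, config$b, config$n_subbands)
  scores <- as.numeric(crossprod(sign(feats) * feats^2, w))
  list(predicted = which.max(scores), scores = scores, features = feats)
}

# --- cross-validation -------------------------------------------------------

#' Block-wise leave-one-out decoding evaluation
#'
#' For supervised methods (FBTRCA), each of the B blocks is held out in turn:
#' models are trained on the remaining B-1 blocks and tested on the held-out
#' block's trials. Unsupervised methods (CCA, FBCCA) need no calibration and
#' are simply scored per block.
#'
#' @param epochs An [ssvep_epochs()] object with `block` and `target_index`
#'   metadata covering the full 2.84 s window.
#' @param layout A [speller_layout()].
#' @param method `"fbcca"`, `"fbtrca"`, or `"cca"`.
#' @param config A [filter_bank_config()] (ignored for `"cca"`).
#' @param data_length Decoded segment length in seconds (default 1).
#' @param latency Visual latency in seconds (default 0.14).
#' @param n_harmonics Reference harmonics Nh for CCA/FBCCA (default 5).
#' @param ensemble FBTRCA ensemble variant (default TRUE).
#' @return Object of class `decoding_result`: tibbles `per_block`
#'   (block, n_trials, accuracy) and `predictions` (block, trial, true,
#'   predicted, margin), plus the mean `accuracy` and metadata.
#' @export
loo_block_cv <- function(epochs, layout, method = c("fbcca", "fbtrca", "cca"),
                         config = filter_bank_config(), data_length = 1,
                         latency = 0.14, n_harmonics = 5, ensemble = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "ssvep_epochs"))
  if (!all(c("block", "target_index") %in% names(epochs$info)))
    stop("epochs must carry `block` and `target_index` metadata", call. = FALSE)
  blocks <- sort(unique(epochs$info$block))
  if (method == "fbtrca" && length(blocks) < 2)
    stop("leave-one-block-out TRCA needs >= 2 blocks", call. = FALSE)
  seg <- classification_segment(epochs, data_length, latency)
  rate <- seg$sampling_rate
  n_samples <- dim(seg$data)[2]
  refs <- make_references(layout, n_harmonics, rate, n_samples)
  preds <- epochs$info
  preds$predicted <- NA_integer_
  preds$margin <- NA_real_

  if (method %in% c("cca", "fbcca")) {
    for (i in seq_len(nrow(preds))) {
      res <- if (method == "cca")
        cca_classify(seg$data[, , i], refs)
      else fbcca_classify(seg$data[, , i], refs, config, rate)
      preds$predicted[i] <- res$predicted
      s <- sort(res$scores, decreasing = TRUE)
      preds$margin[i] <- s[1] - s[2]
    }
  } else {
    for (b in blocks) {
      train_idx <- which(preds$block != b)
      test_idx <- which(preds$block == b)
      model <- fbtrca_train(seg$data[, , train_idx, drop = FALSE],
                            preds$target_index[train_idx], config, rate)
      for (i in test_idx) {
        res <- fbtrca_classify(seg$data[, , i], model, ensemble = ensemble)
        preds$predicted[i] <- res$predicted
        s <- sort(res$scores, decreasing = TRUE)
        preds$margin[i] <- s[1] - s[2]
      }
    }
  }
  per_block <- preds |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     accuracy = mean(.data$predicted == .data$target_index),
                     .groups = "drop")
  structure(list(per_block = per_block,
                 predictions = preds,
                 accuracy = mean(preds$predicted == preds$target_index),
                 method = method, data_length = data_length,
                 config = if (method == "cca") NULL else config),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result>", toupper(x$method), "| data length", x$data_length,
      "s | accuracy", sprintf("%.3f", x$accuracy), "over",
      nrow(x$predictions), "trials in", nrow(x$per_block), "blocks\n")
  invisible(x)
}
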