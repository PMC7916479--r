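# Cross-electrode transfer (ET): templates recorded with one electrode type
# (train-electrode) are projected to 1-D per class, and a test trial from the
# other electrode type is matched to each candidate template by a per-trial
# least-squares spatial filter — no calibration with the test electrode. The
# template-match correlation r1 is fused with the standard CCA reference
# correlation r2 as p = sign(r1)*r1^2 + sign(r2)*r2^2.

#' Build an electrode-transfer model from train-electrode data
#'
#' Per class and sub-band, the class-mean epoch of the train-electrode is
#' projected to a 1-D template by one of three spatial filters:
#' `"avg"` (unweighted channel mean), `"cca"` (spatial weights from CCA
#' between the class mean and the class's sinusoidal reference), or
#' `"trca"` (the class's TRCA filter trained on the train-electrode trials).
#' Templates are mean-removed.
#'
#' @param segments Channels x samples x trials array of train-electrode
#'   classification segments.
#' @param targets Integer class label per trial.
#' @param projection One of `"avg"`, `"cca"`, `"trca"`.
#' @param config A [filter_bank_config()].
#' @param layout A [speller_layout()] (needed for the CCA projection).
#' @param sampling_rate Hz.
#' @param n_harmonics Reference harmonics for the CCA projection (default 5).
#' @return Object of class `et_model`: `templates` is a list over sub-bands
#'   of samples x classes matrices.
#' @export
build_et_model <- function(segments, targets,
                           projection = c("avg", "cca", "trca"),
                           config = filter_bank_config(),
                           layout = speller_layout(),
                           sampling_rate = 250, n_harmonics = 5) {
  projection <- match.arg(projection)
  d <- dim(segments)
  stopifnot(length(d) == 3, length(targets) == d[3])
  K <- max(targets)
  min_per_class <- min(table(factor(targets, levels = seq_len(K))))
  if (min_per_class < 1)
    stop("need >= 1 training epoch per class", call. = FALSE)
  if (projection == "trca" && min_per_class < 2)
    stop("the TRCA projection needs >= 2 training epochs per class",
         call. = FALSE)
  subbands <- fb_decompose_trials(segments, config, sampling_rate)
  refs <- if (projection == "cca")
    make_references(layout, n_harmonics, sampling_rate, d[2]) else NULL
  templates <- lapply(seq_len(config$n_subbands), function(n) {
    sb <- subbands[[n]]
    tm <- matrix(0, d[2], K)
    for (k in seq_len(K)) {
      idx <- which(targets == k)
      class_mean <- apply(sb[, , idx, drop = FALSE], c(1, 2), mean)
      w <- switch(projection,
        avg = rep(1 / d[1], d[1]),
        cca = cca_first_correlation(class_mean, refs$references[[k]],
                                    weights = TRUE)$wx,
        trca = trca_filter(sb[, , idx, drop = FALSE]))
      proj <- as.vector(crossprod(w, class_mean))
      if (stats::sd(proj) < 1e-12)
        stop("degenerate (constant) projected template for class ", k,
             call. = FALSE)
      tm[, k] <- proj - mean(proj)
    }
    tm
  })
  structure(list(templates = templates, projection = projection,
                 config = config, sampling_rate = sampling_rate,
                 n_samples = d[2], n_classes = K,
                 n_harmonics = n_harmonics),
            class = "et_model")
}

#' @export
print.et_model <- function(x, ...) {
  cat("<et_model> projection:", toupper(x$projection), "|", x$n_classes,
      "classes x", x$config$n_subbands, "sub-bands,", x$n_samples,
      "samples\n")
  invisible(x)
}

# Least-squares spatial filter matching v' X to template tau; both
# mean-removed, no intercept.
ls_spatial_filter <- function(X, tau, ridge = 1e-8) {
  Xc <- X - rowMeans(X)
  G <- ridge_stabilise(tcrossprod(Xc), ridge)
  solve(G, Xc %*% tau)
}

#' Classify a test-electrode segment by electrode transfer
#'
#' For each candidate class k and sub-band n: a least-squares spatial filter
#' v minimizing ||v'X - tau_k||^2 is fitted on the test trial itself (X the
#' band-passed test segment, tau_k the projected train-electrode template);
#' r1 = cor(v'X, tau_k), r2 = first canonical correlation of X with the
#' class's sinusoidal reference, fused as p = sign(r1)*r1^2 + sign(r2)*r2^2.
#' Class scores are sum_n w(n) * p_{n,k} (or w(n) * sign(p)*p^2 with
#' `squared_fusion = TRUE`); the argmax wins, ties to the lowest index.
#'
#' @param segment Channels x samples test matrix (same rate and length as
#'   the model templates).
#' @param model A [build_et_model()].
#' @param references A [make_references()] set matching the segment length.
#' @param squared_fusion Square the fused p across sub-bands (default FALSE).
#' @return List with `predicted`, `scores`, and `features`: a tibble of
#'   (subband, class, r1, r2, p).
#' @export
et_classify <- function(segment, model, references, squared_fusion = FALSE) {
  stopifnot(inherits(model, "et_model"))
  if (ncol(segment) != model$n_samples)
    stop("segment length ", ncol(segment), " does not match the model (",
         model$n_samples, " samples)", call. = FALSE)
  config <- model$config
  subbands <- fb_decompose(segment, config, model$sampling_rate)
  K <- model$n_classes
  N <- config$n_subbands
  r1 <- matrix(0, N, K); r2 <- matrix(0, N, K)
  for (n in seq_len(N)) {
    X <- subbands[[n]]
    for (k in seq_len(K)) {
      tau <- model$templates[[n]][, k]
      v <- ls_spatial_filter(X, tau)
      proj <- as.vector(crossprod(v, X - rowMeans(X)))
      r1[n, k] <- if (stats::sd(proj) < 1e-12) 0 else stats::cor(proj, tau)
      r2[n, k] <- cca_first_correlation(X, references$references[[k]])
    }
  }
  p <- sign(r1) * r1^2 + sign(r2) * r2^2
  w <- fb_weights(config$a, config$b, N)
  fused <- if (squared_fusion) sign(p) * p^2 else p
  scores <- as.numeric(crossprod(fused, w))
  features <- tibble::tibble(
    subband = rep(seq_len(N), times = K),
    class = rep(seq_len(K), each = N),
    r1 = as.vector(r1), r2 = as.vector(r2), p = as.vector(p))
  list(predicted = which.max(scores), scores = scores, features = features)
}

#' Evaluate electrode transfer on a full test-electrode session
#'
#' Builds the ET model from the train-electrode epochs and classifies every
#' test-electrode trial (no test-electrode calibration).
#'
#' @param train_epochs,test_epochs [ssvep_epochs()] objects with
#'   `target_index` (and `block`) metadata, full 2.84 s windows, same rate.
#' @param layout A [speller_layout()].
#' @param projection `"avg"`, `"cca"`, or `"trca"`.
#' @param config A [filter_bank_config()].
#' @param data_length Decoded segment length in seconds (default 1).
#' @param latency Visual latency (default 0.14 s).
#' @param n_harmonics Reference harmonics (default 5).
#' @param squared_fusion See [et_classify()].
#' @return A `decoding_result` (as from [loo_block_cv()]) with method
#'   `"et-<projection>"`.
#' @export
et_evaluate <- function(train_epochs, test_epochs, layout,
                        projection = c("avg", "cca", "trca"),
                        config = filter_bank_config(), data_length = 1,
                        latency = 0.14, n_harmonics = 5,
                        squared_fusion = FALSE) {
  projection <- match.arg(projection)
  stopifnot(inherits(train_epochs, "ssvep_epochs"),
            inherits(test_epochs, "ssvep_epochs"))
  if (train_epochs$sampling_rate != test_epochs$sampling_rate)
    stop("train and test epochs must share a sampling rate", call. = FALSE)
  tr_seg <- classification_segment(train_epochs, data_length, latency)
  te_seg <- classification_segment(test_epochs, data_length, latency)
  rate <- tr_seg$sampling_rate
  model <- build_et_model(tr_seg$data, tr_seg$info$target_index, projection,
                          config, layout, rate, n_harmonics)
  refs <- make_references(layout, n_harmonics, rate, dim(te_seg$data)[2])
  preds <- te_seg$info
  preds$predicted <- NA_integer_
  preds$margin <- NA_real_
  for (i in seq_len(nrow(preds))) {
    res <- et_classify(te_seg$data[, , i], model, refs, squared_fusion)
    preds$predicted[i] <- res$predicted
    s <- sort(res$scores, decreasing = TRUE)
    preds$margin[i] <- s[1] - s[2]
  }
  per_block <- if ("block" %in% names(preds)) {
    preds |>
      dplyr::group_by(.data$block) |>
      dplyr::summarise(n_trials = dplyr::n(),
                       accuracy = mean(.data$predicted == .data$target_index),
                       .groups = "drop")
  } else {
    tibble::tibble(block = 1L, n_trials = nrow(preds),
                   accuracy = mean(preds$predicted == preds$target_index))
  }
  structure(list(per_block = per_block, predictions = preds,
                 accuracy = mean(preds$predicted == preds$target_index),
                 method = paste0("et-", projection),
                 data_length = data_length, config = config),
            class = "decoding_result")
}
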