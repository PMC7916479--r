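# Canonical correlation against sinusoidal references: the unsupervised core
# of SSVEP frequency detection. The first canonical correlation between the
# multichannel segment and a bank of sin/cos harmonics of each candidate
# frequency scores how strongly that frequency is present.

#' Sinusoidal reference set
#'
#' For each target, a 2*Nh x n_samples matrix of sine/cosine pairs at
#' harmonics 1..Nh of the target frequency (phase 0; the cosine row absorbs
#' any phase offset in the data). Rows alternate sin, cos per harmonic.
#'
#' @param layout A [speller_layout()].
#' @param n_harmonics Nh, number of harmonics (default 5).
#' @param sampling_rate Hz.
#' @param n_samples Samples per reference.
#' @return Object of class `reference_set`: list of per-target matrices plus
#'   metadata.
#' @export
make_references <- function(layout, n_harmonics = 5, sampling_rate = 250,
                            n_samples) {
  stopifnot(inherits(layout, "speller_layout"))
  if (n_harmonics < 1) stop("`n_harmonics` must be >= 1", call. = FALSE)
  fmax <- max(layout$stimuli$frequency)
  if (n_harmonics * fmax >= sampling_rate / 2)
    stop("harmonic ", n_harmonics, " of ", fmax,
         " Hz is at or above the Nyquist frequency", call. = FALSE)
  t <- (seq_len(n_samples) - 1) / sampling_rate
  refs <- lapply(seq_len(nrow(layout$stimuli)), function(k) {
    f <- layout$stimuli$frequency[k]
    rows <- lapply(seq_len(n_harmonics), function(h)
      rbind(sin(2 * pi * h * f * t), cos(2 * pi * h * f * t)))
    do.call(rbind, rows)
  })
  structure(list(references = refs, n_harmonics = n_harmonics,
                 sampling_rate = sampling_rate, n_samples = n_samples,
                 frequencies = layout$stimuli$frequency),
            class = "reference_set")
}

# Row-centered covariance pieces with trace-scaled ridge stabilisation.
ridge_stabilise <- function(C, eps = 1e-8) {
  C + diag(eps * mean(diag(C)) + 1e-300, nrow(C))
}

#' First canonical correlation between two multichannel signals
#'
#' Solves the CCA generalized eigenproblem through explicit covariance
#' matrices with a small trace-scaled ridge, and returns the first canonical
#' correlation. Invariant under invertible linear recombination of either
#' signal's rows.
#'
#' @param x,y Numeric matrices (rows = variates, columns = samples) with the
#'   same number of columns.
#' @param ridge Ridge fraction applied to the auto-covariances
#'   (default 1e-8).
#' @param weights If TRUE, also return the spatial weight vector on `x`.
#' @return The first canonical correlation in \[0, 1\]; with
#'   `weights = TRUE`, a list `list(rho, wx)`.
#' @export
cca_first_correlation <- function(x, y, ridge = 1e-8, weights = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  if (ncol(x) != ncol(y))
    stop("`x` and `y` must have the same number of samples", call. = FALSE)
  if (ncol(x) <= nrow(x) + nrow(y))
    warning("sample count not greater than total variates; CCA is ill-posed")
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  n <- ncol(x)
  cxx <- ridge_stabilise(tcrossprod(xc) / n, ridge)
  cyy <- ridge_stabilise(tcrossprod(yc) / n, ridge)
  cxy <- tcrossprod(xc, yc) / n
  m <- solve(cxx, cxy) %*% solve(cyy, t(cxy))
  ev <- eigen(m, only.values = !weights)
  rho2 <- max(0, min(1, Re(ev$values[1])))
  rho <- sqrt(rho2)
  if (!weights) return(rho)
  wx <- Re(ev$vectors[, 1])
  # sign convention: largest-magnitude entry positive
  wx <- wx * sign(wx[which.max(abs(wx))])
  list(rho = rho, wx = wx)
}
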