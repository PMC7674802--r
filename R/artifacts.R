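#' ICA-based artifact-component removal
#'
#' Decomposes the EEG channels (EOG excluded) with a symmetric FastICA
#' (tanh contrast), flags artifactual components by two documented
#' heuristics, zeroes them, and reconstructs the record:
#'
#' 1. **EOG correlation**: a component whose absolute Pearson correlation
#'    with any EOG channel exceeds `eog_cor_threshold` (default 0.7) is
#'    treated as ocular.
#' 2. **Low-frequency dominance**: a component whose spectral power below
#'    `lowfreq_hz` (default 3 Hz) exceeds `lowfreq_frac` (default 0.8) of
#'    its total power is treated as drift/movement artifact. The threshold
#'    is conservative because 1/f-distributed neural background keeps well
#'    under it.
#'
#' The interface accepts a custom `flag_fun(sources, eog_data)` returning a
#' logical vector, so a trained component classifier can be dropped in.
#'
#' @param eeg an `eeg_record` containing both EEG and EOG channels.
#' @param eog_cor_threshold,lowfreq_hz,lowfreq_frac heuristic thresholds.
#' @param n_comp number of components (default: number of EEG channels).
#' @param flag_fun optional replacement for the built-in heuristics.
#' @param max_iter,tol FastICA iteration controls.
#' @return list with `eeg` (reconstructed record; EOG channels untouched)
#'   and `report` (data.frame per component: eog_cor, lowfreq_frac,
#'   rejected).
#' @export
remove_artifacts <- function(eeg, eog_cor_threshold = 0.7, lowfreq_hz = 3,
                             lowfreq_frac = 0.8, n_comp = NULL,
                             flag_fun = NULL, max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(eeg, "eeg_record"))
  eeg_idx <- eeg_channel_idx(eeg$channels)
  eog_idx <- eog_channel_idx(eeg$channels)
  if (length(eog_idx) < 1) {
    stop("remove_artifacts needs at least one EOG channel", call. = FALSE)
  }
  X <- eeg$data[eeg_idx, , drop = FALSE]
  mu <- rowMeans(X)
  Xc <- X - mu
  if (is.null(n_comp)) n_comp <- nrow(Xc)

  ica <- fastica_symmetric(Xc, n_comp, max_iter = max_iter, tol = tol)
  S <- ica$S                                  # components x samples

  eog_data <- eeg$data[eog_idx, , drop = FALSE]
  eog_cor <- apply(S, 1, function(s) max(abs(stats::cor(s, t(eog_data)))))
  lf <- apply(S, 1, function(s) lowfreq_fraction(s, eeg$fs, lowfreq_hz))
  rejected <- if (is.null(flag_fun)) {
    eog_cor > eog_cor_threshold | lf > lowfreq_frac
  } else {
    as.logical(flag_fun(S, eog_data))
  }

  A <- ica$A                                  # mixing: channels x comps
  keep <- !rejected
  recon <- A[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + mu
  out <- eeg
  out$data[eeg_idx, ] <- recon
  list(eeg = out,
       report = data.frame(component = seq_len(n_comp), eog_cor = eog_cor,
                           lowfreq_frac = lf, rejected = rejected))
}

lowfreq_fraction <- function(x, fs, cutoff) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  half <- seq_len(floor(n / 2))
  f <- (half - 1) * fs / n
  sum(p[half][f < cutoff]) / sum(p[half])
}

# Symmetric FastICA with tanh contrast on pre-centered data.
# Returns sources S (comps x samples) and mixing matrix A (channels x comps)
# with X ~= A %*% S.
fastica_symmetric <- function(Xc, n_comp, max_iter = 200, tol = 1e-6) {
  n <- ncol(Xc)
  cv <- tcrossprod(Xc) / n
  eig <- eigen(cv, symmetric = TRUE)
  d <- eig$values[seq_len(n_comp)]
  if (any(d <= .Machine$double.eps * max(d))) {
    stop("ICA decomposition failure: rank-deficient covariance", call. = FALSE)
  }
  E <- eig$vectors[, seq_len(n_comp), drop = FALSE]
  K <- diag(1 / sqrt(d), n_comp) %*% t(E)     # whitening
  Z <- K %*% Xc

  set_ortho <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- set_ortho(matrix(stats::rnorm(n_comp^2), n_comp))
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- set_ortho(G %*% t(Z) / n - diag(rowMeans(Gp)) %*% W)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  # S = (W K) Xc with W orthonormal, so the mixing matrix inverts exactly:
  A <- E %*% diag(sqrt(d), n_comp) %*% t(W)
  list(S = S, A = A, W = W %*% K)
}
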