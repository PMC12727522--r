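#' Extract high-frequency activity (HFA) from broadband recordings
#'
#' The high-gamma analytic amplitude is computed per electrode with a bank
#' of eight Gaussian band-pass filters with log-spaced centre frequencies
#' spanning 70--150 Hz (bandwidth sigma = cf/6, constant-Q-like growth).
#' Filtering and the Hilbert transform are performed jointly in the
#' frequency domain: the FFT of the signal is multiplied by the Gaussian
#' filter response on non-negative frequencies (doubled on strictly
#' positive bins, zeroed on negative bins) and the magnitude of the inverse
#' transform is the band's analytic amplitude. The eight band amplitudes
#' are reduced per electrode to their first principal component (sign fixed
#' to correlate positively with the mean band amplitude), downsampled to
#' 100 Hz by block averaging, and z-scored per recording block.
#'
#' @param raw `electrodes x samples` matrix (or a vector for one
#'   electrode) of broadband signal.
#' @param fs sampling rate of `raw` in Hz; must be >= 400 and a multiple
#'   of `fs_out`.
#' @param fs_out output frame rate (default 100 Hz).
#' @param band `c(low, high)` Hz of the high-gamma range.
#' @param n_filters number of Gaussian filters (default 8).
#' @param blocks optional integer vector (length = output frames) of
#'   recording-block ids; z-scoring is computed within block. Default: one
#'   block.
#' @return object of class `neural_recording` with `hfa`
#'   (`electrodes x frames`, z-scored per block), `fs = fs_out`, and the
#'   band amplitudes' PCA loadings in `pca_loadings`.
#' @export
extract_hfa <- function(raw, fs, fs_out = 100, band = c(70, 150),
                        n_filters = 8, blocks = NULL) {
  if (is.vector(raw)) raw <- matrix(raw, nrow = 1)
  if (!all(is.finite(raw))) stop("raw signal must be finite")
  if (fs < 400) stop("fs must be >= 400 Hz")
  r <- fs / fs_out
  if (abs(r - round(r)) > 1e-9) stop("fs must be a multiple of fs_out")
  r <- as.integer(round(r))
  n <- ncol(raw)
  if (n < fs) stop("signal shorter than filter support (need >= 1 s)")

  cfs <- exp(seq(log(band[1]), log(band[2]), length.out = n_filters))
  sds <- cfs / 6
  # frequency of each FFT bin; analytic-signal weights
  freq <- (seq_len(n) - 1) / n * fs
  pos <- freq <= fs / 2
  h <- numeric(n)
  h[pos] <- 2
  h[1] <- 1
  if (n %% 2 == 0) h[n / 2 + 1] <- 1

  n_out <- floor(n / r)
  out <- matrix(0, nrow(raw), n_out)
  loadings <- matrix(0, n_filters, nrow(raw))
  for (e in seq_len(nrow(raw))) {
    xf <- stats::fft(raw[e, ])
    amps <- matrix(0, n, n_filters)
    for (k in seq_len(n_filters)) {
      g <- numeric(n)
      g[pos] <- exp(-(freq[pos] - cfs[k])^2 / (2 * sds[k]^2))
      amps[, k] <- Mod(stats::fft(xf * g * h, inverse = TRUE) / n)
    }
    ac <- scale(amps, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(ac), symmetric = TRUE)
    v1 <- ev$vectors[, 1]
    sc <- ac %*% v1
    if (stats::cor(sc, rowMeans(amps)) < 0) { v1 <- -v1; sc <- -sc }
    loadings[, e] <- v1
    # block-average anti-alias + decimate to fs_out
    out[e, ] <- colMeans(matrix(sc[seq_len(n_out * r)], r, n_out))
  }

  if (is.null(blocks)) blocks <- rep(1L, n_out)
  if (length(blocks) != n_out) stop("blocks must have one id per output frame")
  for (b in unique(blocks)) {
    j <- blocks == b
    m <- rowMeans(out[, j, drop = FALSE])
    s <- apply(out[, j, drop = FALSE], 1, stats::sd)
    s[s < 1e-12] <- 1
    out[, j] <- (out[, j, drop = FALSE] - m) / s
  }
  structure(list(hfa = out, fs = fs_out, blocks = blocks,
                 pca_loadings = loadings,
                 electrodes = data.frame(electrode = seq_len(nrow(out)),
                                         participant = "P1",
                                         hemisphere = "left", region = "STG")),
            class = "neural_recording")
}

#' Normalize each sentence response to its silent prestimulus baseline
#'
#' For every trial and electrode, subtracts the mean and divides by the
#' standard deviation of the 0.5 s silent baseline window preceding
#' sentence onset, over the trial's frames.
#'
#' @param recording a `neural_recording`.
#' @param alignment data.frame with columns `trial, start, baseline_start,
#'   onset, offset, end` (frames); defaults to `recording$alignment`.
#' @return the recording with baseline-normalized `hfa`.
#' @export
baseline_normalize <- function(recording, alignment = recording$alignment) {
  stopifnot(inherits(recording, "neural_recording"))
  if (is.null(alignment)) stop("no alignment table available")
  hfa <- recording$hfa
  for (i in seq_len(nrow(alignment))) {
    a <- alignment[i, ]
    if (a$onset - a$baseline_start < 0.5 * recording$fs)
      stop("trial ", a$trial, ": baseline window shorter than 0.5 s")
    bl <- hfa[, a$baseline_start:(a$onset - 1L), drop = FALSE]
    m <- rowMeans(bl)
    s <- apply(bl, 1, stats::sd)
    if (any(s < 1e-12))
      stop("trial ", a$trial, ": degenerate (zero-variance) baseline")
    idx <- a$start:a$end
    hfa[, idx] <- (hfa[, idx, drop = FALSE] - m) / s
  }
  recording$hfa <- hfa
  recording
}

# vectorized two-group one-way ANOVA F statistics (equal to t^2):
# X is trials x k (per-timepoint speech values), b is trials' baseline values
two_group_f <- function(X, b) {
  n1 <- nrow(X); n2 <- length(b)
  m1 <- colMeans(X); v1 <- apply(X, 2, stats::var)
  m2 <- mean(b); v2 <- stats::var(b)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  sp[sp < 1e-24] <- 1e-24
  f <- (m1 - m2)^2 / (sp * (1 / n1 + 1 / n2))
  list(f = f, df1 = 1, df2 = n1 + n2 - 2,
       p = stats::pf(f, 1, n1 + n2 - 2, lower.tail = FALSE))
}

longest_run <- function(x) {
  r <- rle(x)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else max(runs)
}

#' Select speech-responsive electrodes
#'
#' An electrode is speech-responsive when its stimulus-aligned HFA differs
#' from the silent-baseline level for at least 0.1 s (10 contiguous frames)
#' of Bonferroni-corrected significant timepoints, in either the
#' onset-aligned first 0.5 s or the offset-aligned last 0.5 s of the spoken
#' sentences. Each tested timepoint compares, across sentences, the HFA at
#' that timepoint against the per-sentence mean baseline HFA with a
#' two-group one-way ANOVA F-test; the Bonferroni factor is the number of
#' tested timepoints pooled over both windows.
#'
#' @param recording a `neural_recording`.
#' @param alignment alignment table (default `recording$alignment`); trials
#'   that repeat sentences are all used.
#' @param alpha significance threshold after Bonferroni (default 0.01).
#' @param window_s aligned window length in seconds (default 0.5).
#' @param run_s required contiguous significant duration (default 0.1 s).
#' @return object of class `responsiveness_result`: data.frame `electrodes`
#'   (`electrode, responsive, longest_run_onset_s, longest_run_offset_s`)
#'   plus matrices `f_onset, f_offset, p_onset, p_offset`
#'   (`electrodes x timepoints`) and the Bonferroni factor `n_tests`.
#' @export
select_speech_responsive <- function(recording, alignment = recording$alignment,
                                     alpha = 0.01, window_s = 0.5,
                                     run_s = 0.1) {
  stopifnot(inherits(recording, "neural_recording"))
  if (is.null(alignment) || nrow(alignment) < 2)
    stop("need at least 2 sentences to assess responsiveness")
  fs <- recording$fs
  w <- as.integer(round(window_s * fs))
  need <- as.integer(round(run_s * fs))
  hfa <- recording$hfa
  n_e <- nrow(hfa)
  n_tr <- nrow(alignment)

  bl <- matrix(0, n_tr, n_e)     # per-sentence mean baseline HFA
  on_arr <- array(0, c(n_tr, w, n_e))
  off_arr <- array(0, c(n_tr, w, n_e))
  for (i in seq_len(n_tr)) {
    a <- alignment[i, ]
    bl[i, ] <- rowMeans(hfa[, a$baseline_start:(a$onset - 1L), drop = FALSE])
    on_idx <- a$onset:(a$onset + w - 1L)
    off_idx <- (a$offset - w + 1L):a$offset
    if (max(on_idx) > a$end || min(off_idx) < a$onset)
      stop("trial ", a$trial, ": sentence shorter than the aligned window")
    on_arr[i, , ] <- t(hfa[, on_idx, drop = FALSE])
    off_arr[i, , ] <- t(hfa[, off_idx, drop = FALSE])
  }

  n_tests <- 2L * w
  f_on <- p_on <- f_off <- p_off <- matrix(0, n_e, w)
  for (e in seq_len(n_e)) {
    r1 <- two_group_f(on_arr[, , e, drop = TRUE], bl[, e])
    r2 <- two_group_f(off_arr[, , e, drop = TRUE], bl[, e])
    f_on[e, ] <- r1$f; p_on[e, ] <- r1$p
    f_off[e, ] <- r2$f; p_off[e, ] <- r2$p
  }
  sig_on <- p_on * n_tests < alpha
  sig_off <- p_off * n_tests < alpha
  run_on <- apply(sig_on, 1, longest_run)
  run_off <- apply(sig_off, 1, longest_run)
  electrodes <- data.frame(
    electrode = seq_len(n_e),
    responsive = run_on >= need | run_off >= need,
    longest_run_onset_s = run_on / fs,
    longest_run_offset_s = run_off / fs)
  structure(list(electrodes = electrodes, f_onset = f_on, f_offset = f_off,
                 p_onset = p_on, p_offset = p_off, n_tests = n_tests,
                 alpha = alpha),
            class = "responsiveness_result")
}

#' @export
print.responsiveness_result <- function(x, ...) {
  cat("<responsiveness_result> ", sum(x$electrodes$responsive), "/",
      nrow(x$electrodes), " electrodes speech-responsive (Bonferroni x",
      x$n_tests, ", alpha ", x$alpha, ")\n", sep = "")
  invisible(x)
}
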