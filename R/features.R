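#' Analysis-window specification
#'
#' @param n_window Window length in samples.
#' @param n_increment Window increment in samples.
#' @return A `window_spec` list.
#' @export
window_spec <- function(n_window, n_increment) {
  if (!(n_increment >= 1 && n_window >= n_increment)) {
    abort("need n_window >= n_increment >= 1")
  }
  structure(list(n_window = as.integer(n_window),
                 n_increment = as.integer(n_increment)),
            class = "window_spec")
}

config_window_spec <- function(config, fs) {
  window_spec(round(config$window_ms * fs / 1000),
              round(config$increment_ms * fs / 1000))
}

#' Slide analysis windows over the annotated contractions of a recording
#'
#' Each non-rest annotation segment of length `L` samples yields
#' `floor((L - n_window)/n_increment) + 1` windows (none if `L < n_window`),
#' labelled with the segment's motion class and cycle. Windows never
#' straddle a segment boundary, so transitional contraction/rest windows are
#' discarded rather than mislabelled.
#'
#' @param record An [emg_record()].
#' @param spec A [window_spec()] (samples), or `NULL` to derive one from
#'   `config` and the recording's sampling rate.
#' @param config An [emg_config()] used when `spec` is `NULL`.
#' @return A tibble with one row per window: `window_index`, `start_sample`
#'   (1-based index of the first sample), `start_s`, `label`, `cycle`,
#'   ordered by start time.
#' @export
segment_windows <- function(record, spec = NULL, config = emg_config()) {
  stopifnot(inherits(record, "emg_record"))
  if (is.null(spec)) spec <- config_window_spec(config, record$fs)
  act <- record$segments[record$segments$label != REST_LABEL, , drop = FALSE]
  rows <- lapply(seq_len(nrow(act)), function(i) {
    seg <- act[i, ]
    first0 <- ceiling(seg$onset_s * record$fs - 1e-9)
    last0 <- ceiling(seg$offset_s * record$fs - 1e-9) - 1
    L <- last0 - first0 + 1
    if (L < spec$n_window) return(NULL)
    k <- (L - spec$n_window) %/% spec$n_increment + 1
    start0 <- first0 + (seq_len(k) - 1L) * spec$n_increment
    tibble(start_sample = as.integer(start0 + 1L),
           start_s = start0 / record$fs,
           label = seg$label, cycle = seg$cycle)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(start_sample = integer(), start_s = numeric(),
                  label = character(), cycle = integer())
  }
  out <- out[order(out$start_sample), , drop = FALSE]
  dplyr::bind_cols(tibble(window_index = seq_len(nrow(out))), out)
}

#' Root-mean-square amplitude of a window
#'
#' @param x Numeric vector (one channel of one analysis window).
#' @return `sqrt(mean(x^2))`, the standard EMG amplitude descriptor.
#' @export
rms_value <- function(x) sqrt(mean(x^2))

# Burg lattice recursion, vectorised across windows. X is n_samples x
# n_windows; returns order x n_windows coefficients a_k in the error-filter
# convention x[n] + sum_k a_k x[n-k] = e[n]. Columns are demeaned first;
# a zero-variance column falls back to all-zero coefficients. The reflection
# coefficients are bounded by 1 in magnitude (Cauchy-Schwarz), so the
# estimated model is always stable.
burg_matrix <- function(X, order) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N <= order) abort("window length must exceed the AR order")
  X <- sweep(X, 2, colMeans(X))
  W <- ncol(X)
  A <- matrix(0, order, W)
  f <- X
  b <- X
  for (m in seq_len(order)) {
    fm <- f[(m + 1):N, , drop = FALSE]
    bm <- b[m:(N - 1), , drop = FALSE]
    den <- colSums(fm * fm) + colSums(bm * bm)
    num <- colSums(fm * bm)
    k <- ifelse(den > 0, -2 * num / den, 0)
    if (m > 1) {
      A[1:(m - 1), ] <- A[1:(m - 1), , drop = FALSE] +
        A[(m - 1):1, , drop = FALSE] * rep(k, each = m - 1)
    }
    A[m, ] <- k
    kk <- rep(k, each = N - m)
    f[(m + 1):N, ] <- fm + bm * kk
    b[(m + 1):N, ] <- bm + fm * kk
  }
  A
}

#' Burg autoregressive coefficients of a window
#'
#' Estimates an order-`order` all-pole model by the Burg lattice method.
#' Coefficients are returned in the error-filter convention
#' `x[n] + a_1 x[n-1] + ... + a_p x[n-p] = e[n]`, i.e. for a process
#' `x[n] = 0.9 x[n-1] + e[n]` the first coefficient is near `-0.9`. The
#' window is demeaned before estimation; a constant (zero-variance) window
#' yields all-zero coefficients.
#'
#' @param x Numeric vector, length greater than `order`.
#' @param order Model order (the pipeline default is 6).
#' @return Numeric vector of length `order`.
#' @export
ar_coefficients <- function(x, order) {
  if (any(!is.finite(x))) abort("AR input must be finite")
  as.numeric(burg_matrix(matrix(as.numeric(x), ncol = 1), order))
}

# DCT-II basis applied to the log-magnitude spectrum, vectorised across
# windows. X is n_samples x n_windows.
fc_matrix <- function(X, n_fc, epsilon) {
  X <- as.matrix(X)
  N <- nrow(X)
  Y <- log(Mod(stats::mvfft(X)) + epsilon)
  k <- seq_len(N) - 1
  B <- cos(outer(k + 0.5, seq_len(n_fc) - 1) * pi / N)
  crossprod(B, Y)
}

#' Fourier-derived cepstral (FC) coefficients of a window
#'
#' Two steps: (1) the N-point DFT of the window; (2) a DCT of the
#' log-magnitude spectrum,
#' `FC_i = sum_{k=0}^{N-1} Y_k cos((k + 1/2)(i - 1) pi / N)`, with
#' `Y_k = log(|X[k]| + epsilon)`. The sum runs over the full N-bin spectrum
#' (conjugate-symmetric for real signals); `i = 1` is the DC-like term. The
#' additive `epsilon` keeps empty spectral bins finite.
#'
#' @param x Numeric vector (one channel of one analysis window).
#' @param n_fc Number of coefficients to keep (`n_fc <= length(x)`).
#' @param epsilon Additive guard inside the logarithm (default 1e-12).
#' @return Numeric vector of length `n_fc`.
#' @export
fc_coefficients <- function(x, n_fc, epsilon = 1e-12) {
  if (n_fc > length(x)) abort("`n_fc` must not exceed the window length")
  if (any(!is.finite(x))) abort("FC input must be finite")
  as.numeric(fc_matrix(matrix(as.numeric(x), ncol = 1), n_fc, epsilon))
}

#' Extract per-window features from an annotated recording
#'
#' Computes, for every analysis window of every annotated contraction, one
#' feature vector: either the Burg AR coefficients plus RMS per channel
#' (`kind = "ar"`, dimension `n_channels * (ar_order + 1)`) or the first
#' `n_fc` Fourier-derived cepstral coefficients per channel
#' (`kind = "fc"`, dimension `n_channels * n_fc`). Per-channel blocks are
#' concatenated in channel order.
#'
#' @param record An [emg_record()].
#' @param kind `"ar"` or `"fc"`.
#' @param config An [emg_config()] supplying window/increment lengths, AR
#'   order, FC count and epsilon.
#' @param windows Optional precomputed window table from
#'   [segment_windows()]; recomputed when `NULL`.
#' @return A feature tibble (class `emg_features`): columns `cycle`,
#'   `window_index`, `start_s`, `label`, then one column per feature,
#'   named `ch<i>_ar<k>` / `ch<i>_rms` or `ch<i>_fc<k>`.
#' @export
extract_features <- function(record, kind = c("ar", "fc"),
                             config = emg_config(), windows = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(record, "emg_record"))
  spec <- config_window_spec(config, record$fs)
  if (is.null(windows)) windows <- segment_windows(record, spec)
  nch <- ncol(record$data)
  fnames <- feature_names_for(kind, nch, config)
  if (nrow(windows) == 0) {
    empty <- as_tibble(setNames(
      rep(list(numeric()), length(fnames)), fnames))
    out <- dplyr::bind_cols(
      tibble(cycle = integer(), window_index = integer(),
             start_s = numeric(), label = character()), empty)
    return(new_feature_set(out, kind = kind, n_channels = nch))
  }
  idx <- outer(seq_len(spec$n_window) - 1L, windows$start_sample, `+`)
  blocks <- lapply(seq_len(nch), function(ch) {
    Xw <- matrix(record$data[, ch][idx], nrow = spec$n_window)
    if (kind == "ar") {
      rbind(burg_matrix(Xw, config$ar_order), sqrt(colMeans(Xw^2)))
    } else {
      fc_matrix(Xw, config$n_fc, config$fc_epsilon)
    }
  })
  fm <- t(do.call(rbind, blocks))
  colnames(fm) <- fnames
  out <- dplyr::bind_cols(
    tibble(cycle = windows$cycle, window_index = windows$window_index,
           start_s = windows$start_s, label = windows$label),
    as_tibble(fm))
  new_feature_set(out, kind = kind, n_channels = nch)
}

feature_names_for <- function(kind, n_channels, config) {
  per <- if (kind == "ar") {
    c(paste0("ar", seq_len(config$ar_order)), "rms")
  } else {
    paste0("fc", seq_len(config$n_fc))
  }
  as.vector(t(outer(paste0("ch", seq_len(n_channels), "_"), per, paste0)))
}
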