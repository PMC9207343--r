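#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal `x + i H(x)` where `H` is the Hilbert
#' transform, computed by one-sided spectral weighting.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("input must be finite numeric", call. = FALSE)
  }
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Weighted phase lag index of two signals
#'
#' Estimates the WPLI from the instantaneous cross-spectrum of the analytic
#' signals: phase leads and lags are weighted by the magnitude of the
#' imaginary part of the cross-spectrum, making the index insensitive to
#' zero-lag (volume-conducted) coupling,
#' \deqn{\mathrm{WPLI} = \frac{|\sum_t |\Im S_{xy}(t)|\,
#'   \mathrm{sgn}\,\Im S_{xy}(t)|}{\sum_t |\Im S_{xy}(t)|}.}
#' When the denominator vanishes (e.g. identical signals, for which the
#' imaginary cross-spectrum is identically zero) the index is defined as 0.
#' The absolute value in the numerator keeps the estimate in \[0, 1\].
#'
#' A fraction `edge_trim` of samples is discarded at each end before
#' summation to suppress Hilbert edge transients. Inputs are expected to be
#' band-limited (e.g. alpha-band extracted, see [wavelet_alpha_extract()]).
#'
#' @param x,y Real numeric vectors of equal length (>= 64 samples).
#' @param edge_trim Fraction in \[0, 0.45\] of samples dropped at each end.
#' @return WPLI value in \[0, 1\].
#' @export
#' @examples
#' t <- seq(0, 4, by = 1 / 400)
#' x <- sin(2 * pi * 10 * t)
#' y <- sin(2 * pi * 10 * t - pi / 2)  # constant quarter-cycle lag
#' wpli_pair(x, y)  # 1
wpli_pair <- function(x, y, edge_trim = 0.05) {
  if (length(x) != length(y)) {
    stop("signals have different lengths", call. = FALSE)
  }
  if (length(x) < 64) stop("signals must have >= 64 samples", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite input", call. = FALSE)
  }
  if (edge_trim < 0 || edge_trim > 0.45) {
    stop("`edge_trim` must be in [0, 0.45]", call. = FALSE)
  }
  .wpli_from_analytic(analytic_signal(x), analytic_signal(y), edge_trim)
}

.wpli_from_analytic <- function(zx, zy, edge_trim = 0.05) {
  n <- length(zx)
  drop <- floor(n * edge_trim)
  idx <- seq.int(drop + 1, n - drop)
  im <- Im(zx[idx] * Conj(zy[idx]))
  den <- sum(abs(im))
  if (den == 0) return(0)
  abs(sum(im)) / den  # sum(|im| * sign(im)) == sum(im)
}

#' @rdname connectivity_matrix
#' @param edge_trim Fraction of samples discarded at each end of the
#'   analytic signal before the WPLI summation (Hilbert edge transients).
#' @details The `eeg_recording` method computes entry (i, j) as
#'   `wpli_pair(channel i, channel j)`; the diagonal is 0 and the result is
#'   symmetric by construction.
#' @export
#' @examples
#' cfg <- kuramoto_config(n_oscillators = 3, n_samples = 3000,
#'                        burn_in = 500, seed = 1)
#' m <- connectivity_matrix(matrix(0.4, 3, 3) - diag(0.4, 3))
#' rec <- to_eeg(simulate_kuramoto(cfg, m), labels = rownames(m))
#' connectivity_matrix(rec)
connectivity_matrix.eeg_recording <- function(x, edge_trim = 0.05, ...) {
  nc <- n_channels(x)
  if (nc < 2) stop("need at least 2 channels", call. = FALSE)
  za <- lapply(seq_len(nc), function(i) analytic_signal(x$data[, i]))
  w <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1)) {
    for (j in seq.int(i + 1, nc)) {
      wij <- tryCatch(
        .wpli_from_analytic(za[[i]], za[[j]], edge_trim),
        error = function(e) {
          stop(sprintf("WPLI failed for channels %s-%s: %s",
                       x$channel_labels[i], x$channel_labels[j],
                       conditionMessage(e)), call. = FALSE)
        }
      )
      w[i, j] <- wij
      w[j, i] <- wij
    }
  }
  connectivity_matrix(w, channel_labels = x$channel_labels)
}
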