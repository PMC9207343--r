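#' Daubechies scaling (lowpass) filter
#'
#' Computes the orthonormal Daubechies scaling filter with `n_moments`
#' vanishing moments (filter length `2 * n_moments`) by spectral
#' factorization of the Daubechies half-band polynomial: the minimum-phase
#' root set of the binomial polynomial is combined with the `(1 + z)^N`
#' factor and normalized so the coefficients sum to `sqrt(2)`.
#'
#' @param n_moments Number of vanishing moments (1..12; `db10` = 10).
#' @return Numeric vector of `2 * n_moments` filter coefficients.
#' @export
#' @examples
#' h <- daubechies_filter(10)
#' sum(h^2)  # 1 (orthonormal)
daubechies_filter <- function(n_moments) {
  n <- as.integer(n_moments)
  if (is.na(n) || n < 1 || n > 12) {
    stop("`n_moments` must be an integer in 1..12", call. = FALSE)
  }
  if (n == 1) return(c(1, 1) / sqrt(2))  # Haar
  k <- 0:(n - 1)
  pc <- choose(n - 1 + k, k)           # P(y), ascending powers
  yr <- polyroot(pc)
  zroots <- vapply(yr, function(y) {
    b <- 2 - 4 * y                      # z + 1/z = 2 - 4y
    disc <- sqrt(as.complex(b^2 - 4))
    z1 <- (b + disc) / 2
    z2 <- (b - disc) / 2
    if (Mod(z1) < 1) z1 else z2         # minimum-phase factor
  }, complex(1))
  coef <- 1 + 0i
  for (i in seq_len(n)) coef <- c(0i, coef) + c(coef, 0i)   # (1 + z)^N
  for (z in zroots) coef <- c(0i, coef) - z * c(coef, 0i)   # (z - z_r)
  h <- Re(coef)
  h * sqrt(2) / sum(h)
}

# Squared-magnitude transfer function (length M) of the MODWT
# multiresolution detail at the requested `levels`, for scaling filter `h`.
# The MRA detail at level j is the signal circularly filtered with
# |G(2^{j-1} f) prod_{l<j-1} H(2^l f)|^2, a zero-phase operation; summing
# the squared transfers over all levels plus the smooth gives exactly 1
# (orthonormal filters), so reconstruction from all levels is the identity.
.modwt_detail_transfer <- function(M, h, levels) {
  L <- length(h)
  if (M < L) stop("signal too short for the wavelet filter", call. = FALSE)
  hm <- h / sqrt(2)                              # MODWT scaling filter
  gm <- rev(hm) * (-1)^(seq_along(hm) - 1)       # QMF wavelet filter
  H <- fft(c(hm, numeric(M - L)))
  G <- fft(c(gm, numeric(M - L)))
  idx0 <- 0:(M - 1)
  total <- numeric(M)
  for (j in levels) {
    Tj <- G[(2^(j - 1) * idx0) %% M + 1]
    if (j > 1) {
      for (l in 0:(j - 2)) Tj <- Tj * H[(2^l * idx0) %% M + 1]
    }
    total <- total + Mod(Tj)^2
  }
  total
}

# Dyadic level whose MODWT detail band fs/2^(j+1) .. fs/2^j contains 10 Hz.
alpha_level <- function(fs) max(1L, floor(log2(fs / 10)))

#' Extract the alpha band from an EEG recording
#'
#' Isolates alpha-band activity by wavelet multiresolution decomposition:
#' each channel is decomposed with the maximal-overlap discrete wavelet
#' transform (default wavelet `db10`) and reconstructed from the detail
#' level whose octave band contains 10 Hz (level 5 at 400 Hz, spanning
#' 6.25-12.5 Hz). The transform is linear, length-preserving and zero-phase;
#' boundaries are handled by whole-signal reflection. Because the alpha band
#' (8-13 Hz) straddles two dyadic levels, `include_adjacent = TRUE` adds the
#' next-finer detail level (12.5-25 Hz at 400 Hz), and `method = "fir"`
#' substitutes a zero-phase 8-13 Hz FIR band-pass instead of the wavelet
#' reconstruction.
#'
#' @param rec An [eeg_recording()].
#' @param wavelet Wavelet name, `"db1"` .. `"db12"`. Default `"db10"`.
#' @param level Decomposition level to reconstruct; default chosen from the
#'   sampling rate so the detail band contains 10 Hz.
#' @param include_adjacent Also reconstruct the next-finer detail level.
#' @param method `"modwt"` (wavelet reconstruction, default) or `"fir"`
#'   (zero-phase FIR band-pass, 8-13 Hz).
#' @return An `eeg_recording` of identical shape containing the band-limited
#'   signal.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 400)[-1]
#' rec <- eeg_recording(cbind(a = sin(2 * pi * 10 * t)), fs = 400)
#' out <- wavelet_alpha_extract(rec)
#' var(out$data) / var(rec$data)  # close to 1: 10 Hz is retained
wavelet_alpha_extract <- function(rec, wavelet = "db10", level = NULL,
                                  include_adjacent = FALSE,
                                  method = c("modwt", "fir")) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "eeg_recording"))
  n <- n_samples(rec)
  out <- rec$data

  if (method == "fir") {
    ny <- rec$fs / 2
    if (ny <= 13) stop("sampling rate too low for an 8-13 Hz band", call. = FALSE)
    ord <- min(round(rec$fs), floor((n - 1) / 3) * 2)  # ~1 s of taps
    b <- signal::fir1(ord, c(8, 13) / ny, type = "pass")
    for (i in seq_len(ncol(out))) {
      out[, i] <- signal::filtfilt(signal::Ma(b), rec$data[, i])
    }
  } else {
    if (!grepl("^db[0-9]+$", wavelet)) {
      stop("unsupported wavelet: ", wavelet, call. = FALSE)
    }
    h <- daubechies_filter(as.integer(sub("db", "", wavelet)))
    level <- level %||% alpha_level(rec$fs)
    if (level < 1) stop("`level` must be >= 1", call. = FALSE)
    if (n < 2^level) {
      stop(sprintf("signal too short for level %d: need >= %d samples, got %d",
                   level, 2^level, n), call. = FALSE)
    }
    levels <- if (include_adjacent) c(level, max(1L, level - 1L)) else level
    M <- 2L * n                       # reflection extension
    trans <- .modwt_detail_transfer(M, h, unique(levels))
    for (i in seq_len(ncol(out))) {
      xe <- c(rec$data[, i], rev(rec$data[, i]))
      y <- Re(fft(fft(xe) * trans, inverse = TRUE)) / M
      out[, i] <- y[seq_len(n)]
    }
  }
  eeg_recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, group = rec$group)
}
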