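#' Complexity estimator parameters
#'
#' Bundles the tunable parameters of the three complexity estimators.
#' `hfd_kmax` defaults to 18, the setting used for real EEG; simulated
#' signals are scored with `hfd_kmax = 6`.
#'
#' @param hfd_kmax Maximum subsampling scale for Higuchi's fractal
#'   dimension (>= 2).
#' @param fdispen_m Embedding dimension for dispersion entropy (default 3).
#' @param fdispen_c Number of amplitude classes (default 3).
#' @param fdispen_d Embedding time delay (default 1).
#' @param fdispen_mapping Amplitude-to-class mapping: `"ncdf"` (normal CDF
#'   with the signal's mean and SD, then uniform quantization; default) or
#'   `"linear"` (equal-width bins over the signal range).
#' @param fdispen_normalize Divide the entropy by its maximum
#'   `log((2c-1)^(m-1))` (default FALSE).
#' @param lzc_threshold Binarization rule for Lempel-Ziv complexity; only
#'   `"median"` is defined.
#' @return A `complexity_params` list.
#' @export
complexity_params <- function(hfd_kmax = 18, fdispen_m = 3, fdispen_c = 3,
                              fdispen_d = 1,
                              fdispen_mapping = c("ncdf", "linear"),
                              fdispen_normalize = FALSE,
                              lzc_threshold = "median") {
  fdispen_mapping <- match.arg(fdispen_mapping)
  lzc_threshold <- match.arg(lzc_threshold)
  if (hfd_kmax < 2) stop("`hfd_kmax` must be >= 2", call. = FALSE)
  if (fdispen_m < 2) stop("`fdispen_m` must be >= 2", call. = FALSE)
  if (fdispen_c < 2) stop("`fdispen_c` must be >= 2", call. = FALSE)
  if (fdispen_d < 1) stop("`fdispen_d` must be >= 1", call. = FALSE)
  structure(
    list(hfd_kmax = as.integer(hfd_kmax), fdispen_m = as.integer(fdispen_m),
         fdispen_c = as.integer(fdispen_c), fdispen_d = as.integer(fdispen_d),
         fdispen_mapping = fdispen_mapping,
         fdispen_normalize = fdispen_normalize,
         lzc_threshold = lzc_threshold),
    class = "complexity_params"
  )
}

#' Lempel-Ziv complexity
#'
#' Binarizes the signal at its median (samples strictly above the median
#' map to 1, all others to 0), counts the number of productions c(n) of the
#' Lempel-Ziv (1976) exhaustive parsing (the final incomplete word counts as
#' one production), and returns the normalized complexity
#' `C(n) = c(n) / (n / log2(n))`. Values approach 1 for i.i.d. random
#' binary sequences and 0 for constant signals.
#'
#' @param x Numeric vector, length >= 32.
#' @return Normalized complexity (roughly in \[0, 1.1\]).
#' @export
#' @examples
#' lzc(rep(1, 14000))          # ~0.002: a constant parses into 2 words
#' # lzc(rnorm(14000))         # ~1: incompressible
lzc <- function(x) {
  n <- length(x)
  if (n < 32) stop("signal too short for LZC: need >= 32 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite input", call. = FALSE)
  b <- as.integer(x > median(x))
  cn <- .lz76_count_cpp(b)
  cn * log2(n) / n
}

# Raw LZ76 production count of an already-binarized sequence.
lz76_count <- function(bits) .lz76_count_cpp(as.integer(bits))

#' Higuchi's fractal dimension
#'
#' Estimates the fractal dimension of a time series from mean curve lengths
#' at subsampling scales `k = 1..kmax`: for each scale the k decimated
#' curves starting at offsets m = 1..k are measured, their normalized
#' lengths averaged to L(k), and the least-squares slope of `log(L(k))`
#' against `log(1/k)` is returned. Smooth curves give values near 1,
#' uncorrelated noise near 2.
#'
#' @param x Numeric vector, length >= 10 * kmax.
#' @param kmax Maximum scale (default 18, the real-EEG setting; use 6 for
#'   the simulated signals).
#' @return Fractal dimension estimate.
#' @export
#' @examples
#' hfd(seq_len(2000), kmax = 6)  # straight line: 1
hfd <- function(x, kmax = 18) {
  n <- length(x)
  kmax <- as.integer(kmax)
  if (kmax < 2) stop("`kmax` must be >= 2", call. = FALSE)
  if (n < 10 * kmax) {
    stop(sprintf("signal too short for kmax = %d: need >= %d samples",
                 kmax, 10 * kmax), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite input", call. = FALSE)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      nm <- floor((n - m) / k)           # Gauss-bracket index limit
      if (nm < 1) {
        Lm[m] <- NA_real_
        next
      }
      idx <- m + (0:nm) * k
      Lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  keep <- Lk > 0
  if (sum(keep) < 2) return(1)          # flat signal: a smooth curve
  fit <- lsfit(log(1 / seq_len(kmax))[keep], log(Lk[keep]))
  unname(fit$coefficients[2])
}

# Map a signal to integer classes 1..c. "ncdf": Gaussian CDF with the
# signal's own mean/sd, then uniform quantization (a zero-variance signal
# maps to the middle class); "linear": equal-width bins over the range.
.fdispen_classify <- function(x, c_classes, mapping) {
  if (mapping == "ncdf") {
    s <- sd(x)
    if (s == 0) return(rep(ceiling(c_classes / 2), length(x)))
    y <- pnorm(x, mean = mean(x), sd = s)
  } else {
    rg <- range(x)
    if (rg[1] == rg[2]) return(rep(ceiling(c_classes / 2), length(x)))
    y <- (x - rg[1]) / (rg[2] - rg[1])
  }
  clip(ceiling(y * c_classes), 1, c_classes)
}

# Frequencies of fluctuation patterns: embedded class vectors (dimension m,
# delay d) reduced to their m-1 successive differences; each difference
# lies in -(c-1)..(c-1), giving (2c-1)^(m-1) possible patterns.
.fluctuation_pattern_counts <- function(u, m, c_classes, d) {
  n <- length(u)
  n_emb <- n - (m - 1) * d
  if (n_emb < 1) stop("signal too short for the embedding", call. = FALSE)
  base <- 2 * c_classes - 1
  code <- numeric(n_emb)
  for (j in seq_len(m - 1)) {
    dj <- u[seq.int(1 + j * d, length.out = n_emb)] -
      u[seq.int(1 + (j - 1) * d, length.out = n_emb)]
    code <- code * base + (dj + c_classes - 1)
  }
  tabulate(code + 1, nbins = base^(m - 1))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Fluctuation-based dispersion entropy
#'
#' Maps the signal to `c` amplitude classes, embeds the class series with
#' dimension `m` and delay `d`, reduces each embedded vector to its `m - 1`
#' successive differences (the fluctuation pattern), and returns the Shannon
#' entropy (natural log) of the pattern distribution. There are
#' `(2c-1)^(m-1)` possible patterns, so the entropy is bounded by
#' `log((2c-1)^(m-1))`; with the defaults m = 3, c = 3 the bound is
#' log(25) = 3.219.
#'
#' @param x Numeric vector; length must exceed `(m-1) * d + 100`.
#' @param params A [complexity_params()]; the `fdispen_*` entries are used.
#' @return Entropy in nats (or in \[0, 1\] when `fdispen_normalize`).
#' @export
#' @examples
#' fdispen(rep(3.7, 200))   # constant: single pattern, entropy 0
fdispen <- function(x, params = complexity_params()) {
  stopifnot(inherits(params, "complexity_params"))
  m <- params$fdispen_m
  cc <- params$fdispen_c
  d <- params$fdispen_d
  if (length(x) < (m - 1) * d + 100) {
    stop(sprintf("signal too short for FDispEn: need > %d samples",
                 (m - 1) * d + 100), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite input", call. = FALSE)
  u <- .fdispen_classify(x, cc, params$fdispen_mapping)
  counts <- .fluctuation_pattern_counts(u, m, cc, d)
  h <- shannon_entropy(counts / sum(counts))
  if (params$fdispen_normalize) h / log((2 * cc - 1)^(m - 1)) else h
}

#' Score a recording with all three complexity measures
#'
#' Computes LZC, HFD and FDispEn for every channel and tags each row with
#' the channel's scalp region. The result is a long-format complexity table
#' with one row per channel and measure; regional summaries are means over a
#' region's channels (see [regional_means()]).
#'
#' @param rec An [eeg_recording()].
#' @param params A [complexity_params()].
#' @param regions Named region map as from [region_map()]; every channel of
#'   `rec` must be present in the map.
#' @return Data frame with columns `source_id`, `group`, `channel`,
#'   `region`, `measure`, `value`.
#' @export
score_recording <- function(rec, params = complexity_params(),
                            regions = region_map()) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing_ch <- setdiff(rec$channel_labels, names(regions))
  if (length(missing_ch) > 0) {
    stop("channel(s) not in region map: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(n_channels(rec)), function(i) {
    x <- rec$data[, i]
    ch <- rec$channel_labels[i]
    data.frame(
      source_id = rec$subject_id, group = rec$group, channel = ch,
      region = unname(regions[ch]),
      measure = c("LZC", "HFD", "FDispEn"),
      value = c(lzc(x), hfd(x, params$hfd_kmax), fdispen(x, params)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @rdname score_recording
#' @param recs List of recordings (e.g. from [run_ensemble()] or
#'   [gen_synthetic_eeg()]).
#' @export
score_recordings <- function(recs, params = complexity_params(),
                             regions = region_map()) {
  do.call(rbind, lapply(recs, score_recording, params = params,
                        regions = regions))
}

#' Per-unit regional mean complexity
#'
#' Averages a complexity table over the channels of each scalp region,
#' per source (subject or simulation run) and measure. Channels with region
#' `"unassigned"` are excluded.
#'
#' @param tbl Complexity table from [score_recording()] /
#'   [score_recordings()].
#' @return Data frame with columns `source_id`, `region`, `measure`,
#'   `value`.
#' @export
regional_means <- function(tbl) {
  tbl <- tbl[tbl$region != "unassigned", , drop = FALSE]
  out <- aggregate(value ~ source_id + region + measure, data = tbl,
                   FUN = mean)
  out[order(out$measure, out$region, out$source_id), , drop = FALSE]
}
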