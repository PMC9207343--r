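# Independent brute-force oracles used to validate the fast implementations.

# LZ76 exhaustive-production parsing by direct substring search: the next
# word is the shortest prefix of the remainder that does not occur in the
# text preceding its last character; a reproducible tail counts as one
# final word.
lz76_oracle <- function(bits) {
  s <- paste(as.integer(bits), collapse = "")
  n <- nchar(s)
  cnt <- 0L
  p <- 1L
  while (p <= n) {
    k <- 1L
    repeat {
      if (p + k - 1L > n) {           # ran off the end: incomplete word
        return(cnt + 1L)
      }
      word <- substr(s, p, p + k - 1L)
      hist <- substr(s, 1L, p + k - 2L)
      if (!grepl(word, hist, fixed = TRUE)) break
      k <- k + 1L
    }
    cnt <- cnt + 1L
    p <- p + k
  }
  cnt
}

# Naive fluctuation-pattern frequencies: enumerate embedded vectors with an
# explicit loop and count difference patterns in a named table.
fdispen_counts_oracle <- function(u, m, c_classes, d) {
  n_emb <- length(u) - (m - 1) * d
  pats <- character(n_emb)
  for (i in seq_len(n_emb)) {
    v <- u[i + (0:(m - 1)) * d]
    pats[i] <- paste(diff(v), collapse = ",")
  }
  # order counts on the same coding as the implementation
  base <- 2 * c_classes - 1
  all_diffs <- expand.grid(rep(list((-(c_classes - 1)):(c_classes - 1)), m - 1))
  keys <- apply(as.matrix(all_diffs[, rev(seq_len(m - 1)), drop = FALSE]), 1,
                paste, collapse = ",")
  counts <- table(factor(pats, levels = keys))
  as.integer(counts)
}

# Direct per-sample evaluation of the weighted phase lag index from two
# analytic signals built with an explicit DFT (no shared code with the
# package implementation).
wpli_oracle <- function(x, y, edge_trim = 0.05) {
  analytic <- function(v) {
    n <- length(v)
    j <- 0:(n - 1)
    V <- vapply(j, function(kk) sum(v * exp(-2i * pi * kk * j / n)), complex(1))
    w <- numeric(n)
    if (n %% 2 == 0) {
      w[c(1, n / 2 + 1)] <- 1
      w[2:(n / 2)] <- 2
    } else {
      w[1] <- 1
      w[2:((n + 1) / 2)] <- 2
    }
    vapply(j, function(tt) sum(V * w * exp(2i * pi * j * tt / n)) / n,
           complex(1))
  }
  zx <- analytic(x)
  zy <- analytic(y)
  n <- length(x)
  drop <- floor(n * edge_trim)
  num <- 0
  den <- 0
  for (t in seq.int(drop + 1, n - drop)) {
    im <- Im(zx[t] * Conj(zy[t]))
    num <- num + abs(im) * sign(im)
    den <- den + abs(im)
  }
  if (den == 0) 0 else abs(num) / den
}

# Small helpers for building fixtures in code.
make_sine <- function(freq, fs = 400, duration = 5, phase = 0) {
  t <- seq_len(round(fs * duration)) / fs
  sin(2 * pi * freq * t + phase)
}

uniform_cmat <- function(n, value, labels = NULL) {
  m <- matrix(value, n, n) - diag(value, n)
  connectivity_matrix(m, channel_labels = labels %||% paste0("ch", seq_len(n)))
}

# Minimal complexity table with one channel per region, for statistics
# tests: `values` is a named list region -> matrix (units x measures).
null_complexity_table <- function(n_units, prefix, rng_values) {
  regions <- c("anterior", "central", "posterior")
  measures <- c("LZC", "HFD", "FDispEn")
  grid <- expand.grid(unit = seq_len(n_units), region = regions,
                      measure = measures, stringsAsFactors = FALSE)
  data.frame(
    source_id = paste0(prefix, grid$unit),
    group = prefix,
    channel = c(anterior = "Fz", central = "Cz", posterior = "Pz")[grid$region],
    region = grid$region,
    measure = grid$measure,
    value = rng_values(nrow(grid)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
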