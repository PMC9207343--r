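#' Connectivity matrix over EEG channels
#'
#' A symmetric nonnegative weighted graph over channels: weights in
#' \[0, 1\], zero diagonal, labelled rows/columns. `connectivity_matrix()`
#' is a generic: applied to a numeric matrix it validates and wraps it;
#' applied to an [eeg_recording()] it estimates the WPLI matrix (see
#' [wpli_pair()]).
#'
#' @param x A square numeric matrix or an `eeg_recording`.
#' @param ... Passed to methods.
#' @return An object of class `connectivity_matrix` (a labelled numeric
#'   matrix).
#' @export
connectivity_matrix <- function(x, ...) UseMethod("connectivity_matrix")

#' @rdname connectivity_matrix
#' @param channel_labels Labels for the matrix rows/columns; defaults to the
#'   dimnames of `x`.
#' @export
connectivity_matrix.matrix <- function(x, channel_labels = rownames(x), ...) {
  if (nrow(x) != ncol(x)) stop("matrix must be square", call. = FALSE)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(x)))
  }
  if (length(channel_labels) != nrow(x)) {
    stop("label count does not match matrix dimension", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite weights", call. = FALSE)
  if (max(abs(x - t(x))) >= 1e-12) {
    stop("matrix is not symmetric (tolerance 1e-12)", call. = FALSE)
  }
  if (any(diag(x) != 0)) stop("diagonal must be exactly 0", call. = FALSE)
  if (min(x) < 0 || max(x) > 1) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  x <- (x + t(x)) / 2  # enforce exact symmetry
  dimnames(x) <- list(channel_labels, channel_labels)
  class(x) <- c("connectivity_matrix", class(matrix()))
  x
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d nodes, mean strength %.4f\n",
              nrow(x), mean_strength(x)))
  invisible(x)
}

#' Mean connectivity strength
#'
#' Arithmetic mean of the strict upper-triangle entries, i.e. of the
#' N(N-1)/2 undirected edge weights.
#'
#' @param mat A [connectivity_matrix()].
#' @return Scalar mean edge strength.
#' @export
#' @examples
#' m <- connectivity_matrix(matrix(0.5, 3, 3) - diag(0.5, 3))
#' mean_strength(m)  # 0.5
mean_strength <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 nodes", call. = FALSE)
  mean(mat[upper.tri(mat)])
}

#' Average connectivity matrices elementwise
#'
#' Used to pool subject-level WPLI matrices into a group matrix.
#'
#' @param mats Non-empty list of [connectivity_matrix()] objects with
#'   identical dimensions and labels.
#' @return The elementwise mean as a `connectivity_matrix`.
#' @export
average_matrices <- function(mats) {
  if (!is.list(mats) || length(mats) == 0) {
    stop("`mats` must be a non-empty list", call. = FALSE)
  }
  lab <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(rownames(m), lab)) {
      stop("matrices have mismatched channel labels", call. = FALSE)
    }
  }
  avg <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  connectivity_matrix(avg, channel_labels = lab)
}

#' Induce a regional lesion in a connectivity matrix
#'
#' Emulates network disconnection: every edge incident to a channel in
#' `region_channels` is replaced by the constant `strength`. The default
#' region is the five central channels (T3, C3, Cz, C4, T4) and the default
#' strength 0.1, the lowest non-zero edge weight observed in the averaged
#' patient matrix of the study this models.
#'
#' @param mat A [connectivity_matrix()].
#' @param channels Channel labels defining the lesioned region; must be a
#'   subset of the matrix labels.
#' @param strength Replacement edge strength in \[0, 1\].
#' @return The lesioned `connectivity_matrix`.
#' @export
#' @examples
#' m <- connectivity_matrix(matrix(0.5, 21, 21) - diag(0.5, 21),
#'                          channel_labels = eeg_channels_1020())
#' mean_strength(induce_lesion(m))  # (120*0.5 + 90*0.1)/210 = 0.3286
induce_lesion <- function(mat, channels = region_channels("central"),
                          strength = 0.1) {
  stopifnot_scalar_prob(strength, "strength")
  lab <- rownames(mat)
  unknown <- setdiff(channels, lab)
  if (length(unknown) > 0) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- which(lab %in% channels)
  out <- unclass(mat)
  out[idx, ] <- strength
  out[, idx] <- strength
  diag(out) <- 0
  connectivity_matrix(out, channel_labels = lab)
}

#' Read / write connectivity matrices as CSV
#'
#' Layout: first column and header row carry channel labels, values at full
#' precision.
#'
#' @param path File path.
#' @param mat Matrix to write.
#' @return `read_connectivity_csv()` returns a [connectivity_matrix()];
#'   `write_connectivity_csv()` returns `path` invisibly.
#' @export
read_connectivity_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  connectivity_matrix(as.matrix(df), channel_labels = rownames(df))
}

#' @rdname read_connectivity_csv
#' @export
write_connectivity_csv <- function(mat, path) {
  df <- as.data.frame(unclass(mat))
  write.csv(df, path, row.names = TRUE)
  invisible(path)
}
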