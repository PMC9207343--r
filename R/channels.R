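#' Default 10-20 montage channel labels
#'
#' The 21 electrode locations of the study montage, in recording order.
#'
#' @return Character vector of 21 channel labels.
#' @export
#' @examples
#' eeg_channels_1020()
eeg_channels_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "T1", "T2", "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

#' Scalp region map for the 10-20 montage
#'
#' Assigns each channel to one of three scalp regions used for regional
#' complexity summaries: anterior (Fp1, Fp2, F7, F3, Fz, F4, F8), central
#' (T3, C3, Cz, C4, T4) and posterior (T5, P3, Pz, P4, T6, O1, O2).
#' The anterior temporal electrodes T1 and T2 belong to the montage but to
#' none of the three regions; they are mapped to `"unassigned"` and excluded
#' from regional means.
#'
#' @param labels Channel labels to map. Defaults to the full montage.
#' @return Named character vector: `labels` -> region.
#' @export
#' @examples
#' table(region_map())
region_map <- function(labels = eeg_channels_1020()) {
  anterior  <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")
  central   <- c("T3", "C3", "Cz", "C4", "T4")
  posterior <- c("T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  reg <- rep("unassigned", length(labels))
  reg[labels %in% anterior]  <- "anterior"
  reg[labels %in% central]   <- "central"
  reg[labels %in% posterior] <- "posterior"
  names(reg) <- labels
  reg
}

#' Channels belonging to a scalp region
#'
#' @param region One of `"anterior"`, `"central"`, `"posterior"`.
#' @param map A region map as returned by [region_map()].
#' @return Character vector of channel labels.
#' @export
region_channels <- function(region = c("anterior", "central", "posterior"),
                            map = region_map()) {
  region <- match.arg(region)
  names(map)[map == region]
}
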