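#' Standard 10-20 / 10-10 electrode montages
#'
#' Builds a flat (top-view) 2D layout of scalp electrodes on the unit head
#' circle. Positions follow the proportional 10-20 placement system: the
#' vertex (Cz) is at the origin, the preauricular/inion rim is the unit
#' circle, and each electrode row sits at a fixed anterior-posterior
#' fraction with lateral sites spread over the chord at that row.
#'
#' Two layouts are provided: the classic 19-electrode 10-20 set and an
#' extended 63-electrode 10-10 set (the density of a 64-channel cap once
#' the vertical EOG channel is added).
#'
#' @param n_channels Number of EEG channels: 19 or 63.
#' @param include_veog If `TRUE`, append a `"VEOG"` channel placed below the
#'   left eye (outside the head circle; excluded from scalp interpolation).
#' @return A data.frame with columns `label`, `x`, `y` and logical `eog`.
#' @examples
#' m <- montage_1020(19)
#' subset(m, label == "Fz")
#' @export
montage_1020 <- function(n_channels = 63, include_veog = TRUE) {
  rows <- list(
    # y fraction, labels left-to-right (left hemisphere first)
    list(y =  0.8, labels = c("Fp1", "Fpz", "Fp2")),
    list(y =  0.6, labels = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y =  0.4, labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    list(y =  0.2, labels = c("FT9", "FT7", "FC5", "FC3", "FC1", "FCz",
                              "FC2", "FC4", "FC6", "FT8", "FT10")),
    list(y =  0.0, labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    list(y = -0.2, labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8")),
    list(y = -0.4, labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    list(y = -0.6, labels = c("PO7", "PO3", "POz", "PO4", "PO8")),
    list(y = -0.8, labels = c("O1", "Oz", "O2"))
  )
  pos <- do.call(rbind, lapply(rows, function(r) {
    k <- length(r$labels)
    half <- (k - 1) / 2
    # lateral fractions -1..1 across the row, scaled to the chord width so
    # outermost row sites land on the head circle
    lat <- (seq_len(k) - 1 - half) / max(half, 1)
    chord <- sqrt(max(0, 1 - r$y^2))
    data.frame(label = r$labels, x = lat * chord, y = r$y,
               stringsAsFactors = FALSE)
  }))
  if (n_channels == 19) {
    keep <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
              "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
    pos <- pos[match(keep, pos$label), ]
  } else if (n_channels != 63) {
    stop("montage_1020: supported layouts are 19 or 63 EEG channels")
  }
  pos$eog <- FALSE
  if (include_veog) {
    pos <- rbind(pos, data.frame(label = "VEOG", x = -0.25, y = 1.05,
                                 eog = TRUE, stringsAsFactors = FALSE))
  }
  rownames(pos) <- NULL
  pos
}

#' Names of the EEG (non-EOG) channels of a montage or recording
#' @param x A montage data.frame, `raw_recording`, `epochs` or `evoked`.
#' @return Character vector of channel labels.
#' @export
eeg_channels <- function(x) {
  m <- if (is.data.frame(x)) x else x$montage
  m$label[!m$eog]
}
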