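# Package archive format for epoched/evoked data: magic "ERPA", a 4-byte
# little-endian JSON header length, the JSON header (dims, time axis,
# montage, labels), then the data tensor as little-endian float32.

write_erp_archive <- function(header, payload, path) {
  hj <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("ERPA"), con)
  writeBin(length(hj), con, size = 4, endian = "little")
  writeBin(hj, con)
  writeBin(as.numeric(payload), con, size = 4, endian = "little")
  invisible(path)
}

read_erp_archive <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "ERPA")
    stop("read_erp_archive: not an ERP archive (bad magic)")
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)))
  len <- prod(unlist(header$dim))
  payload <- readBin(con, "numeric", len, size = 4, endian = "little")
  if (length(payload) < len) stop("read_erp_archive: truncated payload")
  list(header = header, payload = payload)
}

#' Write an evoked waveform to the package archive format
#' @param x An [evoked].
#' @param path Output path (conventionally `.erpa`).
#' @return Invisibly, `path`.
#' @export
write_evoked <- function(x, path) {
  stopifnot(inherits(x, "evoked"))
  header <- list(kind = "evoked", dim = dim(x$data), times = x$times,
                 sampling_rate = x$sampling_rate, condition = x$condition,
                 n = x$n, montage = x$montage)
  write_erp_archive(header, x$data, path)
}

#' Read an evoked waveform from the package archive format
#' @param path Path written by [write_evoked()].
#' @return An [evoked].
#' @export
read_evoked <- function(path) {
  a <- read_erp_archive(path)
  h <- a$header
  if (h$kind != "evoked") stop("read_evoked: archive does not hold an evoked")
  m <- as.data.frame(h$montage)
  evoked(matrix(a$payload, h$dim[1], h$dim[2]), h$times, h$sampling_rate,
         m, h$condition, h$n)
}

#' Export an evoked waveform as CSV
#'
#' Long CSV with one row per channel x time point (`channel`, `time_ms`,
#' `amplitude_uV`).
#'
#' @param x An [evoked].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_evoked_csv <- function(x, path) {
  stopifnot(inherits(x, "evoked"))
  df <- data.frame(channel = rep(x$channels, times = length(x$times)),
                   time_ms = rep(x$times, each = length(x$channels)),
                   amplitude_uV = as.numeric(x$data))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
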