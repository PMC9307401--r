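# EDF+ reader/writer. EDF is the 16-bit European Data Format: a 256-byte
# fixed header, 256 bytes of header per signal (field-major), then data
# records of little-endian int16 samples. EDF+ adds an "EDF Annotations"
# signal whose samples carry time-stamped annotation lists (TALs) as text.
# Event markers use the label grammar dec:<side> / fb:<valence> / blk:E=<v>.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

num_field <- function(x, width) pad_field(formatC(x, format = "fg", width = 1), width)

# marker labels <-> event_list
labels_from_events <- function(events) {
  lab <- paste0(events$event, ":", events$value)
  data.frame(sample = c(1L, events$sample),
             label = c(sprintf("blk:E=%g", events$block_E[1]), lab),
             stringsAsFactors = FALSE)
}

events_from_labels <- function(sample, label) {
  block_E <- NA_real_
  blk <- grepl("^blk:E=", label)
  if (any(blk)) block_E <- as.numeric(sub("^blk:E=", "", label[blk][1]))
  keep <- grepl("^(dec|fb):", label)
  if (!any(keep))
    return(event_list(integer(0), character(0), character(0), integer(0),
                      numeric(0)))
  sample <- sample[keep]
  label <- label[keep]
  event <- sub(":.*$", "", label)
  value <- sub("^[^:]*:", "", label)
  ord <- order(sample)
  trial <- integer(length(sample))
  trial[ord] <- cumsum(event[ord] == "dec")
  event_list(sample, event, value, pmax(trial, 1L), block_E)
}

#' Write a recording and its events as EDF+
#'
#' 16-bit EDF+ with 1-second data records, physical units microvolts, and
#' an annotations signal carrying the event markers (`dec:<side>`,
#' `fb:<valence>`, plus one `blk:E=<v>` annotation at t = 0). The recording
#' length is padded with zeros to a whole number of records.
#'
#' @param raw A [raw_recording].
#' @param events An [event_list] (or `NULL` for no markers).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(raw, events, path) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf: sampling rate must be an integer number of Hz")
  fs <- as.integer(round(fs))
  n_ch <- nrow(raw$data)
  n_rec <- as.integer(ceiling(ncol(raw$data) / fs))
  X <- matrix(0, n_ch, n_rec * fs)
  X[, seq_len(ncol(raw$data))] <- raw$data

  phys_max <- pmax(apply(abs(X), 1, max) * 1.0005, 1)
  phys_min <- -phys_max
  dmin <- -32768L; dmax <- 32767L

  # annotations: one TAL per marker; size records to the densest one.
  # With no events the annotations signal is omitted (plain EDF).
  has_ann <- !is.null(events) && nrow(events) > 0
  tals <- vector("list", n_rec)
  for (r in seq_len(n_rec)) tals[[r]] <- sprintf("+%d\024\024", r - 1L)
  if (has_ann) {
    marks <- labels_from_events(events)
    onset <- (marks$sample - 1) / fs
    rec <- pmin(floor(onset), n_rec - 1) + 1
    for (i in seq_along(onset)) {
      tals[[rec[i]]] <- paste0(tals[[rec[i]]],
                               sprintf("\001+%.6f\024%s\024", onset[i],
                                       marks$label[i]))
    }
  }
  tal_bytes <- lapply(tals, function(s) {
    b <- charToRaw(s)
    b[b == as.raw(1)] <- as.raw(0)  # TAL separator placeholder -> NUL
    c(b, as.raw(0))
  })
  ns_ann <- as.integer(ceiling(max(vapply(tal_bytes, length, 0L)) / 2))

  ns <- n_ch + if (has_ann) 1L else 0L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad_field("0", 8))
  wr(pad_field("X X X X", 80))
  wr(pad_field("Startdate 01-JAN-2000 X X X", 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(num_field(256L * (ns + 1L), 8))
  wr(pad_field("EDF+C", 44))
  wr(num_field(n_rec, 8))
  wr(num_field(1L, 8))
  wr(num_field(ns, 4))
  ann <- function(x) if (has_ann) x else character(0)
  lab <- c(raw$channels, ann("EDF Annotations"))
  wr(paste(vapply(lab, pad_field, "", width = 16), collapse = ""))
  wr(strrep(" ", 80 * ns))                                  # transducer
  wr(paste(vapply(c(rep("uV", n_ch), ann("")), pad_field, "", width = 8),
           collapse = ""))                                  # physical dim
  wr(paste(vapply(c(formatC(phys_min, digits = 6, format = "g"), ann("-1")),
                  pad_field, "", width = 8), collapse = ""))
  wr(paste(vapply(c(formatC(phys_max, digits = 6, format = "g"), ann("1")),
                  pad_field, "", width = 8), collapse = ""))
  wr(paste(vapply(rep(dmin, ns), num_field, "", width = 8), collapse = ""))
  wr(paste(vapply(rep(dmax, ns), num_field, "", width = 8), collapse = ""))
  wr(strrep(" ", 80 * ns))                                  # prefiltering
  wr(paste(vapply(c(rep(fs, n_ch), ann(as.character(ns_ann))), num_field, "",
                  width = 8), collapse = ""))
  wr(strrep(" ", 32 * ns))                                  # reserved

  scale <- (dmax - dmin) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    j <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(n_ch)) {
      dig <- as.integer(round((X[i, j] - phys_min[i]) * scale[i] + dmin))
      writeBin(dig, con, size = 2, endian = "little")
    }
    if (has_ann) {
      tb <- tal_bytes[[r]]
      writeBin(c(tb, raw(2 * ns_ann - length(tb))), con)
    }
  }
  invisible(path)
}

read_header_field <- function(con, width, offset) {
  b <- readBin(con, "raw", width)
  if (length(b) < width)
    stop(sprintf("read_edf: truncated header at byte offset %d", offset))
  trimws(rawToChar(b))
}

#' Read an EDF or EDF+ file
#'
#' Parses the header, reconstructs the continuous recording in physical
#' units (all data signals must share one sampling rate), and decodes any
#' `EDF Annotations` signal into an [event_list] via the marker grammar
#' `dec:<side>` / `fb:<valence>` / `blk:E=<v>`. Channel positions are
#' looked up in the built-in 10-10 table; unknown labels get the head
#' center. A file without annotations yields an empty event list with a
#' warning.
#'
#' @param path EDF file path.
#' @return list with `raw` ([raw_recording]) and `events` ([event_list]).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_edf: no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  read_header_field(con, 8, 0)                      # version
  read_header_field(con, 160, 8)                    # patient + recording id
  read_header_field(con, 16, 168)                   # date + time
  header_bytes <- as.integer(read_header_field(con, 8, 184))
  read_header_field(con, 44, 192)                   # reserved / EDF+C
  n_rec <- as.integer(read_header_field(con, 8, 236))
  rec_dur <- as.numeric(read_header_field(con, 8, 244))
  ns <- as.integer(read_header_field(con, 4, 252))
  if (is.na(ns) || ns < 1) stop("read_edf: malformed header (signal count)")

  sig_field <- function(width) {
    off <- seek(con)
    vapply(seq_len(ns), function(i) read_header_field(con, width, off + (i - 1) * width), "")
  }
  labels <- sig_field(16)
  sig_field(80)                                     # transducer
  dims <- sig_field(8)
  phys_min <- as.numeric(sig_field(8))
  phys_max <- as.numeric(sig_field(8))
  dig_min <- as.numeric(sig_field(8))
  dig_max <- as.numeric(sig_field(8))
  sig_field(80)                                     # prefiltering
  nsamp <- as.integer(sig_field(8))
  sig_field(32)                                     # reserved

  is_ann <- labels == "EDF Annotations"
  data_idx <- which(!is_ann)
  if (length(data_idx) == 0) stop("read_edf: file contains no data signals")
  bad_unit <- dims[data_idx] != "" & !(dims[data_idx] %in% c("uV", "µV"))
  if (any(bad_unit))
    stop(sprintf("read_edf: non-microvolt channels present (%s)",
                 paste(labels[data_idx][bad_unit], collapse = ", ")))
  fs <- nsamp[data_idx] / rec_dur
  if (length(unique(fs)) != 1)
    stop("read_edf: data signals with mixed sampling rates are unsupported")
  fs <- fs[1]

  rec_samples <- sum(nsamp)
  X <- matrix(0, length(data_idx), n_rec * nsamp[data_idx[1]])
  ann_text <- raw(0)
  for (r in seq_len(n_rec)) {
    offset <- header_bytes + (r - 1) * 2 * rec_samples
    buf <- readBin(con, "integer", rec_samples, size = 2, endian = "little")
    if (length(buf) < rec_samples)
      stop(sprintf("read_edf: truncated data record %d at byte offset %d",
                   r, offset + 2 * length(buf)))
    pos <- 0
    for (s in seq_len(ns)) {
      seg <- buf[(pos + 1):(pos + nsamp[s])]
      pos <- pos + nsamp[s]
      if (is_ann[s]) {
        ann_text <- c(ann_text, writeBin(as.integer(seg), raw(),
                                         size = 2, endian = "little"))
      } else {
        i <- match(s, data_idx)
        phys <- (seg - dig_min[s]) / (dig_max[s] - dig_min[s]) *
          (phys_max[s] - phys_min[s]) + phys_min[s]
        X[i, ((r - 1) * nsamp[s] + 1):(r * nsamp[s])] <- phys
      }
    }
  }

  lut <- montage_1020(63, include_veog = TRUE)
  mi <- match(labels[data_idx], lut$label)
  montage <- data.frame(label = labels[data_idx],
                        x = ifelse(is.na(mi), 0, lut$x[mi]),
                        y = ifelse(is.na(mi), 0, lut$y[mi]),
                        eog = grepl("EOG", labels[data_idx], ignore.case = TRUE),
                        stringsAsFactors = FALSE)
  raw_rec <- raw_recording(X, fs, montage, reference = "as-recorded")

  if (!any(is_ann)) {
    warning("read_edf: file has no annotations; returning an empty event list")
    return(list(raw = raw_rec,
                events = events_from_labels(integer(0), character(0))))
  }
  # TALs: "+onset\x14label\x14\x00"; timestamp TALs have an empty label
  tal_text <- rawToChar(ann_text[ann_text != as.raw(0)])
  tal_list <- regmatches(tal_text,
                         gregexpr("\\+[-0-9.]+\024[^\024]+\024", tal_text))[[1]]
  onsets <- numeric(0); labs <- character(0)
  for (tal in tal_list) {
    parts <- strsplit(tal, "\024")[[1]]
    lab <- parts[2]
    if (!nzchar(lab)) next
    onsets <- c(onsets, as.numeric(sub("^\\+", "", parts[1])))
    labs <- c(labs, lab)
  }
  events <- events_from_labels(as.integer(round(onsets * fs)) + 1L, labs)
  list(raw = raw_rec, events = events)
}

#' Write events as a tab-separated sidecar file
#'
#' Two columns, `sample` and `label`, with the marker grammar
#' `dec:<side>` / `fb:<valence>` / `blk:E=<v>`.
#'
#' @param events An [event_list].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(labels_from_events(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events sidecar TSV
#' @param path TSV path written by [write_events_tsv()].
#' @return An [event_list].
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  events_from_labels(df$sample, df$label)
}
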