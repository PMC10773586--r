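# Minimal EDF/EDF+ codec: 16-bit samples, one header + per-signal headers,
# optional "EDF Annotations" channel holding seizure intervals as TALs.
# Covers what this package writes and reads back; not a general clinical-EDF
# implementation (no discontinuous files, no sub-second start offsets).

edf_pad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF field too long: '", s, "'", call. = FALSE)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits per channel over a symmetric physical
#' range covering the channel's amplitude (so round-trip error is bounded by
#' one quantization step). Seizure annotations can be embedded as an EDF+
#' annotation channel, written to a sidecar text file (`<path>.ann`, one
#' "onset<TAB>offset" pair per line), or dropped.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @param annotations one of "edfplus", "sidecar", "none".
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(recording, path,
                      annotations = c("edfplus", "sidecar", "none")) {
  stopifnot(inherits(recording, "eeg_recording"))
  annotations <- match.arg(annotations)
  samples <- recording$samples
  n_ch <- nrow(samples)
  rate <- recording$rate
  total_s <- ncol(samples) / rate

  if (any(nchar(recording$channel_labels) > 16L)) {
    stop("EDF channel labels are limited to 16 characters: ",
         paste(recording$channel_labels[nchar(recording$channel_labels) > 16L],
               collapse = ", "), call. = FALSE)
  }

  # integral-second recordings use 1 s data records, otherwise a single record
  if (abs(total_s - round(total_s)) < 1e-9) {
    rec_dur <- 1
    n_rec <- as.integer(round(total_s))
  } else {
    rec_dur <- total_s
    n_rec <- 1L
  }
  spr <- as.integer(round(rate * rec_dur))  # samples per record per channel

  # symmetric physical range in whole microvolts, always covering the data
  pm <- pmax(ceiling(apply(abs(samples), 1, max) * 1.001), 1)
  dmin <- -32767L; dmax <- 32767L

  with_ann <- annotations == "edfplus"
  ann <- recording$annotations
  tals <- character(n_rec)
  ann_spr <- 0L
  if (with_ann) {
    # record-keeping TAL per record; all seizure TALs ride in record 1
    tals <- sprintf("+%g\x14\x14", (seq_len(n_rec) - 1) * rec_dur)
    if (nrow(ann) > 0) {
      tals[1] <- paste0(tals[1], paste0(
        sprintf("+%.4f\x15%.4f\x14seizure\x14",
                ann$onset, ann$offset - ann$onset), collapse = ""))
    }
    ann_spr <- as.integer(ceiling((max(nchar(tals, type = "bytes")) + 2) / 2))
  }

  ns <- n_ch + as.integer(with_ann)
  header_bytes <- 256L + 256L * ns

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr(recording$subject_id, 80); wr("eegtda", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr(if (with_ann) "EDF+C" else "", 44)
  wr(n_rec, 8); wr(format(rec_dur, digits = 7), 8); wr(ns, 4)

  labels <- c(recording$channel_labels, if (with_ann) "EDF Annotations")
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr(if (i <= n_ch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) -pm[i] else -1, 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) pm[i] else 1, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefiltering
  for (i in seq_len(ns)) wr(if (i <= n_ch) spr else ann_spr, 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(n_ch)) {
      dig <- round((samples[i, idx] + pm[i]) / (2 * pm[i]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
    if (with_ann) {
      raw_tal <- charToRaw(tals[r])
      writeBin(c(raw_tal, raw(2 * ann_spr - length(raw_tal))), con)
    }
  }

  if (annotations == "sidecar") {
    write_annotations(recording$annotations, paste0(path, ".ann"))
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads signals back to microvolts and recovers seizure annotations from an
#' embedded EDF+ annotation channel, from a sidecar `<path>.ann` file, or
#' neither -- "auto" (the default) prefers the embedded channel, then the
#' sidecar, then none.
#'
#' @param path an EDF file written by [write_edf()] (or any plain
#'   fixed-rate EDF).
#' @param annotations one of "auto", "edfplus", "sidecar", "none".
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, annotations = c("auto", "edfplus", "sidecar",
                                           "none")) {
  annotations <- match.arg(annotations)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))

  rd(8)                                   # version
  subject_id <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)                                  # reserved ("EDF+C" when EDF+)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)

  is_ann <- labels == "EDF Annotations"
  sig <- which(!is_ann)
  out <- lapply(sig, function(i) numeric(n_rec * spr[i]))
  names(out) <- as.character(sig)
  tal_raw <- raw(0)

  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        tal_raw <- c(tal_raw, readBin(con, "raw", 2 * spr[i]))
      } else {
        dig <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
        out[[as.character(i)]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
          (dig - dig_min[i]) * g + phys_min[i]
      }
    }
  }

  samples <- do.call(rbind, out)
  rate <- spr[sig[1]] / rec_dur

  ann <- NULL
  if (annotations %in% c("auto", "edfplus") && any(is_ann)) {
    ann <- parse_tal_annotations(tal_raw)
  }
  sidecar <- paste0(path, ".ann")
  if (is.null(ann) && annotations %in% c("auto", "sidecar") &&
      file.exists(sidecar)) {
    ann <- read_annotations(sidecar)
  }
  if (annotations == "edfplus" && !any(is_ann)) {
    stop("no EDF Annotations channel in ", path, call. = FALSE)
  }

  eeg_recording(samples, rate = rate, channel_labels = labels[sig],
                annotations = ann, subject_id = subject_id)
}

# TAL stream -> data.frame(onset, offset); duration-less (record-keeping)
# TALs are skipped
parse_tal_annotations <- function(tal_raw) {
  txt <- rawToChar(tal_raw[tal_raw != as.raw(0)])
  tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
  onsets <- numeric(0); offsets <- numeric(0)
  for (tal in tals) {
    for (piece in strsplit(tal, "\x14", fixed = TRUE)[[1]]) {
      if (!grepl("\x15", piece)) next
      parts <- strsplit(piece, "\x15", fixed = TRUE)[[1]]
      onset <- as.numeric(parts[1]); dur <- as.numeric(parts[2])
      if (is.finite(onset) && is.finite(dur)) {
        onsets <- c(onsets, onset); offsets <- c(offsets, onset + dur)
      }
    }
  }
  data.frame(onset = onsets, offset = offsets)
}

#' Read and write sidecar annotation files
#'
#' Plain-text seizure intervals: one "onset<TAB>offset" pair per line,
#' seconds from recording start.
#'
#' @param annotations data frame with columns onset, offset.
#' @param path file path.
#' @return `read_annotations()` returns a data.frame(onset, offset);
#'   `write_annotations()` returns `path` invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations)
  utils::write.table(df[, c("onset", "offset")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (file.size(path) == 0) return(data.frame(onset = numeric(0),
                                              offset = numeric(0)))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("onset", "offset"))
  df
}
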