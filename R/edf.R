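# Minimal EDF (European Data Format, 16-bit) codec: standard 256-byte
# header + 256 bytes per signal, then int16 little-endian data records.
# Covers uniform-rate continuous recordings; no annotations, no EDF+ events.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

#' Write a recording as a 16-bit EDF file
#'
#' Samples are scaled to the signal's symmetric physical range and quantized
#' to 16 bits; the whole recording is stored as one data record, so no
#' padding is introduced. Round-tripping reproduces the samples within the
#' quantization step (physical range / 65534).
#'
#' @param recording A [seizure_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "seizure_recording"))
  smp <- recording$samples
  nch <- nrow(smp); n <- ncol(smp)
  con <- file(path, "wb")
  on.exit(close(con))
  dur <- n / recording$sampling_rate_hz
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad(paste("X X X X"), 80L),
    edf_pad(paste("Startdate X X X X", recording$seizure_id), 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (nch + 1L), 8L),
    edf_pad("", 44L),
    edf_pad(1L, 8L),
    edf_pad(format(dur, digits = 8), 8L),
    edf_pad(nch, 4L))
  writeChar(hdr, con, eos = NULL)
  pm <- apply(abs(smp), 1L, max)
  pm[pm == 0] <- 1
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  field(recording$channel_labels, 16L)
  field(rep("", nch), 80L)                       # transducer
  field(rep("uV", nch), 8L)                      # physical dimension
  field(formatC(-pm, format = "g", digits = 6), 8L)
  field(formatC(pm, format = "g", digits = 6), 8L)
  field(rep(-32767L, nch), 8L)
  field(rep(32767L, nch), 8L)
  field(rep("", nch), 80L)                       # prefiltering
  field(rep(n, nch), 8L)                         # samples per record
  field(rep("", nch), 32L)
  for (i in seq_len(nch)) {
    dig <- as.integer(round(smp[i, ] / pm[i] * 32767))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(con, width, n = 1L) {
  trimws(vapply(seq_len(n), function(i) readChar(con, width), character(1)))
}

#' Read a 16-bit EDF file
#'
#' Parses the standard EDF header and data records and returns a
#' [seizure_recording()]. All selected signals must share one sampling
#' rate; malformed numeric header fields fail with the field named.
#'
#' @param path EDF file path.
#' @param channels Optional regular expression; only matching channel
#'   labels are kept. An empty selection is an error.
#' @param seizure_id Identifier for the returned recording (default: file
#'   name without extension).
#' @return A [seizure_recording()].
#' @export
read_edf <- function(path, channels = NULL, seizure_id = NULL) {
  if (!file.exists(path)) stop("read_edf: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  num_field <- function(name, width) {
    raw <- read_edf_field(con, width)
    val <- suppressWarnings(as.numeric(raw))
    if (is.na(val))
      stop("read_edf: malformed header field '", name, "': '", raw, "'")
    val
  }
  read_edf_field(con, 8L)                  # version
  read_edf_field(con, 80L)                 # patient id
  read_edf_field(con, 80L)                 # recording id
  read_edf_field(con, 8L)                  # start date
  read_edf_field(con, 8L)                  # start time
  header_bytes <- num_field("header bytes", 8L)
  read_edf_field(con, 44L)                 # reserved
  n_records <- num_field("number of data records", 8L)
  rec_dur <- num_field("record duration", 8L)
  ns <- as.integer(num_field("number of signals", 4L))
  if (ns < 1L) stop("read_edf: malformed header field 'number of signals'")
  if (header_bytes != 256L * (ns + 1L))
    stop("read_edf: malformed header field 'header bytes' (expected ",
         256L * (ns + 1L), ", got ", header_bytes, ")")
  labels <- read_edf_field(con, 16L, ns)
  read_edf_field(con, 80L, ns)             # transducer
  read_edf_field(con, 8L, ns)              # physical dimension
  pmin_ <- as.numeric(read_edf_field(con, 8L, ns))
  pmax_ <- as.numeric(read_edf_field(con, 8L, ns))
  dmin <- as.numeric(read_edf_field(con, 8L, ns))
  dmax <- as.numeric(read_edf_field(con, 8L, ns))
  if (any(is.na(pmin_)) || any(is.na(pmax_)) || any(is.na(dmin)) ||
      any(is.na(dmax)) || any(dmax <= dmin))
    stop("read_edf: malformed header field 'physical/digital min/max'")
  read_edf_field(con, 80L, ns)             # prefiltering
  spr <- as.integer(read_edf_field(con, 8L, ns))
  if (any(is.na(spr)) || any(spr < 1L))
    stop("read_edf: malformed header field 'samples per record'")
  read_edf_field(con, 32L, ns)
  keep <- seq_len(ns)
  if (!is.null(channels)) {
    keep <- grep(channels, labels)
    if (length(keep) == 0L)
      stop("read_edf: channel selection '", channels,
           "' matches no channel; available: ",
           paste(labels, collapse = ", "))
  }
  if (length(unique(spr[keep])) != 1L)
    stop("read_edf: selected channels have mixed sampling rates (",
         paste(unique(spr[keep]), collapse = ", "), " samples/record)")
  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- numeric(0)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[i])
        stop("read_edf: truncated data record ", r)
      if (i %in% keep) {
        phys <- pmin_[i] + (dig - dmin[i]) *
          (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
        data[[i]] <- c(data[[i]], phys)
      }
    }
  }
  if (is.null(seizure_id))
    seizure_id <- sub("\\.[^.]*$", "", basename(path))
  seizure_recording(do.call(rbind, data[keep]),
                    sampling_rate_hz = spr[keep][1L] / rec_dur,
                    channel_labels = labels[keep],
                    seizure_id = seizure_id)
}

#' Read a seizure recording from disk
#'
#' Adapter around [read_edf()] with channel-subset selection.
#'
#' @param path Path to an EDF file.
#' @param channels Optional regular expression selecting channels.
#' @param seizure_id Optional identifier.
#' @return A [seizure_recording()].
#' @export
read_recording <- function(path, channels = NULL, seizure_id = NULL) {
  read_edf(path, channels = channels, seizure_id = seizure_id)
}
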