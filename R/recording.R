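#' Multichannel seizure recording
#'
#' Container for one seizure's intracranial recording: a channels x
#' timepoints sample matrix (microvolts), its sampling rate, and unique
#' channel labels of the form rod letter(s) + contact number (e.g. `"A1"`,
#' `"TB'12"`). Bipolar channels carry labels like `"A1-A2"`.
#'
#' @param samples Numeric matrix, channels in rows, timepoints in columns.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one unique label per row.
#' @param seizure_id Identifier for the seizure (any scalar).
#' @param onset_sample Optional 1-based sample index of seizure onset.
#' @return An object of class `seizure_recording`.
#' @export
seizure_recording <- function(samples, sampling_rate_hz, channel_labels,
                              seizure_id = "s1", onset_sample = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("seizure_recording: samples must be numeric")
  if (length(sampling_rate_hz) != 1L || !is.finite(sampling_rate_hz) ||
      sampling_rate_hz <= 0)
    stop("seizure_recording: sampling_rate_hz must be a positive scalar")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples))
    stop("seizure_recording: one label per channel required")
  if (anyDuplicated(channel_labels))
    stop("seizure_recording: channel labels must be unique")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate_hz = sampling_rate_hz,
         channel_labels = channel_labels, seizure_id = seizure_id,
         onset_sample = onset_sample),
    class = "seizure_recording")
}

#' @export
print.seizure_recording <- function(x, ...) {
  cat("<seizure_recording> ", x$seizure_id, ": ",
      nrow(x$samples), " channels x ", ncol(x$samples), " samples @ ",
      x$sampling_rate_hz, " Hz\n", sep = "")
  invisible(x)
}

# Split a monopolar label into (rod, contact). Rod is everything before the
# trailing integer, so primed rods like "A'3" parse too.
parse_contact_label <- function(label) {
  m <- regmatches(label, regexec("^(.*?)([0-9]+)$", label))[[1]]
  if (length(m) != 3L || m[2] == "")
    stop("cannot parse channel label into rod + contact: '", label, "'")
  list(rod = m[2], contact = as.integer(m[3]))
}

#' Bipolar derivation along electrode rods
#'
#' References each contact to its closest neighbour on the same rod:
#' output channel `"A1-A2"` holds `A1 - A2`, for every adjacent contact pair
#' (k, k+1) present on a rod. Contacts whose next neighbour is missing
#' produce no channel; they are reported in the `dropped` attribute.
#'
#' @param recording A [seizure_recording()] with monopolar labels such as
#'   `"A1"`.
#' @return A [seizure_recording()] of bipolar channels, ordered by rod (first
#'   appearance) then contact number. Attribute `dropped` lists contacts that
#'   could not be paired.
#' @export
bipolar_derivation <- function(recording) {
  stopifnot(inherits(recording, "seizure_recording"))
  parsed <- lapply(recording$channel_labels, parse_contact_label)
  rods <- vapply(parsed, `[[`, character(1), "rod")
  contacts <- vapply(parsed, `[[`, integer(1), "contact")
  out <- list(); labs <- character(0); dropped <- character(0)
  for (rod in unique(rods)) {
    idx <- which(rods == rod)
    idx <- idx[order(contacts[idx])]
    cc <- contacts[idx]
    for (p in seq_along(idx)) {
      nxt <- match(cc[p] + 1L, cc)
      if (is.na(nxt)) {
        if (p == length(idx)) next    # last contact on rod: expected, silent
        dropped <- c(dropped, recording$channel_labels[idx[p]])
        next
      }
      out[[length(out) + 1L]] <-
        recording$samples[idx[p], ] - recording$samples[idx[nxt], ]
      labs <- c(labs, paste0(rod, cc[p], "-", rod, cc[p] + 1L))
    }
  }
  if (length(out) == 0L)
    stop("bipolar_derivation: no adjacent contact pairs found")
  if (length(dropped))
    warning("bipolar_derivation: dropped contacts without a next neighbour: ",
            paste(dropped, collapse = ", "))
  res <- seizure_recording(do.call(rbind, out), recording$sampling_rate_hz,
                           labs, recording$seizure_id, recording$onset_sample)
  attr(res, "dropped") <- dropped
  res
}

# Butterworth high-pass designed so that the two-pass (forward-backward)
# magnitude is -3 dB at `cutoff_hz`. filtfilt squares the magnitude, so the
# one-pass design point is moved to the frequency where a Butterworth of the
# given order is -1.5 dB, computed through the bilinear prewarp.
design_highpass <- function(cutoff_hz, sampling_rate_hz, order = 4L) {
  nyq <- sampling_rate_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("highpass_filter: cutoff must lie in (0, Nyquist = ", nyq, ") Hz")
  r <- (10^0.15 - 1)^(1 / (2 * order))   # single-pass -1.5 dB point ratio
  w0 <- tan(pi * cutoff_hz / sampling_rate_hz)
  fc <- atan(r * w0) * sampling_rate_hz / pi
  signal::butter(order, fc / nyq, type = "high")
}

#' Zero-phase high-pass filter
#'
#' Applies a zero-phase (forward-backward) Butterworth high-pass so that the
#' overall magnitude response is -3 dB at `cutoff_hz`. The default 20 Hz
#' cutoff emphasises the fast activity characteristic of ictal discharges.
#' Each channel is demeaned and odd-reflection padded before filtering to
#' suppress edge transients.
#'
#' @param recording A [seizure_recording()].
#' @param cutoff_hz -3 dB cutoff in Hz; must be below Nyquist.
#' @param order Butterworth order of the one-pass prototype (default 4).
#' @return Filtered [seizure_recording()] of the same shape.
#' @export
highpass_filter <- function(recording, cutoff_hz = 20, order = 4L) {
  stopifnot(inherits(recording, "seizure_recording"))
  fs <- recording$sampling_rate_hz
  bf <- design_highpass(cutoff_hz, fs, order)
  n <- ncol(recording$samples)
  np <- min(n - 1L, ceiling(12 * fs / cutoff_hz))
  filt <- t(apply(recording$samples, 1L, function(x) {
    x <- x - mean(x)
    ext <- c(2 * x[1L] - x[(np + 1L):2L], x,
             2 * x[n] - x[(n - 1L):(n - np)])
    signal::filtfilt(bf, ext)[(np + 1L):(np + n)]
  }))
  seizure_recording(filt, fs, recording$channel_labels,
                    recording$seizure_id, recording$onset_sample)
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase by the Hilbert transform
#'
#' Computes the phase of the analytic signal of each channel, wrapped to
#' (-pi, pi]. All-zero channels have no defined phase; they are returned as
#' zeros and listed in the `degenerate_channels` attribute (with a warning).
#'
#' @param recording A [seizure_recording()] with at least 16 timepoints.
#' @return An object of class `phase_series` with fields `phases`
#'   (channels x timepoints, radians), `sampling_rate_hz` and
#'   `channel_labels`.
#' @export
instantaneous_phase <- function(recording) {
  stopifnot(inherits(recording, "seizure_recording"))
  if (ncol(recording$samples) < 16L)
    stop("instantaneous_phase: need at least 16 timepoints")
  degenerate <- character(0)
  ph <- t(apply(recording$samples, 1L, function(x) {
    if (all(x == 0)) return(rep(0, length(x)))
    Arg(analytic_signal(x))
  }))
  zero <- apply(recording$samples == 0, 1L, all)
  if (any(zero)) {
    degenerate <- recording$channel_labels[zero]
    warning("instantaneous_phase: all-zero channel(s), phase set to 0: ",
            paste(degenerate, collapse = ", "))
  }
  rownames(ph) <- recording$channel_labels
  structure(
    list(phases = ph, sampling_rate_hz = recording$sampling_rate_hz,
         channel_labels = recording$channel_labels,
         degenerate_channels = degenerate),
    class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat("<phase_series> ", nrow(x$phases), " channels x ", ncol(x$phases),
      " samples @ ", x$sampling_rate_hz, " Hz\n", sep = "")
  invisible(x)
}
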