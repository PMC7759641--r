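#' Phase locking value of two phase sequences
#'
#' The PLV is the modulus of the time average of the unit phasor of the
#' relative phase, `| mean(exp(i (a - b))) |`. It equals 1 for perfectly
#' locked phases and approaches 0 for a uniform relative phase. Symmetric in
#' its arguments and invariant to adding a common phase sequence to both.
#'
#' @param phase_a,phase_b Numeric vectors of phases (radians), equal length.
#' @return A scalar in \[0, 1\].
#' @export
plv_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b))
    stop("plv_pair: phase sequences must have equal length")
  if (length(phase_a) == 0L) stop("plv_pair: empty phase sequences")
  d <- phase_a - phase_b
  min(1, sqrt(mean(cos(d))^2 + mean(sin(d))^2))
}

#' Sliding analysis windows
#'
#' Half-open sample ranges `[start, end)` anchored at the signal start and
#' advancing by the step; the last window is the last one that fits entirely
#' inside the signal, so the window count is
#' `floor((n_samples - W) / D) + 1` with `W`, `D` in samples.
#'
#' @param n_samples Total number of samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param window_length_s Window length in seconds (default 4).
#' @param window_step_s Step between window starts in seconds (default 1).
#' @return Data frame with 0-based `start`, exclusive `end` (in samples) and
#'   `start_s` (window start time in seconds); one row per window.
#' @examples
#' nrow(sliding_windows(64 * 256, 256))  # 61 windows of 4 s stepping 1 s
#' @export
sliding_windows <- function(n_samples, sampling_rate_hz,
                            window_length_s = 4, window_step_s = 1) {
  W <- round(window_length_s * sampling_rate_hz)
  D <- round(window_step_s * sampling_rate_hz)
  if (W < 1L || D < 1L)
    stop("sliding_windows: window and step must be at least one sample")
  if (n_samples < W)
    stop("sliding_windows: signal (", n_samples,
         " samples) shorter than one window (", W, " samples)")
  starts <- seq.int(0L, n_samples - W, by = D)
  data.frame(start = starts, end = starts + W,
             start_s = starts / sampling_rate_hz)
}

#' Windowed connectivity matrix for one seizure
#'
#' An L x T matrix of edgewise PLV values: row `l` is one channel pair (see
#' [edge_index()]), column `t` one analysis window.
#'
#' @param values Numeric L x T matrix with entries in \[0, 1\].
#' @param edge_index An [edge_index()] with `L` pairs.
#' @param window_length_s,window_step_s Window parameters (seconds).
#' @param seizure_id Identifier.
#' @param window_start_s Optional window start times (length T, seconds).
#' @return An object of class `fc_series`.
#' @export
fc_series <- function(values, edge_index, window_length_s = 4,
                      window_step_s = 1, seizure_id = "s1",
                      window_start_s = NULL) {
  values <- as.matrix(values)
  stopifnot(inherits(edge_index, "edge_index"))
  if (nrow(values) != edge_index$L)
    stop("fc_series: values must have one row per edge (L = ",
         edge_index$L, ")")
  if (ncol(values) < 1L) stop("fc_series: need at least one window")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("fc_series: values must be finite and in [0, 1]")
  if (is.null(window_start_s))
    window_start_s <- (seq_len(ncol(values)) - 1L) * window_step_s
  structure(
    list(values = values, edge_index = edge_index,
         window_length_s = window_length_s, window_step_s = window_step_s,
         seizure_id = seizure_id, window_start_s = window_start_s),
    class = "fc_series")
}

#' @export
print.fc_series <- function(x, ...) {
  cat("<fc_series> ", x$seizure_id, ": ", nrow(x$values), " edges x ",
      ncol(x$values), " windows (", x$window_length_s, " s / ",
      x$window_step_s, " s)\n", sep = "")
  invisible(x)
}

#' Multi-seizure dataset
#'
#' A list of [fc_series()] objects for the same patient sharing one edge
#' index (same channels, different seizure durations).
#'
#' @param seizures List of [fc_series()] objects.
#' @return An object of class `multi_seizure_dataset` with fields `seizures`,
#'   `S`, `edge_index`.
#' @export
multi_seizure_dataset <- function(seizures) {
  if (inherits(seizures, "fc_series")) seizures <- list(seizures)
  if (length(seizures) < 1L)
    stop("multi_seizure_dataset: need at least one seizure")
  stopifnot(all(vapply(seizures, inherits, logical(1), "fc_series")))
  ref <- seizures[[1L]]$edge_index
  same <- vapply(seizures, function(s)
    identical(s$edge_index$pairs, ref$pairs), logical(1))
  if (!all(same))
    stop("multi_seizure_dataset: all seizures must share one edge index")
  structure(list(seizures = seizures, S = length(seizures), edge_index = ref),
            class = "multi_seizure_dataset")
}

#' @export
print.multi_seizure_dataset <- function(x, ...) {
  cat("<multi_seizure_dataset> S = ", x$S, " seizures, L = ",
      x$edge_index$L, " edges, T = (",
      paste(vapply(x$seizures, function(s) ncol(s$values), integer(1)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# durations T(s) of a multi_seizure_dataset
dataset_durations <- function(X)
  vapply(X$seizures, function(s) ncol(s$values), integer(1))

#' Windowed PLV connectivity series from a recording
#'
#' Computes the instantaneous phase of every channel, then for each sliding
#' window the PLV of every channel pair, giving the L x T connectivity
#' matrix of one seizure. The recording is expected to be already
#' re-referenced (e.g. [bipolar_derivation()]) and filtered
#' ([highpass_filter()]); [estimate_fc()] chains those steps.
#'
#' @param recording A [seizure_recording()].
#' @param window_length_s,window_step_s Window length and step (seconds;
#'   defaults 4 and 1).
#' @return An [fc_series()].
#' @export
build_fc_series <- function(recording, window_length_s = 4,
                            window_step_s = 1) {
  stopifnot(inherits(recording, "seizure_recording"))
  ph <- instantaneous_phase(recording)$phases
  win <- sliding_windows(ncol(ph), recording$sampling_rate_hz,
                         window_length_s, window_step_s)
  ei <- edge_index(nrow(ph), recording$channel_labels)
  Tn <- nrow(win)
  # accumulate the mean unit phasor per edge and window in one pass
  vals <- matrix(0, ei$L, Tn)
  for (t in seq_len(Tn)) {
    seg <- ph[, (win$start[t] + 1L):win$end[t], drop = FALSE]
    Z <- exp(1i * seg)
    M <- tcrossprod(Z, Conj(Z)) / ncol(seg)   # [i,j] = mean e^{i(phi_i-phi_j)}
    vals[, t] <- pmin(1, Mod(M[ei$pairs]))
  }
  fc_series(vals, ei, window_length_s, window_step_s,
            recording$seizure_id, win$start_s)
}

#' Full connectivity pipeline for one recording
#'
#' Convenience wrapper chaining bipolar derivation (optional), zero-phase
#' high-pass filtering and windowed PLV estimation.
#'
#' @param recording A [seizure_recording()] with monopolar labels (or
#'   already-derived channels if `montage = "none"`).
#' @param montage `"bipolar"` (default) or `"none"`.
#' @param highpass_hz High-pass -3 dB cutoff in Hz (default 20).
#' @param window_length_s,window_step_s Window parameters (defaults 4 s, 1 s).
#' @return An [fc_series()].
#' @export
estimate_fc <- function(recording, montage = c("bipolar", "none"),
                        highpass_hz = 20, window_length_s = 4,
                        window_step_s = 1) {
  montage <- match.arg(montage)
  if (montage == "bipolar") recording <- bipolar_derivation(recording)
  recording <- highpass_filter(recording, highpass_hz)
  build_fc_series(recording, window_length_s, window_step_s)
}
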