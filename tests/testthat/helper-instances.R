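# Small random problem instances built in code (no fixture files).

# multi-seizure dataset of i.i.d. uniform PLV-like values
random_dataset <- function(n_nodes, durations, seed) {
  set.seed(seed)
  ei <- edge_index(n_nodes)
  multi_seizure_dataset(lapply(seq_along(durations), function(s)
    fc_series(matrix(runif(ei$L * durations[s]), ei$L, durations[s]),
              ei, seizure_id = paste0("s", s))))
}

# monopolar sinusoid recording on labelled rods
sine_recording <- function(labels, freqs_hz, fs = 256, dur_s = 4,
                           phases = 0, id = "s1") {
  tt <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  freqs_hz <- rep_len(freqs_hz, length(labels))
  phases <- rep_len(phases, length(labels))
  smp <- t(vapply(seq_along(labels),
                  function(i) cos(2 * pi * freqs_hz[i] * tt + phases[i]),
                  numeric(length(tt))))
  seizure_recording(smp, fs, labels, id)
}

# independent evaluation of the fused-lasso functional, term by term
constraint_oracle <- function(v, gamma, eta) {
  acc <- 0
  for (t in seq_along(v)) acc <- acc + gamma * abs(v[t])
  if (length(v) > 1)
    for (t in seq_len(length(v) - 1)) acc <- acc + eta * abs(v[t + 1] - v[t])
  for (t in seq_along(v)) acc <- acc + v[t]^2
  acc
}

# naive double-loop evaluation of the joint objective
objective_oracle <- function(F, V, Xlist, zeta, lambda) {
  S <- length(Xlist)
  acc <- 0
  for (s in seq_len(S)) {
    R <- Xlist[[s]] - F %*% t(V[[s]])
    for (l in seq_len(nrow(R))) for (t in seq_len(ncol(R)))
      acc <- acc + zeta[s] * R[l, t]^2
  }
  pen <- 0
  for (k in seq_len(ncol(F))) for (l in seq_len(nrow(F)))
    pen <- pen + abs(F[l, k])
  acc + lambda / S * pen
}
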