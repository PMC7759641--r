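#' Planted low-rank connectivity dataset
#'
#' Generates per-seizure connectivity matrices from a known model:
#' `X{s} = clip(F_true V_true{s}^t + noise, 0, 1)`, with one shared sparse
#' non-negative subgraph factor `F_true` (each column supported on a random
#' `edge_sparsity` fraction of edges, weights uniform on (0.3, 1)) and
#' per-seizure boxcar activations (one contiguous support interval per
#' component and seizure, random onset and length, height 1). Noise is
#' additive Gaussian, then clipped to the PLV range \[0, 1\].
#'
#' @param n_nodes Number of channels (>= 3); edges L = n_nodes(n_nodes-1)/2.
#' @param K Number of planted subgraphs (1 <= K <= L).
#' @param durations Integer vector of window counts T(s), one per seizure,
#'   all >= 2.
#' @param edge_sparsity Fraction of edges active per subgraph (0 < f <= 1).
#' @param noise_sigma Standard deviation of the additive noise (>= 0).
#' @param seed Integer seed; generation is reproducible bit-for-bit.
#' @return List with elements `dataset` (a [multi_seizure_dataset()]) and
#'   `truth` (a `planted_model`: `true_subgraphs`, `true_activations`,
#'   `supports` (per seizure x component `[start, end]` window interval),
#'   `noise_sigma`, `seed`, `zero_row_fraction`).
#' @export
generate_planted_dataset <- function(n_nodes, K, durations,
                                     edge_sparsity = 0.1,
                                     noise_sigma = 0.05, seed = 1L) {
  if (n_nodes < 3L) stop("generate_planted_dataset: n_nodes >= 3 required")
  if (K < 1L) stop("generate_planted_dataset: K >= 1 required")
  if (any(durations < 2L))
    stop("generate_planted_dataset: every duration must be >= 2")
  if (edge_sparsity <= 0 || edge_sparsity > 1)
    stop("generate_planted_dataset: edge_sparsity in (0, 1] required")
  if (noise_sigma < 0)
    stop("generate_planted_dataset: noise_sigma >= 0 required")
  ei <- edge_index(n_nodes)
  L <- ei$L
  if (K > L) stop("generate_planted_dataset: K must not exceed L = ", L)
  n_active <- max(1L, round(edge_sparsity * L))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  Fm <- matrix(0, L, K)
  for (k in seq_len(K)) {
    idx <- sample.int(L, n_active)
    Fm[idx, k] <- stats::runif(n_active, 0.3, 1)
  }
  S <- length(durations)
  draw_support <- function(Ts) {
    len <- max(1L, round(stats::runif(1, 0.2, 0.6) * Ts))
    onset <- sample.int(Ts - len + 1L, 1L)
    c(onset, onset + len - 1L)
  }
  supports <- vector("list", S)
  V <- vector("list", S)
  for (s in seq_len(S)) {
    Ts <- durations[s]
    sup <- matrix(0L, K, 2L, dimnames = list(NULL, c("start", "end")))
    Vm <- matrix(0, Ts, K)
    for (k in seq_len(K)) {
      iv <- draw_support(Ts)
      if (s > 1L) {   # supports must differ across seizures
        tries <- 0L
        while (identical(iv, supports[[s - 1L]][k, , drop = TRUE]) &&
               tries < 10L) {
          iv <- draw_support(Ts); tries <- tries + 1L
        }
      }
      sup[k, ] <- iv
      Vm[iv[1L]:iv[2L], k] <- 1
    }
    supports[[s]] <- sup
    V[[s]] <- Vm
  }
  # keep the clean product inside the PLV range: where components overlap on
  # one edge their superposition may exceed 1, so rescale F once globally
  peak <- max(vapply(V, function(Vm) max(Fm %*% t(Vm)), numeric(1)))
  if (peak > 1) Fm <- Fm / peak
  seizures <- vector("list", S)
  for (s in seq_len(S)) {
    Xs <- Fm %*% t(V[[s]])
    if (noise_sigma > 0)
      Xs <- Xs + matrix(stats::rnorm(length(Xs), 0, noise_sigma),
                        nrow(Xs), ncol(Xs))
    Xs <- pmin(pmax(Xs, 0), 1)
    seizures[[s]] <- fc_series(Xs, ei, seizure_id = paste0("s", s))
  }
  truth <- structure(
    list(true_subgraphs = Fm, true_activations = V, supports = supports,
         noise_sigma = noise_sigma, seed = as.integer(seed),
         zero_row_fraction = mean(rowSums(Fm) == 0)),
    class = "planted_model")
  list(dataset = multi_seizure_dataset(seizures), truth = truth)
}

#' Phase-coupling schedule for synthetic oscillatory signals
#'
#' Declares which channel groups share a common phase during which time
#' intervals, the within-group phase-noise concentration, and the carrier
#' frequency.
#'
#' @param groups List of integer vectors of channel indices.
#' @param intervals List over seizures; each element a list (one per group)
#'   of two-column matrices of `[start_s, end_s)` intervals in seconds (zero
#'   rows = that group never couples in that seizure).
#' @param coupling_strength Phase-noise concentration (>= 0); per-channel
#'   phase jitter inside a coupled interval has standard deviation
#'   `1 / sqrt(coupling_strength)` radians (`Inf` = perfect locking).
#' @param carrier_hz Oscillation frequency in Hz; should lie above the
#'   analysis high-pass cutoff.
#' @return An object of class `coupling_schedule`.
#' @export
coupling_schedule <- function(groups, intervals, coupling_strength = 50,
                              carrier_hz = 40) {
  if (coupling_strength < 0)
    stop("coupling_schedule: coupling_strength >= 0 required")
  if (carrier_hz <= 0) stop("coupling_schedule: carrier_hz > 0 required")
  structure(list(groups = groups, intervals = intervals,
                 coupling_strength = coupling_strength,
                 carrier_hz = carrier_hz),
            class = "coupling_schedule")
}

#' Synthetic phase-coupled oscillatory recordings
#'
#' Each channel carries a cosine at the schedule's carrier frequency whose
#' phase follows a random walk. During a group's coupled intervals, member
#' channels share the group's common phase walk plus small independent
#' jitter (standard deviation `1/sqrt(coupling_strength)`); elsewhere each
#' channel follows its own independent walk, so between-channel PLV is high
#' exactly when and where the schedule says so.
#'
#' @param schedule A [coupling_schedule()].
#' @param n_channels Number of channels.
#' @param sampling_rate_hz Sampling rate (>= 4 x carrier).
#' @param durations_s Numeric vector of seizure durations in seconds.
#' @param seed Integer seed.
#' @param channel_labels Optional labels (default contacts `C1..Cn` on one
#'   rod, so bipolar derivation is well-defined).
#' @param phase_diffusion Per-sample standard deviation of the phase walks
#'   (radians; default 0.4 -- phases decorrelate well within one analysis window).
#' @return List of [seizure_recording()] objects, one per duration.
#' @export
generate_phase_locked_signals <- function(schedule, n_channels,
                                          sampling_rate_hz, durations_s,
                                          seed = 1L, channel_labels = NULL,
                                          phase_diffusion = 0.4) {
  stopifnot(inherits(schedule, "coupling_schedule"))
  if (sampling_rate_hz < 4 * schedule$carrier_hz)
    stop("generate_phase_locked_signals: sampling rate must be >= 4x carrier")
  idx_all <- unlist(schedule$groups, use.names = FALSE)
  if (length(idx_all) && max(idx_all) > n_channels)
    stop("generate_phase_locked_signals: group index exceeds n_channels")
  if (is.null(channel_labels))
    channel_labels <- paste0("C", seq_len(n_channels))
  sigma_j <- if (is.infinite(schedule$coupling_strength)) 0 else
    if (schedule$coupling_strength == 0) Inf else
      1 / sqrt(schedule$coupling_strength)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  nG <- length(schedule$groups)
  out <- vector("list", length(durations_s))
  for (s in seq_along(durations_s)) {
    n <- round(durations_s[s] * sampling_rate_hz)
    tt <- (seq_len(n) - 1L) / sampling_rate_hz
    carrier <- 2 * pi * schedule$carrier_hz * tt
    own <- matrix(stats::rnorm(n_channels * n, 0, phase_diffusion),
                  n_channels, n)
    own <- t(apply(own, 1L, cumsum))
    common <- if (nG)
      t(apply(matrix(stats::rnorm(nG * n, 0, phase_diffusion), nG, n),
              1L, cumsum)) else matrix(0, 0, n)
    # membership[i, t] = first group coupling channel i at sample t, else 0
    member <- matrix(0L, n_channels, n)
    if (length(schedule$intervals) >= s) {
      ivs <- schedule$intervals[[s]]
      for (g in seq_len(nG)) {
        if (length(ivs) < g || is.null(ivs[[g]])) next
        iv <- ivs[[g]]
        if (is.null(dim(iv))) iv <- matrix(iv, ncol = 2L)
        for (r in seq_len(nrow(iv))) {
          if (iv[r, 1L] < 0 || iv[r, 2L] > durations_s[s] + 1e-9)
            stop("coupling interval outside seizure duration")
          a <- floor(iv[r, 1L] * sampling_rate_hz) + 1L
          b <- min(n, ceiling(iv[r, 2L] * sampling_rate_hz))
          for (i in schedule$groups[[g]]) {
            sel <- a:b
            sel <- sel[member[i, sel] == 0L]
            member[i, sel] <- g
          }
        }
      }
    }
    phases <- matrix(0, n_channels, n)
    for (i in seq_len(n_channels)) {
      ph <- own[i, ]
      m <- member[i, ]
      if (any(m > 0L)) {
        jit <- if (sigma_j == 0) 0 else
          if (is.infinite(sigma_j)) stats::runif(n, -pi, pi) else
            stats::rnorm(n, 0, sigma_j)
        coupled <- m > 0L
        ph[coupled] <- common[cbind(m[coupled], which(coupled))] +
          (if (length(jit) == 1L) jit else jit[coupled])
      }
      phases[i, ] <- carrier + ph
    }
    out[[s]] <- seizure_recording(cos(phases), sampling_rate_hz,
                                  channel_labels,
                                  seizure_id = paste0("s", s))
  }
  out
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Exact one-to-one assignment of the rows of `score` (small side) to
# distinct columns, maximizing the total, by bitmask dynamic programming.
# Requires nrow(score) <= ncol(score) <= ~15.
dp_assign <- function(score) {
  n_small <- nrow(score); n_big <- ncol(score)
  nmask <- bitwShiftL(1L, n_big)
  dp <- matrix(-Inf, n_small + 1L, nmask)
  dp[1L, 1L] <- 0
  choice <- matrix(NA_integer_, n_small, nmask)
  for (i in seq_len(n_small)) {
    for (mask in which(is.finite(dp[i, ])) - 1L) {
      base <- dp[i, mask + 1L]
      for (j in seq_len(n_big)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) > 0L) next
        nm <- bitwOr(mask, bit) + 1L
        val <- base + score[i, j]
        if (val > dp[i + 1L, nm]) {
          dp[i + 1L, nm] <- val
          choice[i, nm] <- j
        }
      }
    }
  }
  best_mask <- which.max(dp[n_small + 1L, ]) - 1L
  res <- integer(n_small)
  mask <- best_mask
  for (i in n_small:1L) {
    j <- choice[i, mask + 1L]
    res[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  res
}

# Optimal matching: returns, per row of `score`, the matched column index
# (NA for rows left unmatched when there are more rows than columns).
optimal_assignment <- function(score) {
  n1 <- nrow(score); n2 <- ncol(score)
  if (n1 <= n2) {
    dp_assign(score)
  } else {
    cols_to_rows <- dp_assign(t(score))   # per column, its matched row
    res <- rep(NA_integer_, n1)
    res[cols_to_rows] <- seq_len(n2)
    res
  }
}

#' Recovery metrics of a fit against a planted model
#'
#' Matches estimated components to planted ones by the exact one-to-one
#' assignment maximizing summed cosine similarity between subgraph columns,
#' then reports, per planted component: subgraph cosine similarity,
#' activation cosine similarity (activations concatenated over seizures) and
#' the Jaccard overlap between the planted support and the windows where the
#' estimated activation exceeds `activity_threshold` of its maximum.
#' Planted components left unmatched (when the fit has fewer components)
#' score 0. Metrics are invariant to column permutation and to positive
#' per-component rescaling split between the factors.
#'
#' @param fit A `btnd_decomposition`, or a list with elements `F` (L x K)
#'   and `V` (list of T(s) x K matrices).
#' @param truth A `planted_model` from [generate_planted_dataset()].
#' @param activity_threshold Fraction of the column maximum above which an
#'   estimated activation is called active (default 0.2).
#' @return An object of class `recovery_report`: `matching` (estimated
#'   component per planted component, NA when unmatched), `subgraph_cosine`,
#'   `activation_cosine`, `support_jaccard` (per planted component) and
#'   their means (`mean_subgraph_cosine`, `mean_activation_cosine`,
#'   `mean_support_jaccard`).
#' @export
recovery_report <- function(fit, truth, activity_threshold = 0.2) {
  stopifnot(inherits(truth, "planted_model"))
  if (inherits(fit, "btnd_decomposition")) {
    F_hat <- fit$subgraphs$weights
    V_hat <- lapply(fit$activations, function(a) a$values)
  } else {
    F_hat <- as.matrix(fit$F)
    V_hat <- lapply(fit$V, as.matrix)
  }
  F_true <- truth$true_subgraphs
  V_true <- truth$true_activations
  if (nrow(F_hat) != nrow(F_true))
    stop("recovery_report: fit and truth disagree on the number of edges")
  if (length(V_hat) != length(V_true) ||
      !all(vapply(V_hat, nrow, integer(1)) ==
             vapply(V_true, nrow, integer(1))))
    stop("recovery_report: fit and truth disagree on seizure durations")
  K_true <- ncol(F_true); K_hat <- ncol(F_hat)
  score <- matrix(0, K_true, K_hat)
  for (i in seq_len(K_true)) for (j in seq_len(K_hat))
    score[i, j] <- cosine_sim(F_true[, i], F_hat[, j])
  matching <- optimal_assignment(score)
  cat_true <- do.call(rbind, V_true)
  cat_hat <- do.call(rbind, V_hat)
  sg <- act <- jac <- numeric(K_true)
  for (i in seq_len(K_true)) {
    j <- matching[i]
    if (is.na(j)) next
    sg[i] <- score[i, j]
    act[i] <- cosine_sim(cat_true[, i], cat_hat[, j])
    true_on <- cat_true[, i] > 0
    mx <- max(cat_hat[, j])
    est_on <- if (mx > 0) cat_hat[, j] >= activity_threshold * mx else
      rep(FALSE, length(true_on))
    u <- sum(true_on | est_on)
    jac[i] <- if (u == 0) 0 else sum(true_on & est_on) / u
  }
  structure(
    list(matching = matching, subgraph_cosine = sg,
         activation_cosine = act, support_jaccard = jac,
         mean_subgraph_cosine = mean(sg),
         mean_activation_cosine = mean(act),
         mean_support_jaccard = mean(jac),
         activity_threshold = activity_threshold),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> mean subgraph cosine = ",
      round(x$mean_subgraph_cosine, 3),
      ", mean activation cosine = ", round(x$mean_activation_cosine, 3),
      ", mean support Jaccard = ", round(x$mean_support_jaccard, 3), "\n",
      sep = "")
  invisible(x)
}
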