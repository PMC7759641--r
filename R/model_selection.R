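#' Fraction of edges active in the subgraph factor
#'
#' An edge counts as active when it has a nonzero weight in at least one
#' component of the (un-normalized) subgraph factor. This is the density
#' that [tune_lambda()] drives to its target.
#'
#' @param F A [subgraph_set()] or L x K matrix.
#' @return Scalar in \[0, 1\].
#' @export
edge_density <- function(F) {
  Fm <- as_factor_matrix(F)
  mean(rowSums(Fm != 0) > 0)
}

#' Tune the sparsity weight to a target edge density
#'
#' Bisects `lambda` (with `gamma = lambda`, the default coupling) between 0
#' and an instance-specific upper bound guaranteed to empty the subgraph
#' factor, refitting at each step with a fixed seed, until the fraction of
#' edges retained in at least one subgraph lies within `tol` of
#' `target_density` or `max_steps` bisections have elapsed (then the
#' closest-achieving fit is returned). The default target of 0.20 keeps the
#' 20% most resilient connections.
#'
#' @param X A [multi_seizure_dataset()].
#' @param config A [btnd_config()]; its `lambda`/`gamma` are overridden.
#' @param target_density Target fraction of active edges (default 0.2).
#' @param tol Acceptable deviation from the target (default 0.05).
#' @param max_steps Maximum bisection steps (default 20).
#' @return List of class `lambda_tuning`: `lambda`, `fit` (the
#'   `btnd_decomposition` at that `lambda`), `density`, and `trace`
#'   (data frame of visited `lambda` / `density`, in visit order).
#' @export
tune_lambda <- function(X, config, target_density = 0.2, tol = 0.05,
                        max_steps = 20L) {
  if (target_density <= 0 || target_density >= 1)
    stop("tune_lambda: target_density must lie in (0, 1)")
  config <- resolve_config(config, X)
  # upper bound from the gradient of the fit term at F = 0: with every
  # activation column inside the unit l2 ball, |(X V)_lk| <= ||X[l, ]||_2,
  # so lambda >= 2 S max_l sum_s zeta_s ||X_s[l, ]|| zeroes F.
  row_bound <- rowSums(vapply(
    seq_len(X$S),
    function(s) config$zeta[s] *
      sqrt(rowSums(X$seizures[[s]]$values^2)),
    numeric(X$edge_index$L)))
  lam_hi <- 2 * X$S * max(row_bound)
  if (lam_hi <= 0) stop("tune_lambda: degenerate all-zero dataset")
  fit_at <- function(lam) {
    cfg <- config
    cfg$lambda <- lam
    cfg$base_fused <- fused_lasso_params(gamma = lam, eta = config$base_fused$eta)
    cfg$per_seizure_fused <- adapt_fused_params(cfg$base_fused,
                                                dataset_durations(X))
    btnd_fit(X, cfg)
  }
  lam_lo <- 0
  trace <- data.frame(lambda = numeric(0), density = numeric(0))
  best <- NULL
  for (step in seq_len(max_steps)) {
    lam <- (lam_lo + lam_hi) / 2
    f <- fit_at(lam)
    d <- edge_density(f$subgraphs)
    trace <- rbind(trace, data.frame(lambda = lam, density = d))
    if (is.null(best) ||
        abs(d - target_density) < abs(best$density - target_density))
      best <- list(lambda = lam, fit = f, density = d)
    if (abs(d - target_density) <= tol) break
    if (d > target_density) lam_lo <- lam else lam_hi <- lam
  }
  structure(c(best, list(trace = trace, target_density = target_density)),
            class = "lambda_tuning")
}

#' @export
print.lambda_tuning <- function(x, ...) {
  cat("<lambda_tuning> lambda = ", format(x$lambda, digits = 4),
      ", achieved density = ", round(x$density, 3),
      " (target ", x$target_density, ", ", nrow(x$trace), " steps)\n",
      sep = "")
  invisible(x)
}

#' Sweep the number of subgraphs
#'
#' Fits the decomposition for each K in `k_min:k_max` (defaults 3 to 10)
#' with the same restart budget and records the weighted relative
#' reconstruction error; [elbow_select()] then picks the model order at the
#' error curve's elbow. K values whose fit fails are skipped with a warning.
#'
#' @param X A [multi_seizure_dataset()].
#' @param config A [btnd_config()]; its `K` is overridden.
#' @param k_min,k_max Range of K to explore (defaults 3 and 10).
#' @return An object of class `ksweep_result`: `k_values`, `errors`,
#'   `decompositions` (per K), `selected_k`.
#' @export
sweep_k <- function(X, config, k_min = 3L, k_max = 10L) {
  if (k_min < 1L) stop("sweep_k: k_min >= 1 required")
  if (k_max > edge_index_L(X)) stop("sweep_k: k_max must not exceed L")
  if (k_max < k_min) stop("sweep_k: k_max >= k_min required")
  ks <- seq.int(k_min, k_max)
  fits <- vector("list", length(ks))
  errs <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    cfg <- config
    cfg$K <- ks[i]
    res <- tryCatch(btnd_fit(X, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      warning("sweep_k: fit failed for K = ", ks[i], ": ",
              conditionMessage(res))
      next
    }
    fits[[i]] <- res
    errs[i] <- relative_error(res, X)
  }
  keep <- !is.na(errs)
  if (sum(keep) < 3L) stop("sweep_k: fewer than 3 successful fits")
  ks <- ks[keep]; errs <- errs[keep]; fits <- fits[keep]
  structure(
    list(k_values = ks, errors = errs, decompositions = fits,
         selected_k = elbow_select(ks, errs)),
    class = "ksweep_result")
}

edge_index_L <- function(X) X$edge_index$L

#' @export
print.ksweep_result <- function(x, ...) {
  cat("<ksweep_result> K in ", min(x$k_values), "..", max(x$k_values),
      ", selected K = ", x$selected_k, "\n", sep = "")
  print(data.frame(K = x$k_values, error = round(x$errors, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Elbow selection on an error-versus-K curve
#'
#' Picks the K whose point lies farthest (perpendicular distance) from the
#' chord joining the first and last points of the curve, after min-max
#' normalization of both axes -- a parameter-free, rescaling-invariant
#' reading of the usual visual elbow. Ties go to the smaller K; a
#' monotonically non-decreasing error curve has no elbow and returns
#' `k_min` with a warning.
#'
#' @param k_values Increasing vector of K (length >= 3).
#' @param errors Corresponding reconstruction errors.
#' @return The selected K.
#' @export
elbow_select <- function(k_values, errors) {
  n <- length(k_values)
  if (n < 3L) stop("elbow_select: need at least 3 points")
  if (length(errors) != n) stop("elbow_select: length mismatch")
  if (is.unsorted(k_values, strictly = TRUE))
    stop("elbow_select: k_values must be strictly increasing")
  if (all(diff(errors) >= 0)) {
    warning("elbow_select: errors never decrease; no elbow, returning k_min")
    return(k_values[1L])
  }
  x <- (k_values - k_values[1L]) / (k_values[n] - k_values[1L])
  rng <- max(errors) - min(errors)
  y <- if (rng > 0) (errors - min(errors)) / rng else rep(0, n)
  # distance from (x, y) to the chord (x1,y1)-(xn,yn)
  dx <- x[n] - x[1L]; dy <- y[n] - y[1L]
  d <- abs(dy * x - dx * y + x[n] * y[1L] - y[n] * x[1L]) /
    sqrt(dx^2 + dy^2)
  if (max(d) < 1e-9) {
    warning("elbow_select: error curve is linear; no elbow, returning k_min")
    return(k_values[1L])
  }
  k_values[which(d >= max(d) - 1e-9)[1L]]
}

#' Normalize and threshold the subgraph factor
#'
#' Divides each nonzero column by its maximum (so connectivity strengths lie
#' in \[0, 1\]) and zeroes entries below `threshold` (default 0.2) to drop
#' non-significant interactions. Idempotent. All-zero components are kept
#' as zeros and flagged.
#'
#' @param F A [subgraph_set()] (or L x K matrix).
#' @param threshold Retention threshold on the normalized scale
#'   (0 <= threshold < 1, default 0.2).
#' @return An object of class `subgraph_report`: `normalized_weights`
#'   (L x K, thresholded), `retained_edges` (per component, a data frame of
#'   edge endpoints and weights in descending order), `zero_components`,
#'   `threshold` and the `edge_index` when available.
#' @export
normalize_and_threshold <- function(F, threshold = 0.2) {
  if (threshold < 0 || threshold >= 1)
    stop("normalize_and_threshold: threshold in [0, 1) required")
  Fm <- as_factor_matrix(F)
  ei <- if (inherits(F, "subgraph_set")) F$edge_index else NULL
  K <- ncol(Fm)
  zero_components <- integer(0)
  W <- Fm
  for (k in seq_len(K)) {
    mx <- max(Fm[, k])
    if (mx == 0) {
      zero_components <- c(zero_components, k)
      next
    }
    wk <- Fm[, k] / mx
    wk[wk < threshold] <- 0
    W[, k] <- wk
  }
  labels <- if (!is.null(ei)) edge_labels(ei) else
    paste0("e", seq_len(nrow(Fm)))
  retained <- lapply(seq_len(K), function(k) {
    idx <- which(W[, k] > 0)
    idx <- idx[order(W[idx, k], decreasing = TRUE)]
    data.frame(edge = idx, label = labels[idx], weight = W[idx, k],
               row.names = NULL)
  })
  structure(
    list(normalized_weights = W, retained_edges = retained,
         zero_components = zero_components, threshold = threshold,
         edge_index = ei),
    class = "subgraph_report")
}

#' @export
print.subgraph_report <- function(x, ...) {
  cat("<subgraph_report> ", ncol(x$normalized_weights),
      " components, threshold ", x$threshold, "; retained edges per ",
      "component: ",
      paste(vapply(x$retained_edges, nrow, integer(1)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Flag subgraphs active before seizure onset
#'
#' A component is non-specific for the ictal events when it is already
#' expressed pre-ictally: in every seizure its mean activation over the
#' pre-onset windows is at least half its mean activation over the
#' remaining (ictal) windows. Components with all-zero activation are
#' flagged (vacuously pre-ictal).
#'
#' @param decomposition A `btnd_decomposition`.
#' @param preictal_windows Number of pre-onset windows, a scalar or one
#'   value per seizure; must be positive and smaller than every T(s).
#' @param ratio Pre/ictal mean-activation ratio at or above which a
#'   component is flagged (default 0.5).
#' @return Logical vector, one flag per component.
#' @export
flag_nonspecific <- function(decomposition, preictal_windows, ratio = 0.5) {
  stopifnot(inherits(decomposition, "btnd_decomposition"))
  V <- lapply(decomposition$activations, function(a) a$values)
  S <- length(V)
  pw <- rep_len(as.integer(preictal_windows), S)
  Ts <- vapply(V, nrow, integer(1))
  if (any(pw < 1L) || any(pw >= Ts))
    stop("flag_nonspecific: preictal_windows must lie in [1, T(s) - 1]")
  K <- ncol(V[[1L]])
  flags <- logical(K)
  for (k in seq_len(K)) {
    all_zero <- all(vapply(V, function(v) all(v[, k] == 0), logical(1)))
    if (all_zero) { flags[k] <- TRUE; next }
    pre_dominant <- vapply(seq_len(S), function(s) {
      pre <- mean(V[[s]][seq_len(pw[s]), k])
      ict <- mean(V[[s]][(pw[s] + 1L):Ts[s], k])
      pre >= ratio * ict
    }, logical(1))
    flags[k] <- all(pre_dominant)
  }
  flags
}
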