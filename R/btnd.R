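#' Subgraph set (shared factor F)
#'
#' The L x K non-negative matrix whose columns are functional connectivity
#' subgraphs: column k holds the edge weights of subgraph k, indexed by
#' `edge_index`.
#'
#' @param weights Non-negative L x K numeric matrix.
#' @param edge_index An [edge_index()] with `L` pairs.
#' @return An object of class `subgraph_set`.
#' @export
subgraph_set <- function(weights, edge_index) {
  weights <- as.matrix(weights)
  stopifnot(inherits(edge_index, "edge_index"))
  if (nrow(weights) != edge_index$L)
    stop("subgraph_set: weights must have L = ", edge_index$L, " rows")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("subgraph_set: weights must be finite and non-negative")
  structure(list(weights = weights, edge_index = edge_index),
            class = "subgraph_set")
}

#' @export
print.subgraph_set <- function(x, ...) {
  cat("<subgraph_set> ", nrow(x$weights), " edges x ", ncol(x$weights),
      " subgraphs, ", sum(x$weights > 0), " nonzero entries\n", sep = "")
  invisible(x)
}

#' Activation profiles of one seizure (factor V\{s\})
#'
#' The T(s) x K non-negative matrix whose column k is the activation time
#' course of subgraph k during seizure s.
#'
#' @param values Non-negative T x K numeric matrix.
#' @param seizure_id Identifier.
#' @return An object of class `activation_profiles`.
#' @export
activation_profiles <- function(values, seizure_id = "s1") {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("activation_profiles: values must be finite and non-negative")
  structure(list(values = values, seizure_id = seizure_id),
            class = "activation_profiles")
}

#' @export
print.activation_profiles <- function(x, ...) {
  cat("<activation_profiles> ", x$seizure_id, ": ", nrow(x$values),
      " windows x ", ncol(x$values), " subgraphs\n", sep = "")
  invisible(x)
}

#' Configuration of the joint decomposition
#'
#' Collects the hyperparameters of the factorization: the number of
#' subgraphs `K`, the subgraph sparsity weight `lambda`, the base
#' fused-lasso weights (`gamma`, `eta`) for the activation columns, the
#' per-seizure weights `zeta` and per-seizure fused-lasso parameters (both
#' derived from the data at fit time when left `NULL`), the restart budget
#' and the stopping rule.
#'
#' By default `gamma = lambda` (they are tied unless `gamma` is given) and
#' `eta = 0.2`; the restart budget defaults to 20.
#'
#' @param K Number of subgraphs (>= 1).
#' @param lambda Subgraph sparsity weight (>= 0).
#' @param gamma Activation sparsity weight; defaults to `lambda`.
#' @param eta Activation compactness weight (default 0.2).
#' @param zeta Optional per-seizure weights; default `NULL` means
#'   [compute_zeta()] at fit time (inverse squared Frobenius energy).
#' @param per_seizure_fused Optional list of [fused_lasso_params()], one per
#'   seizure; default `NULL` means [adapt_fused_params()] at fit time.
#' @param n_restarts Number of random restarts (default 20).
#' @param max_iter Maximum alternations per restart (default 500).
#' @param rel_tol Relative objective-change stopping threshold
#'   (default 1e-5).
#' @param seed Integer seed controlling all randomness of the fit.
#' @return An object of class `btnd_config`.
#' @export
btnd_config <- function(K, lambda = 0, gamma = lambda, eta = 0.2,
                        zeta = NULL, per_seizure_fused = NULL,
                        n_restarts = 20L, max_iter = 500L, rel_tol = 1e-5,
                        seed = 1L) {
  K <- as.integer(K)
  if (K < 1L) stop("btnd_config: K >= 1 required")
  if (lambda < 0 || gamma < 0 || eta < 0)
    stop("btnd_config: lambda, gamma, eta must be >= 0")
  if (n_restarts < 1L) stop("btnd_config: n_restarts >= 1 required")
  if (max_iter < 1L) stop("btnd_config: max_iter >= 1 required")
  if (rel_tol <= 0) stop("btnd_config: rel_tol > 0 required")
  structure(
    list(K = K, lambda = lambda,
         base_fused = fused_lasso_params(gamma = gamma, eta = eta),
         per_seizure_fused = per_seizure_fused, zeta = zeta,
         n_restarts = as.integer(n_restarts),
         max_iter = as.integer(max_iter), rel_tol = rel_tol,
         seed = as.integer(seed)),
    class = "btnd_config")
}

#' Per-seizure weights from seizure energy
#'
#' Balances the data-fit term across seizures by weighting each seizure
#' inversely to its energy: `zeta_s = 1 / ||X{s}||_F^2`, so every seizure
#' contributes its relative (not absolute) residual.
#'
#' @param X A [multi_seizure_dataset()].
#' @return Numeric vector of positive weights, one per seizure.
#' @export
compute_zeta <- function(X) {
  stopifnot(inherits(X, "multi_seizure_dataset"))
  e <- vapply(X$seizures, function(s) sum(s$values^2), numeric(1))
  if (any(e <= 0))
    stop("compute_zeta: seizure with zero energy (||X||_F = 0)")
  1 / e
}

#' Duration-adapted fused-lasso parameters
#'
#' Rescales the base activation weights to each seizure's duration so the l1
#' and total-variation budgets stay comparable per unit of column norm:
#' `gamma_s = gamma * sqrt(T_ref / T(s))` (same for `eta`), with `T_ref` the
#' median duration. Equal durations return the base values unchanged.
#'
#' @param base A [fused_lasso_params()].
#' @param durations Integer vector of window counts T(s), all >= 2.
#' @return List of [fused_lasso_params()], one per seizure.
#' @export
adapt_fused_params <- function(base, durations) {
  stopifnot(inherits(base, "fused_lasso_params"))
  if (any(durations < 2L)) stop("adapt_fused_params: durations must be >= 2")
  t_ref <- stats::median(durations)
  lapply(durations, function(Ts) {
    f <- sqrt(t_ref / Ts)
    fused_lasso_params(gamma = base$gamma * f, eta = base$eta * f)
  })
}

# Fill data-derived fields of a config and check shapes against the data.
resolve_config <- function(config, X) {
  stopifnot(inherits(config, "btnd_config"),
            inherits(X, "multi_seizure_dataset"))
  if (config$K > X$edge_index$L)
    stop("btnd: K must not exceed the number of edges L = ", X$edge_index$L)
  durations <- dataset_durations(X)
  if (any(durations < 2L)) stop("btnd: every seizure needs T(s) >= 2 windows")
  if (is.null(config$zeta)) config$zeta <- compute_zeta(X)
  if (length(config$zeta) != X$S || any(config$zeta <= 0))
    stop("btnd: zeta must hold one positive weight per seizure")
  if (is.null(config$per_seizure_fused))
    config$per_seizure_fused <- adapt_fused_params(config$base_fused,
                                                   durations)
  if (length(config$per_seizure_fused) != X$S)
    stop("btnd: per_seizure_fused must hold one entry per seizure")
  config
}

as_factor_matrix <- function(F) {
  if (inherits(F, "subgraph_set")) F$weights else as.matrix(F)
}
as_activation_list <- function(V) {
  lapply(V, function(v)
    if (inherits(v, "activation_profiles")) v$values else as.matrix(v))
}

#' Penalized data-fit objective of the joint factorization
#'
#' `sum_s zeta_s ||X{s} - F V{s}^t||_F^2 + (lambda / S) sum_{l,k} |F_lk|`.
#' The fused-lasso constraint on the activation columns is enforced by the
#' updates, not added here as a penalty.
#'
#' @param F A [subgraph_set()] (or L x K matrix).
#' @param V List of [activation_profiles()] (or T(s) x K matrices).
#' @param X A [multi_seizure_dataset()].
#' @param config A [btnd_config()]; `zeta` is derived from `X` if unset.
#' @return Scalar objective value.
#' @export
btnd_objective <- function(F, V, X, config) {
  config <- resolve_config(config, X)
  Fm <- as_factor_matrix(F)
  Vl <- as_activation_list(V)
  if (length(Vl) != X$S) stop("btnd_objective: one V per seizure required")
  fit <- 0
  for (s in seq_len(X$S)) {
    Xs <- X$seizures[[s]]$values
    if (nrow(Vl[[s]]) != ncol(Xs) || ncol(Vl[[s]]) != ncol(Fm) ||
        nrow(Fm) != nrow(Xs))
      stop("btnd_objective: shape mismatch for seizure ", s)
    fit <- fit + config$zeta[s] * sum((Xs - Fm %*% t(Vl[[s]]))^2)
  }
  fit + config$lambda / X$S * sum(abs(Fm))
}

#' Exact block update of the shared subgraph factor
#'
#' Minimizes the objective over `F >= 0` with the activations held fixed.
#' The problem separates over the rows of `F` into non-negative lasso
#' problems sharing one K x K Gram matrix; they are solved by cyclic
#' coordinate descent with soft-thresholding at `lambda / (2 S)` and
#' clipping at zero, iterated to stationarity. Never increases the
#' objective.
#'
#' @param F Current [subgraph_set()] (or matrix) used as warm start.
#' @param V List of [activation_profiles()] (or matrices), held fixed.
#' @param X A [multi_seizure_dataset()].
#' @param config A [btnd_config()].
#' @return Updated [subgraph_set()].
#' @export
update_subgraphs <- function(F, V, X, config) {
  config <- resolve_config(config, X)
  Fm <- as_factor_matrix(F)
  Vl <- as_activation_list(V)
  K <- ncol(Fm); S <- X$S
  A <- matrix(0, K, K); B <- matrix(0, nrow(Fm), K)
  for (s in seq_len(S)) {
    A <- A + config$zeta[s] * crossprod(Vl[[s]])
    B <- B + config$zeta[s] * (X$seizures[[s]]$values %*% Vl[[s]])
  }
  thr <- config$lambda / (2 * S)
  # a handful of exact coordinate sweeps per outer iteration is enough for
  # monotone block descent; K = 1 converges in a single sweep
  FA <- Fm %*% A
  for (sweep in seq_len(25L)) {
    delta <- 0
    for (k in seq_len(K)) {
      old_k <- Fm[, k]
      if (A[k, k] <= 0) {            # dead component: only the penalty acts
        new_k <- numeric(length(old_k))
      } else {
        cross <- FA[, k] - old_k * A[k, k]
        new_k <- (B[, k] - thr - cross) / A[k, k]
        new_k[new_k < 0] <- 0
      }
      d <- new_k - old_k
      delta <- max(delta, max(abs(d)))
      if (any(d != 0)) {
        Fm[, k] <- new_k
        FA <- FA + tcrossprod(d, A[k, ])
      }
    }
    if (delta < 1e-9 * (1 + max(Fm))) break
  }
  ei <- if (inherits(F, "subgraph_set")) F$edge_index else X$edge_index
  subgraph_set(Fm, ei)
}

# Constrained least-squares update of one activation column:
# min_{v>=0, C(v)<=1}  a ||v||^2 - 2 c.v   (a = ||f_k||^2 weighted, c given).
# Solved on the penalized path v(mu) = prox_{fused}(c/(a+mu)) with bisection
# on the multiplier mu until the constraint value lands in [1 - tol_band, 1].
solve_activation_column <- function(a, cvec, params, tol_band = 1e-3) {
  v0 <- pmax(cvec, 0) / a
  if (constraint_value_raw(v0, params) <= 1) return(v0)
  path_point <- function(mu) {
    y <- cvec / (a + mu)
    prox_fused_nonneg(y, mu * params$eta / (2 * (a + mu)),
                      mu * params$gamma / (2 * (a + mu)))
  }
  mu_hi <- a
  v_hi <- path_point(mu_hi)
  it <- 0L
  while (constraint_value_raw(v_hi, params) > 1 && it < 60L) {
    mu_hi <- mu_hi * 4; v_hi <- path_point(mu_hi); it <- it + 1L
  }
  if (constraint_value_raw(v_hi, params) > 1)
    return(scale_to_feasible(v_hi, params))   # pathological; force feasible
  mu_lo <- 0
  best <- v_hi
  for (i in seq_len(60L)) {
    cv_best <- constraint_value_raw(best, params)
    if (cv_best >= 1 - tol_band && cv_best <= 1) break
    mu <- (mu_lo + mu_hi) / 2
    v <- path_point(mu)
    cv <- constraint_value_raw(v, params)
    if (cv > 1) mu_lo <- mu else { mu_hi <- mu; best <- v }
  }
  best
}

# constraint_value without class checks, for inner loops
constraint_value_raw <- function(v, params) {
  tv <- if (length(v) > 1L) sum(abs(diff(v))) else 0
  params$gamma * sum(v) + params$eta * tv + sum(v^2)
}

#' Block update of one seizure's activation profiles
#'
#' Minimizes that seizure's data-fit term over each activation column in
#' turn, subject to non-negativity and the fused-lasso budget
#' `C(v, gamma_s, eta_s) <= 1`. Each column subproblem is solved on the
#' penalized proximal path (total-variation proximal operator plus
#' soft-thresholding and clipping) with bisection on the Lagrange
#' multiplier until the constraint is active or the unconstrained minimizer
#' is already feasible. A per-column safeguard keeps the previous feasible
#' column whenever a step would increase the fit term, so the update never
#' increases the objective.
#'
#' Columns matched to an all-zero subgraph column are set to zero and
#' reported in the `zero_components` attribute.
#'
#' @param V_s [activation_profiles()] (or T x K matrix), warm start; columns
#'   must be feasible.
#' @param F [subgraph_set()] (or L x K matrix), held fixed.
#' @param X_s [fc_series()] (or L x T matrix) of the seizure.
#' @param params [fused_lasso_params()] for this seizure (gamma_s, eta_s).
#' @return Updated [activation_profiles()].
#' @export
update_activations <- function(V_s, F, X_s, params) {
  stopifnot(inherits(params, "fused_lasso_params"))
  Vm <- if (inherits(V_s, "activation_profiles")) V_s$values else
    as.matrix(V_s)
  Fm <- as_factor_matrix(F)
  Xm <- if (inherits(X_s, "fc_series")) X_s$values else as.matrix(X_s)
  if (nrow(Vm) != ncol(Xm) || ncol(Vm) != ncol(Fm))
    stop("update_activations: shape mismatch")
  K <- ncol(Fm)
  zero_comp <- integer(0)
  R <- Xm - Fm %*% t(Vm)
  for (k in seq_len(K)) {
    fk <- Fm[, k]
    a <- sum(fk^2)
    if (a == 0) {
      R <- R + tcrossprod(fk, Vm[, k])   # no-op, fk = 0
      if (any(Vm[, k] != 0)) Vm[, k] <- 0
      zero_comp <- c(zero_comp, k)
      next
    }
    R <- R + tcrossprod(fk, Vm[, k])     # residual without component k
    cvec <- drop(crossprod(R, fk))
    v_new <- solve_activation_column(a, cvec, params)
    # safeguard: never let a column step increase the fit term
    fit_old <- a * sum(Vm[, k]^2) - 2 * sum(cvec * Vm[, k])
    fit_new <- a * sum(v_new^2) - 2 * sum(cvec * v_new)
    if (fit_new <= fit_old) Vm[, k] <- v_new
    R <- R - tcrossprod(fk, Vm[, k])
  }
  res <- activation_profiles(
    Vm, if (inherits(V_s, "activation_profiles")) V_s$seizure_id else "s")
  attr(res, "zero_components") <- zero_comp
  res
}

#' Single-restart alternating fit
#'
#' Runs the block-coordinate descent from one random initialization:
#' the subgraph factor starts from randomly chosen data columns (one window
#' per component) and the activations from i.i.d. uniform columns scaled to
#' the constraint boundary. Alternates [update_subgraphs()] and
#' [update_activations()] until the relative objective change drops below
#' `rel_tol` or `max_iter` alternations; the objective trace is recorded and
#' is non-increasing. Deterministic given `restart_seed`.
#'
#' @param X A [multi_seizure_dataset()].
#' @param config A [btnd_config()].
#' @param restart_seed Integer seed for this restart.
#' @return An object of class `btnd_decomposition`.
#' @export
fit_single <- function(X, config, restart_seed = config$seed) {
  config <- resolve_config(config, X)
  K <- config$K; S <- X$S
  durations <- dataset_durations(X)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(restart_seed)
  # init F from data columns: exactly equivariant under edge permutations
  Fm <- matrix(0, X$edge_index$L, K)
  for (k in seq_len(K)) {
    s <- sample.int(S, 1L)
    t <- sample.int(durations[s], 1L)
    Fm[, k] <- X$seizures[[s]]$values[, t]
  }
  V <- vector("list", S)
  for (s in seq_len(S)) {
    Vm <- matrix(stats::runif(durations[s] * K), durations[s], K)
    for (k in seq_len(K))
      Vm[, k] <- scale_to_feasible(Vm[, k], config$per_seizure_fused[[s]])
    V[[s]] <- activation_profiles(Vm, X$seizures[[s]]$seizure_id)
  }
  Fs <- subgraph_set(Fm, X$edge_index)
  trace <- btnd_objective(Fs, V, X, config)
  for (it in seq_len(config$max_iter)) {
    Fs <- update_subgraphs(Fs, V, X, config)
    for (s in seq_len(S))
      V[[s]] <- update_activations(V[[s]], Fs, X$seizures[[s]],
                                   config$per_seizure_fused[[s]])
    obj <- btnd_objective(Fs, V, X, config)
    if (!is.finite(obj))
      stop("fit_single: non-finite objective at iteration ", it)
    prev <- trace[length(trace)]
    trace <- c(trace, obj)
    if (abs(prev - obj) <= config$rel_tol * max(prev, .Machine$double.eps))
      break
  }
  structure(
    list(subgraphs = Fs, activations = V, config = config,
         objective_trace = trace,
         restart_objectives = trace[length(trace)],
         selected_restart = 1L, restart_seed = restart_seed),
    class = "btnd_decomposition")
}

#' Multi-restart joint decomposition
#'
#' The objective is non-convex, so the alternating solver is run from
#' `n_restarts` independent initializations (default 20) and the restart
#' reaching the smallest final objective is returned; ties go to the lowest
#' restart index. All per-restart seeds derive deterministically from
#' `config$seed`.
#'
#' @param X A [multi_seizure_dataset()].
#' @param config A [btnd_config()].
#' @return A `btnd_decomposition`: fields `subgraphs` ([subgraph_set()]),
#'   `activations` (list of [activation_profiles()]), `config` (resolved),
#'   `objective_trace` of the winning restart, `restart_objectives`,
#'   `selected_restart`, `restart_seeds`.
#' @export
btnd_fit <- function(X, config) {
  config <- resolve_config(config, X)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, config$n_restarts)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  fits <- lapply(seeds, function(rs) fit_single(X, config, rs))
  finals <- vapply(fits, function(f) f$restart_objectives, numeric(1))
  best <- which.min(finals)
  out <- fits[[best]]
  out$restart_objectives <- finals
  out$selected_restart <- best
  out$restart_seeds <- seeds
  out
}

#' @export
print.btnd_decomposition <- function(x, ...) {
  cat("<btnd_decomposition> K = ", ncol(x$subgraphs$weights),
      ", S = ", length(x$activations),
      ", objective = ", format(min(x$restart_objectives), digits = 6),
      " (restart ", x$selected_restart, "/",
      length(x$restart_objectives), ", ",
      length(x$objective_trace) - 1L, " iterations)\n", sep = "")
  invisible(x)
}

#' Weighted relative reconstruction error
#'
#' `sqrt( sum_s zeta_s ||X{s} - F V{s}^t||^2 / sum_s zeta_s ||X{s}||^2 )`,
#' the quantity tracked across model orders by [sweep_k()].
#'
#' @param fit A `btnd_decomposition`.
#' @param X The [multi_seizure_dataset()] it was fitted on.
#' @return Scalar in \[0, Inf).
#' @export
relative_error <- function(fit, X) {
  Fm <- fit$subgraphs$weights
  zeta <- fit$config$zeta
  num <- den <- 0
  for (s in seq_len(X$S)) {
    Xs <- X$seizures[[s]]$values
    num <- num + zeta[s] * sum((Xs - Fm %*% t(fit$activations[[s]]$values))^2)
    den <- den + zeta[s] * sum(Xs^2)
  }
  sqrt(num / den)
}
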