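# Stage-to-stage serialization: an RDS array container next to a JSON
# sidecar holding everything needed to re-run the stage (parameters, seeds,
# shapes), plus flat CSV / edge-list / GraphML exports.

sidecar_path <- function(path) paste0(sub("\\.rds$", "", path), ".json")

#' Write / read a connectivity series
#'
#' `write_fc_series()` stores the L x T matrix as an RDS container plus a
#' JSON sidecar (edge pairs, channel labels, window parameters, seizure id);
#' `read_fc_series()` restores the [fc_series()].
#'
#' @param fc An [fc_series()].
#' @param path Output path (`.rds`; the sidecar gets `.json`).
#' @return `path` (write) / an [fc_series()] (read), invisibly for write.
#' @export
write_fc_series <- function(fc, path) {
  stopifnot(inherits(fc, "fc_series"))
  saveRDS(fc$values, path)
  jsonlite::write_json(
    list(kind = "fc_series", seizure_id = fc$seizure_id,
         n_channels = fc$edge_index$n_channels,
         channel_labels = fc$edge_index$labels,
         pairs = fc$edge_index$pairs,
         window_length_s = fc$window_length_s,
         window_step_s = fc$window_step_s,
         window_start_s = fc$window_start_s),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fc_series
#' @export
read_fc_series <- function(path) {
  vals <- readRDS(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ei <- edge_index(meta$n_channels, meta$channel_labels)
  fc_series(vals, ei, meta$window_length_s, meta$window_step_s,
            meta$seizure_id, meta$window_start_s)
}

#' Export / import a connectivity series as CSV
#'
#' Rows are edges (labeled `"A1-A2|A2-A3"`), columns are window start times
#' in seconds. Values survive the round trip to at least 1e-9.
#'
#' @param fc An [fc_series()].
#' @param path CSV file path.
#' @return `path` / an [fc_series()].
#' @export
fc_to_csv <- function(fc, path) {
  stopifnot(inherits(fc, "fc_series"))
  df <- as.data.frame(format(fc$values, digits = 15, trim = TRUE,
                             scientific = FALSE))
  names(df) <- format(fc$window_start_s, digits = 15, trim = TRUE)
  df <- cbind(edge = edge_labels(fc$edge_index), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname fc_to_csv
#' @param window_length_s,window_step_s Window parameters to attach on
#'   import (defaults 4 and 1).
#' @param seizure_id Identifier to attach on import.
#' @export
fc_from_csv <- function(path, window_length_s = 4, window_step_s = 1,
                        seizure_id = "s1") {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- df$edge
  vals <- as.matrix(df[, -1L, drop = FALSE])
  ends <- strsplit(labels, "|", fixed = TRUE)
  chans <- unique(unlist(ends))
  ei <- edge_index(length(chans), chans)
  ord <- match(paste0(chans[ei$pairs[, 1L]], "|", chans[ei$pairs[, 2L]]),
               labels)
  if (anyNA(ord)) stop("fc_from_csv: edge labels do not form a full index")
  fc_series(vals[ord, , drop = FALSE], ei, window_length_s, window_step_s,
            seizure_id,
            window_start_s = as.numeric(colnames(df)[-1L]))
}

#' Write / read a fitted decomposition
#'
#' Stores the factors in an RDS container and the configuration, seeds and
#' objective traces in a JSON sidecar sufficient to re-run the fit.
#'
#' @param fit A `btnd_decomposition`.
#' @param path Output path (`.rds`).
#' @return `path` / a `btnd_decomposition`.
#' @export
write_decomposition <- function(fit, path) {
  stopifnot(inherits(fit, "btnd_decomposition"))
  saveRDS(list(F = fit$subgraphs$weights,
               V = lapply(fit$activations, function(a) a$values),
               pairs = fit$subgraphs$edge_index$pairs,
               n_channels = fit$subgraphs$edge_index$n_channels,
               labels = fit$subgraphs$edge_index$labels,
               seizure_ids = vapply(fit$activations, function(a)
                 as.character(a$seizure_id), character(1))),
          path)
  cfg <- fit$config
  jsonlite::write_json(
    list(kind = "btnd_decomposition",
         K = cfg$K, lambda = cfg$lambda,
         gamma = cfg$base_fused$gamma, eta = cfg$base_fused$eta,
         zeta = cfg$zeta,
         gamma_s = vapply(cfg$per_seizure_fused, `[[`, numeric(1), "gamma"),
         eta_s = vapply(cfg$per_seizure_fused, `[[`, numeric(1), "eta"),
         n_restarts = cfg$n_restarts, max_iter = cfg$max_iter,
         rel_tol = cfg$rel_tol, seed = cfg$seed,
         restart_seeds = fit$restart_seeds,
         restart_objectives = fit$restart_objectives,
         selected_restart = fit$selected_restart,
         objective_trace = fit$objective_trace,
         package_version = as.character(utils::packageVersion("btnd"))),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  arr <- readRDS(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ei <- edge_index(arr$n_channels, arr$labels)
  cfg <- btnd_config(K = meta$K, lambda = meta$lambda, gamma = meta$gamma,
                     eta = meta$eta, zeta = meta$zeta,
                     per_seizure_fused = Map(function(g, e)
                       fused_lasso_params(gamma = g, eta = e),
                       meta$gamma_s, meta$eta_s),
                     n_restarts = meta$n_restarts, max_iter = meta$max_iter,
                     rel_tol = meta$rel_tol, seed = meta$seed)
  structure(
    list(subgraphs = subgraph_set(arr$F, ei),
         activations = Map(activation_profiles, arr$V, arr$seizure_ids),
         config = cfg,
         objective_trace = meta$objective_trace,
         restart_objectives = meta$restart_objectives,
         selected_restart = meta$selected_restart,
         restart_seeds = meta$restart_seeds),
    class = "btnd_decomposition")
}

#' Export subgraphs as a weighted edge list
#'
#' One row per retained edge and component:
#' `contact_a, contact_b, weight, component`.
#'
#' @param F A [subgraph_set()] or [normalize_and_threshold()] report.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
subgraphs_to_csv <- function(F, path) {
  if (inherits(F, "subgraph_report")) {
    W <- F$normalized_weights; ei <- F$edge_index
  } else {
    W <- as_factor_matrix(F)
    ei <- if (inherits(F, "subgraph_set")) F$edge_index else NULL
  }
  if (is.null(ei)) stop("subgraphs_to_csv: an edge index is required")
  lab <- ei$labels
  if (is.null(lab)) lab <- paste0("ch", seq_len(ei$n_channels))
  rows <- do.call(rbind, lapply(seq_len(ncol(W)), function(k) {
    idx <- which(W[, k] > 0)
    if (length(idx) == 0L) return(NULL)
    data.frame(contact_a = lab[ei$pairs[idx, 1L]],
               contact_b = lab[ei$pairs[idx, 2L]],
               weight = format(W[idx, k], digits = 15, trim = TRUE,
                               scientific = FALSE),
               component = k)
  }))
  if (is.null(rows))
    rows <- data.frame(contact_a = character(0), contact_b = character(0),
                       weight = character(0), component = integer(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export subgraphs as GraphML
#'
#' One undirected graph over the channels with an edge attribute
#' `weight_k<component>` per subgraph (absent edges carry weight 0).
#'
#' @param F A [subgraph_set()].
#' @param path GraphML path.
#' @return `path`, invisibly.
#' @export
subgraphs_to_graphml <- function(F, path) {
  stopifnot(inherits(F, "subgraph_set"))
  W <- F$weights; ei <- F$edge_index
  lab <- ei$labels
  if (is.null(lab)) lab <- paste0("ch", seq_len(ei$n_channels))
  keep <- rowSums(W) > 0
  df <- data.frame(from = lab[ei$pairs[keep, 1L]],
                   to = lab[ei$pairs[keep, 2L]])
  for (k in seq_len(ncol(W)))
    df[[paste0("weight_k", k)]] <- W[keep, k]
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = lab))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export activation profiles as CSV
#'
#' Rows are analysis windows (with start time in seconds), columns are
#' components.
#'
#' @param ap An [activation_profiles()].
#' @param path CSV path.
#' @param window_step_s Window step used to label rows (default 1).
#' @param window_start_s Optional explicit start times.
#' @return `path`, invisibly.
#' @export
activations_to_csv <- function(ap, path, window_step_s = 1,
                               window_start_s = NULL) {
  stopifnot(inherits(ap, "activation_profiles"))
  V <- ap$values
  if (is.null(window_start_s))
    window_start_s <- (seq_len(nrow(V)) - 1L) * window_step_s
  df <- data.frame(start_s = window_start_s)
  for (k in seq_len(ncol(V)))
    df[[paste0("component_", k)]] <- format(V[, k], digits = 15,
                                            trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
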