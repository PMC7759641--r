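#' Edge index for upper-triangular channel pairs
#'
#' Fixes the bijection between the row index `l` of a connectivity matrix and
#' the unordered channel pair `(i, j)` with `i < j`. Pairs are enumerated in
#' lexicographic order: (1,2), (1,3), ..., (1,n), (2,3), ...
#'
#' @param n_channels Number of channels (nodes); must be >= 2.
#' @param labels Optional character vector of channel labels (length
#'   `n_channels`).
#' @return An object of class `edge_index` with elements `n_channels`,
#'   `pairs` (L x 2 integer matrix, first column < second column), `L`
#'   (number of pairs, `n_channels * (n_channels - 1) / 2`) and `labels`.
#' @examples
#' ei <- edge_index(4)
#' ei$L          # 6
#' ei$pairs[1, ] # 1 2
#' @export
edge_index <- function(n_channels, labels = NULL) {
  n_channels <- as.integer(n_channels)
  if (length(n_channels) != 1L || is.na(n_channels) || n_channels < 2L)
    stop("edge_index: n_channels must be a single integer >= 2")
  if (!is.null(labels) && length(labels) != n_channels)
    stop("edge_index: labels must have length n_channels")
  i <- rep.int(seq_len(n_channels - 1L), times = (n_channels - 1L):1L)
  j <- unlist(lapply(seq_len(n_channels - 1L), function(a) (a + 1L):n_channels),
              use.names = FALSE)
  structure(
    list(n_channels = n_channels,
         pairs = cbind(i = i, j = as.integer(j)),
         L = (n_channels * (n_channels - 1L)) %/% 2L,
         labels = labels),
    class = "edge_index")
}

#' Human-readable labels for the edges of an index
#'
#' @param ei An [edge_index()].
#' @param sep Separator between the two endpoint labels.
#' @return Character vector of length `ei$L`, e.g. `"A1-A2|B1-B2"`.
#' @export
edge_labels <- function(ei, sep = "|") {
  stopifnot(inherits(ei, "edge_index"))
  lab <- ei$labels
  if (is.null(lab)) lab <- paste0("ch", seq_len(ei$n_channels))
  paste0(lab[ei$pairs[, 1L]], sep, lab[ei$pairs[, 2L]])
}

#' @export
print.edge_index <- function(x, ...) {
  cat("<edge_index> ", x$n_channels, " channels, ", x$L, " edges\n", sep = "")
  invisible(x)
}
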