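#' Fused-lasso constraint parameters
#'
#' The budget on each activation column combines an l1 term (sparsity,
#' weight `gamma`), a total-variation term (temporal compactness, weight
#' `eta`) and a quadratic term (scale control):
#' `gamma * sum |v_t| + eta * sum |v_{t+1} - v_t| + sum v_t^2 <= 1`.
#'
#' @param gamma Sparsity weight (>= 0).
#' @param eta Compactness weight (>= 0); the package default is 0.2.
#' @return An object of class `fused_lasso_params`.
#' @export
fused_lasso_params <- function(gamma = 0, eta = 0.2) {
  if (!is.finite(gamma) || gamma < 0) stop("fused_lasso_params: gamma >= 0")
  if (!is.finite(eta) || eta < 0) stop("fused_lasso_params: eta >= 0")
  structure(list(gamma = gamma, eta = eta), class = "fused_lasso_params")
}

#' Value of the fused-lasso constraint functional
#'
#' Evaluates `gamma * sum |v_t| + eta * sum_{t<T} |v_{t+1} - v_t| +
#' sum v_t^2` for one activation column; the column is feasible when the
#' value is at most 1.
#'
#' @param v Numeric vector (an activation column).
#' @param params A [fused_lasso_params()].
#' @return A non-negative scalar.
#' @examples
#' constraint_value(c(0, 0.5, 0), fused_lasso_params(gamma = 0.1, eta = 0.2))
#' # 0.1*0.5 + 0.2*(0.5 + 0.5) + 0.25 = 0.5
#' @export
constraint_value <- function(v, params) {
  stopifnot(inherits(params, "fused_lasso_params"))
  if (length(v) < 1L || any(!is.finite(v)))
    stop("constraint_value: v must be finite and non-empty")
  tv <- if (length(v) > 1L) sum(abs(diff(v))) else 0
  params$gamma * sum(abs(v)) + params$eta * tv + sum(v^2)
}

# 1-D total-variation denoising: argmin_u 0.5 ||u - y||^2 + w * TV(u).
# Direct non-iterative algorithm (Condat 2013); exact up to float rounding.
tv_denoise <- function(y, w) {
  n <- length(y)
  if (w <= 0 || n == 1L) return(y)
  x <- numeric(n)
  k <- k0 <- km <- kp <- 1L
  vmin <- y[1L] - w; vmax <- y[1L] + w
  umin <- w; umax <- -w
  repeat {
    if (k == n) { x[n] <- vmin + umin; return(x) }
    repeat {
      if (y[k + 1L] + umin < vmin - w) {            # forced negative jump
        x[k0:km] <- vmin
        k <- k0 <- km <- kp <- km + 1L
        vmin <- y[k]; vmax <- y[k] + 2 * w
        umin <- w; umax <- -w
      } else if (y[k + 1L] + umax > vmax + w) {     # forced positive jump
        x[k0:kp] <- vmax
        k <- k0 <- km <- kp <- kp + 1L
        vmin <- y[k] - 2 * w; vmax <- y[k]
        umin <- w; umax <- -w
      } else {                                      # extend current segment
        k <- k + 1L
        umin <- umin + y[k] - vmin
        umax <- umax + y[k] - vmax
        if (umin >= w) {
          vmin <- vmin + (umin - w) / (k - k0 + 1L)
          umin <- w; km <- k
        }
        if (umax <= -w) {
          vmax <- vmax + (umax + w) / (k - k0 + 1L)
          umax <- -w; kp <- k
        }
      }
      if (k >= n) break
    }
    if (umin < 0) {                                 # negative jump at the end
      x[k0:km] <- vmin
      k <- k0 <- km <- km + 1L
      vmin <- y[k]; umin <- w
      umax <- y[k] + w - vmax
    } else if (umax > 0) {                          # positive jump at the end
      x[k0:kp] <- vmax
      k <- k0 <- kp <- kp + 1L
      vmax <- y[k]; umax <- -w
      umin <- y[k] - w - vmin
    } else {
      x[k0:n] <- vmin + umin / (k - k0 + 1L)
      return(x)
    }
  }
}

# Proximal map of the non-negative fused lasso:
# argmin_{v >= 0} 0.5 ||v - y||^2 + w_tv * TV(v) + w_l1 * sum(v)
# = clip_{>=0}( soft_threshold( tv_denoise(y, w_tv), w_l1 ) )
prox_fused_nonneg <- function(y, w_tv, w_l1) {
  u <- tv_denoise(y, w_tv)
  u <- sign(u) * pmax(0, abs(u) - w_l1)
  pmax(u, 0)
}

# Scale a non-negative vector onto the feasible set of the constraint:
# find alpha >= 1 with C(v / alpha) <= 1. With l = gamma*sum|v| + eta*TV(v)
# and q = sum v^2, C(v/a) = l/a + q/a^2, solved at a = (l + sqrt(l^2+4q))/2.
scale_to_feasible <- function(v, params) {
  if (all(v == 0)) return(v)
  l <- params$gamma * sum(abs(v)) +
    params$eta * (if (length(v) > 1L) sum(abs(diff(v))) else 0)
  q <- sum(v^2)
  a <- (l + sqrt(l^2 + 4 * q)) / 2
  if (a > 1) v / a else v
}
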