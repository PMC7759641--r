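test_that("objective equals its brute-force evaluation", {
  X <- random_dataset(4, c(4, 5), seed = 41)    # L = 6
  cfg <- btnd_config(K = 2, lambda = 0.3, seed = 1)
  set.seed(42)
  Fm <- matrix(runif(12), 6, 2)
  V <- list(matrix(runif(8), 4, 2), matrix(runif(10), 5, 2))
  zeta <- compute_zeta(X)
  expect_equal(btnd_objective(Fm, V, X, cfg),
               objective_oracle(Fm, V,
                                lapply(X$seizures, function(s) s$values),
                                zeta, 0.3),
               tolerance = 1e-12)
  # F = 0, V = 0: residual is the data itself
  expect_equal(btnd_objective(0 * Fm, lapply(V, function(v) 0 * v), X, cfg),
               sum(zeta * vapply(X$seizures, function(s) sum(s$values^2),
                                 numeric(1))))
  # noiseless planted data at the true factors with lambda = 0
  g <- generate_planted_dataset(6, 2, c(8, 9), noise_sigma = 0, seed = 2)
  expect_equal(btnd_objective(g$truth$true_subgraphs,
                              g$truth$true_activations, g$dataset,
                              btnd_config(K = 2, lambda = 0)),
               0, tolerance = 1e-20)
  expect_error(btnd_objective(Fm, V[1], X, cfg), "one V per seizure")
})

test_that("subgraph update is an exact non-negative lasso block solve", {
  # fixed point at the truth on noiseless data with lambda = 0
  g <- generate_planted_dataset(6, 2, c(8, 9), noise_sigma = 0, seed = 6)
  cfg <- btnd_config(K = 2, lambda = 0)
  F1 <- update_subgraphs(g$truth$true_subgraphs, g$truth$true_activations,
                         g$dataset, cfg)
  expect_equal(F1$weights, g$truth$true_subgraphs, tolerance = 1e-9)

  # the update never increases the objective
  X <- random_dataset(4, c(4, 5), seed = 43)
  set.seed(44)
  Fm <- matrix(runif(12), 6, 2)
  V <- list(matrix(runif(8), 4, 2), matrix(runif(10), 5, 2))
  cfg2 <- btnd_config(K = 2, lambda = 0.05)
  F2 <- update_subgraphs(Fm, V, X, cfg2)
  expect_lte(btnd_objective(F2, V, X, cfg2),
             btnd_objective(Fm, V, X, cfg2) + 1e-10)

  # instance-specific threshold that empties F: lambda >= 2 S max(B)
  zeta <- compute_zeta(X)
  B <- zeta[1] * X$seizures[[1]]$values %*% V[[1]] +
    zeta[2] * X$seizures[[2]]$values %*% V[[2]]
  cfg3 <- btnd_config(K = 2, lambda = 2 * 2 * max(B) * 1.001)
  expect_true(all(update_subgraphs(Fm, V, X, cfg3)$weights == 0))

  # K = 1, S = 1: each row has the closed-form soft-threshold solution
  X1 <- random_dataset(4, 5, seed = 45)
  v <- matrix(runif(5), 5, 1)
  lam <- 0.02
  cfg4 <- btnd_config(K = 1, lambda = lam)
  F4 <- update_subgraphs(matrix(runif(6), 6, 1), list(v), X1, cfg4)
  z <- compute_zeta(X1)
  for (l in 1:6) {
    xr <- X1$seizures[[1]]$values[l, ]
    expected <- max(0, (2 * z * sum(xr * v) - lam) / (2 * z * sum(v^2)))
    expect_equal(F4$weights[l, 1], expected, tolerance = 1e-4)
  }
})

test_that("activation update solves the constrained column subproblems", {
  p <- fused_lasso_params(gamma = 0.1, eta = 0.2)
  Fm <- matrix(runif(12, 0.2, 1), 6, 2)
  # zero data: zero activations are optimal and feasible
  V0 <- update_activations(matrix(0.1, 4, 2), Fm, matrix(0, 6, 4), p)
  expect_true(all(V0$values == 0))

  # rank-1 noiseless with gamma = eta = 0: the constraint is the unit ball,
  # so the recovered column is v / ||v||
  p0 <- fused_lasso_params(gamma = 0, eta = 0)
  f <- matrix(runif(6, 0.2, 1), 6, 1)
  v <- c(0, 0.8, 0.8, 0.2, 0, 0)
  Xs <- f %*% t(v * sqrt(sum(v^2)))   # scale so the optimum is on the ball
  V1 <- update_activations(matrix(0, 6, 1), f, Xs, p0)
  expect_equal(V1$values[, 1], v / sqrt(sum(v^2)), tolerance = 1e-3)
  expect_equal(sum(V1$values[, 1]^2), 1, tolerance = 1e-3)

  # all-zero subgraph column: activation zeroed and flagged
  f2 <- cbind(f, 0)
  V2 <- update_activations(matrix(0.05, 6, 2), f2, Xs, p0)
  expect_true(all(V2$values[, 2] == 0))
  expect_equal(attr(V2, "zero_components"), 2L)

  # T = 3 toy against exhaustive non-negative grid search (step 0.005)
  pg <- fused_lasso_params(gamma = 0.3, eta = 0.2)
  set.seed(51)
  for (r in 1:3) {
    f3 <- matrix(runif(5, 0.3, 1), 5, 1)
    Xs3 <- matrix(runif(15), 5, 3)
    got <- update_activations(matrix(0, 3, 1), f3, Xs3, pg)$values[, 1]
    a <- sum(f3^2)
    cvec <- drop(crossprod(Xs3, f3))
    grid <- seq(0, 1, by = 0.005)
    best <- c(0, 0, 0); best_val <- Inf
    for (v1 in grid) {
      # prune with the quadratic bound
      if (v1^2 > 1) break
      for (v2 in grid) {
        if (v1^2 + v2^2 > 1) break
        v3 <- grid
        ok <- v1^2 + v2^2 + v3^2 +
          pg$gamma * (v1 + v2 + v3) +
          pg$eta * (abs(v2 - v1) + abs(v3 - v2)) <= 1
        if (!any(ok)) next
        v3ok <- v3[ok]
        vals <- a * (v1^2 + v2^2 + v3ok^2) -
          2 * (cvec[1] * v1 + cvec[2] * v2 + cvec[3] * v3ok)
        i <- which.min(vals)
        if (vals[i] < best_val) {
          best_val <- vals[i]; best <- c(v1, v2, v3ok[i])
        }
      }
    }
    expect_lt(max(abs(got - best)), 0.02)
  }
})

test_that("single-restart fit descends, converges and is deterministic", {
  g <- generate_planted_dataset(6, 2, c(10, 12), noise_sigma = 0, seed = 8)
  cfg <- btnd_config(K = 2, lambda = 0, gamma = 0, eta = 0,
                     n_restarts = 1, seed = 3)
  f <- fit_single(g$dataset, cfg, restart_seed = 21)
  zeta <- compute_zeta(g$dataset)
  norm0 <- sum(zeta * vapply(g$dataset$seizures,
                             function(s) sum(s$values^2), numeric(1)))
  expect_lte(min(f$objective_trace), 1e-6 * norm0)
  expect_true(all(diff(f$objective_trace) <=
                    1e-8 * f$objective_trace[-length(f$objective_trace)] +
                    1e-15))

  # one alternation exactly when max_iter = 1
  cfg1 <- btnd_config(K = 2, max_iter = 1, n_restarts = 1)
  f1 <- fit_single(g$dataset, cfg1, restart_seed = 5)
  expect_length(f1$objective_trace, 2)

  # bit-identical under the same restart seed
  f2 <- fit_single(g$dataset, cfg, restart_seed = 21)
  expect_identical(f$subgraphs$weights, f2$subgraphs$weights)
  expect_identical(lapply(f$activations, `[[`, "values"),
                   lapply(f2$activations, `[[`, "values"))
})

test_that("multi-restart fit keeps the best restart and stays reproducible", {
  g <- generate_planted_dataset(6, 2, c(8, 10), noise_sigma = 0.02, seed = 12)
  cfg <- btnd_config(K = 2, lambda = 0, n_restarts = 4, seed = 9)
  f <- btnd_fit(g$dataset, cfg)
  expect_length(f$restart_objectives, 4)
  expect_equal(f$selected_restart, which.min(f$restart_objectives))
  expect_equal(min(f$objective_trace),
               f$restart_objectives[f$selected_restart])
  # n_restarts = 1 reduces to fit_single with the derived seed
  cfg1 <- btnd_config(K = 2, lambda = 0, n_restarts = 1, seed = 9)
  f1 <- btnd_fit(g$dataset, cfg1)
  set.seed(9)
  rs <- sample.int(2147483646L, 1)
  expect_identical(f1$subgraphs$weights,
                   fit_single(g$dataset, cfg1, rs)$subgraphs$weights)
  # the shipped restart budget
  expect_identical(formals(btnd_config)$n_restarts, 20L)
})

test_that("per-seizure weights follow the inverse-energy rule", {
  ei <- edge_index(4)
  X1 <- multi_seizure_dataset(fc_series(matrix(1 / sqrt(6 * 4) * 2, 6, 4),
                                        ei))  # ||X||_F^2 = 4
  expect_equal(compute_zeta(X1), 0.25)
  X <- random_dataset(4, c(5, 5), seed = 61)
  X$seizures[[2]]$values <- X$seizures[[1]]$values
  z <- compute_zeta(X)
  expect_equal(z[1], z[2])
  # tiling a seizure doubles its energy and halves its weight
  tiled <- fc_series(cbind(X$seizures[[1]]$values,
                           X$seizures[[1]]$values), ei, seizure_id = "t")
  z2 <- compute_zeta(multi_seizure_dataset(list(X$seizures[[1]], tiled)))
  expect_equal(z2[2], z2[1] / 2)
  # degenerate data rejected
  expect_error(compute_zeta(multi_seizure_dataset(
    fc_series(matrix(0, 6, 3), ei))), "zero energy")
})

test_that("fused-lasso weights adapt to seizure duration", {
  base <- fused_lasso_params(gamma = 0.2, eta = 0.2)
  same <- adapt_fused_params(base, c(40, 40, 40))
  expect_equal(vapply(same, `[[`, numeric(1), "gamma"), rep(0.2, 3))
  expect_equal(vapply(same, `[[`, numeric(1), "eta"), rep(0.2, 3))
  two <- adapt_fused_params(base, c(50, 200))
  expect_equal(two[[1]]$gamma, 0.2 * sqrt(125 / 50), tolerance = 1e-12)
  expect_equal(two[[2]]$gamma, 0.2 * sqrt(125 / 200), tolerance = 1e-12)
  # the shipped compactness default
  expect_equal(eval(formals(fused_lasso_params)$eta), 0.2)
})
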