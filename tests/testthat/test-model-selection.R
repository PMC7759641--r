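test_that("elbow selection maximizes distance to the chord", {
  # oracle: evaluate the normalized point-to-chord distance directly
  chord_dist <- function(k, e) {
    x <- (k - k[1]) / (k[length(k)] - k[1])
    y <- (e - min(e)) / (max(e) - min(e))
    dx <- x[length(x)] - x[1]; dy <- y[length(y)] - y[1]
    abs(dy * x - dx * y + x[length(x)] * y[1] - y[length(y)] * x[1]) /
      sqrt(dx^2 + dy^2)
  }
  k <- c(3, 4, 5, 6)
  e <- c(1.0, 0.3, 0.28, 0.27)
  expect_equal(elbow_select(k, e), k[which.max(chord_dist(k, e))])
  expect_equal(elbow_select(k, e), 4)

  # perfectly linear curve: no elbow, warn and return k_min
  expect_warning(sel <- elbow_select(3:7, seq(1, 0.2, length.out = 5)),
                 "no elbow")
  expect_equal(sel, 3)

  # exact tie between two distances: the smaller K wins
  expect_equal(elbow_select(c(3, 4, 5, 6), c(1, 0.4, 0.4, 1)), 4)

  # increasing errors: k_min with a warning
  expect_warning(sel2 <- elbow_select(3:5, c(0.1, 0.2, 0.3)), "no elbow")
  expect_equal(sel2, 3)

  # invariance to affine rescaling of the error axis
  set.seed(71)
  for (r in 1:10) {
    e2 <- sort(runif(6), decreasing = TRUE)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(elbow_select(3:8, e2), elbow_select(3:8, a * e2 + b))
  }
})

test_that("subgraph normalization and thresholding follow the 0-1 scale", {
  ei <- edge_index(3)
  Fm <- cbind(c(2.0, 0.8, 0.2), c(0.5, 0.5, 0.5), c(0, 0, 0))
  rep_ <- normalize_and_threshold(subgraph_set(Fm, ei), 0.2)
  expect_equal(rep_$normalized_weights[, 1], c(1.0, 0.4, 0))
  expect_equal(rep_$normalized_weights[, 2], c(1, 1, 1))
  expect_equal(rep_$zero_components, 3L)
  expect_equal(rep_$retained_edges[[1]]$weight, c(1.0, 0.4))
  expect_equal(nrow(rep_$retained_edges[[3]]), 0)

  # threshold 0 keeps everything
  rep0 <- normalize_and_threshold(subgraph_set(Fm, ei), 0)
  expect_equal(rep0$normalized_weights[, 1], c(1.0, 0.4, 0.1))

  # idempotence: normalize-threshold of the result is itself
  again <- normalize_and_threshold(
    subgraph_set(rep_$normalized_weights, ei), 0.2)
  expect_equal(again$normalized_weights, rep_$normalized_weights)

  # shipped default threshold
  expect_equal(eval(formals(normalize_and_threshold)$threshold), 0.2)
})

test_that("pre-ictally active components are flagged as non-specific", {
  mk_fit <- function(Vlist) {
    ei <- edge_index(3)
    structure(list(
      subgraphs = subgraph_set(matrix(1, 3, ncol(Vlist[[1]])), ei),
      activations = lapply(seq_along(Vlist), function(s)
        activation_profiles(Vlist[[s]], paste0("s", s))),
      config = btnd_config(K = ncol(Vlist[[1]]))),
      class = "btnd_decomposition")
  }
  # component 1 active only after onset; component 2 constant throughout;
  # component 3 at exactly the 50% pre/ictal ratio (flagged by the >= rule)
  V <- cbind(c(0, 0, 1, 1, 1, 1),
             rep(0.5, 6),
             c(0.2, 0.2, 0.4, 0.4, 0.4, 0.4))
  fit <- mk_fit(list(V, V))
  flags <- flag_nonspecific(fit, preictal_windows = 2)
  expect_identical(flags, c(FALSE, TRUE, TRUE))

  # all-zero component is vacuously non-specific
  V2 <- cbind(c(0, 0, 1, 1, 1, 1), rep(0, 6))
  expect_identical(flag_nonspecific(mk_fit(list(V2)), 2), c(FALSE, TRUE))

  # a component pre-ictal in one seizure but silent pre-ictally in another
  # is specific (the rule requires every seizure)
  Va <- cbind(rep(0.5, 6))
  Vb <- cbind(c(0, 0, 1, 1, 1, 1))
  expect_identical(flag_nonspecific(mk_fit(list(Va, Vb)), 2), FALSE)

  expect_error(flag_nonspecific(fit, preictal_windows = 6), "T\\(s\\)")
})

test_that("lambda tuning reaches the target density on a planted instance", {
  # ~20% of edges truly active: 4 components, each on ~5.4% of edges
  g <- generate_planted_dataset(12, 4, c(30, 40), edge_sparsity = 0.054,
                                noise_sigma = 0.02, seed = 3)
  cfg <- btnd_config(K = 4, n_restarts = 2, rel_tol = 1e-4, seed = 5)
  tuning <- tune_lambda(g$dataset, cfg, target_density = 0.2)
  expect_lte(abs(tuning$density - 0.2), 0.05)
  expect_gt(tuning$lambda, 0)
  expect_equal(edge_density(tuning$fit$subgraphs), tuning$density)
  # achieved density decreases as lambda grows along the search trace
  tr <- tuning$trace[order(tuning$trace$lambda), ]
  expect_true(all(diff(tr$density) <= 0.02))
  # shipped default target
  expect_equal(eval(formals(tune_lambda)$target_density), 0.2)
})

test_that("K sweep records a decreasing error curve and finds the elbow", {
  g <- generate_planted_dataset(10, 3, c(25, 30), edge_sparsity = 0.15,
                                noise_sigma = 0.01, seed = 13)
  cfg <- btnd_config(K = 3, lambda = 0, n_restarts = 2, rel_tol = 1e-4,
                     seed = 17)
  sw <- sweep_k(g$dataset, cfg, k_min = 2, k_max = 6)
  expect_equal(sw$k_values, 2:6)
  # errors non-increasing within restart noise
  expect_true(all(diff(sw$errors) <= 0.02))
  expect_equal(sw$selected_k, 3)
  # shipped default sweep range
  expect_equal(eval(formals(sweep_k)$k_min), 3L)
  expect_equal(eval(formals(sweep_k)$k_max), 10L)
})
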