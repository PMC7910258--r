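# Greedy VOP compression: dominance tests, certificates, baking, safety.

make_config <- function(eps, ...) compression_config(epsilon_g = eps, seed = 1, ...)

test_that("scaled copies of one matrix compress to a single VOP at any epsilon", {
  S <- random_psd(3)
  alphas <- c(1, 0.9, 0.5, 0.25, 0.05)
  set <- sar_matrix_set(lapply(alphas, function(a) a * S),
                        global_matrix = S)
  for (eps in c(0, 0.1)) {
    model <- overestimation_model("global", eps, Z = set$global_matrix)
    res <- suppressWarnings(compress(set, model, make_config(eps)))
    expect_length(res$vop_indices, 1L)
    expect_equal(res$vop_indices, 1L)  # the largest copy
  }
})

test_that("orthogonal diagonal matrices with a zero term give two VOPs", {
  set <- sar_matrix_set(list(diag(c(1, 0)) + 0i, diag(c(0, 1)) + 0i))
  model <- overestimation_model("global", 0, Z = matrix(0i, 2, 2))
  expect_warning(res <- compress(set, model, make_config(0)),
                 "exact-domination")
  expect_length(res$vop_indices, 2L)
})

test_that("dominance_test returns bounded/unbounded/inconclusive as specified", {
  set.seed(61)
  n <- 4
  vops <- list(random_psd(n, 2), random_psd(n))
  Z <- random_psd(n, 0.2)
  model <- overestimation_model("global", 0.1, Z = Z)

  # a candidate equal to a current VOP: bounded, one-hot certificate, first
  # coefficient update resolves it under the greedy rule
  cfg <- make_config(0.1, coef_update_rule = "greedy_argmax")
  r <- dominance_test(vops[[1]], vops, model, cfg)
  expect_equal(r$status, "bounded")
  expect_equal(r$c_vop, c(1, 0), tolerance = 1e-12)
  expect_lte(r$iterations, 2L)

  # candidate whose top eigenvalue exceeds any achievable bound: unbounded,
  # and the returned witness violates the scalar condition
  lam_bound <- max(vapply(vops, function(S)
    max(eigen(S, symmetric = TRUE, only.values = TRUE)$values), numeric(1))) +
    0.1 * max(eigen(Z, symmetric = TRUE, only.values = TRUE)$values)
  Sv <- random_psd(n) + diag(rep(2 * lam_bound + 0i, n))
  r2 <- dominance_test(Sv, vops, model, make_config(0.1))
  expect_equal(r2$status, "unbounded")
  b <- r2$witness
  expect_gt(quadratic_form(b, Sv),
            max(vapply(vops, function(S) quadratic_form(b, S), numeric(1))) +
              evaluate_term(model, b))

  # iteration cap 0 with an initially non-PSD P: inconclusive
  Sm <- 0.4 * vops[[1]] + 0.6 * vops[[2]]
  r3 <- dominance_test(Sm, vops, model, make_config(0.1, max_coef_iterations = 0))
  expect_equal(r3$status, "inconclusive")
})

test_that("certificates re-verify PSD and random probes find no bound violation", {
  set <- random_sar_set(300, 4, seed = 42)
  model <- overestimation_model("global", 0.05, Z = set$global_matrix)
  res <- compress(set, model, make_config(0.05), keep_certificates = TRUE)
  expect_gt(length(res$vop_indices), 1L)
  expect_equal(length(res$certificates),
               n_voxels(set) - length(res$vop_indices))

  # independent eigendecomposition of every certificate, against the FINAL
  # VOP set (added VOPs get zero coefficients): bounded stays bounded
  ok <- verify_certificates(set, res)
  expect_true(all(ok))

  # coefficient invariants
  for (cert in res$certificates) {
    expect_true(all(cert$c_vop >= 0))
    expect_equal(sum(cert$c_vop), 1, tolerance = 1e-12)
  }

  # random-probe oracle: the baked bound dominates every voxel
  B <- random_unit_power_vectors(2e4, 4, seed = 4)
  baked <- bake_vops(res)
  bound <- bound_sar(baked, B)
  actual <- sarvop:::actual_sar_max(set, B)
  expect_true(all(bound >= actual * (1 - 1e-9)))
})

test_that("on an extreme-point set every surviving VOP is necessary", {
  # sets built from well-separated extreme matrices plus certifiable convex
  # combinations: the greedy keeps (a subset of) the extremes, and removing
  # any one of them re-opens a violation witness
  set <- extreme_point_set(n_extreme = 10, n_fill = 290, n_ch = 4, seed = 7)
  model <- overestimation_model("global", 0.05, Z = set$global_matrix)
  res <- compress(set, model, make_config(0.05))
  expect_true(all(res$vop_indices <= 10L))   # only extremes survive
  cfg_long <- make_config(0.05, max_coef_iterations = 100)
  for (k in seq_along(res$vop_indices)) {
    others <- res$vop_matrices[-k]
    if (length(others) == 0L) next
    r <- dominance_test(res$vop_matrices[[k]], others, model, cfg_long)
    expect_equal(r$status, "unbounded",
                 label = sprintf("VOP %d dominance status", k))
    b <- r$witness
    expect_gt(quadratic_form(b, res$vop_matrices[[k]]),
              max(vapply(others, function(S) quadratic_form(b, S), numeric(1))) +
                evaluate_term(model, b))
  }
})

test_that("precompute_vops honours the target count and its doubling trace", {
  S <- random_psd(3)
  copies <- sar_matrix_set(lapply(c(1, 0.7, 0.4), function(a) a * S),
                           global_matrix = S)
  p <- precompute_vops(copies, epsilon_g_pre = 0.05, target_count = 10)
  expect_length(p$pre_vops, 1L)

  set <- random_sar_set(200, 4, seed = 6)
  p2 <- precompute_vops(set, epsilon_g_pre = 0.02, target_count = 10)
  expect_lte(length(p2$pre_vops), 10L)
  expect_true(all(diff(p2$trace$n_vops) <= 0))  # doubling only shrinks the set
  expect_equal(p2$epsilon_g_pre,
               0.02 * 2^(nrow(p2$trace) - 1L))

  # a huge factor bounds everything with a single pre-VOP
  p3 <- precompute_vops(set, epsilon_g_pre = 1e4, target_count = 10,
                        auto_tune = FALSE)
  expect_length(p3$pre_vops, 1L)
})

test_that("baked bounds equal unbaked model bounds for all strategies", {
  set <- random_sar_set(120, 4, seed = 20)
  B <- random_unit_power_vectors(1000, 4, seed = 3)

  unbaked_bound <- function(res, B) {
    q <- sarvop:::colmax(Re(res$vop_flat %*% sarvop:::qf_weights(B)))
    q + sarvop:::evaluate_term_many(res$model, B)
  }

  for (strategy in c("global", "diag", "local", "double")) {
    model <- suppressWarnings(build_model(set, strategy, epsilon_g = 0.1,
                                          subset_fraction = 0.1,
                                          epsilon_g_pre = 0.05))
    res <- compress(set, model, make_config(0.1))
    baked <- bake_vops(res)
    expect_equal(bound_sar(baked, B), unbaked_bound(res, B),
                 tolerance = 1e-12, label = strategy)
    if (strategy == "double") {
      expect_length(baked$secondary, length(model$pre_vops))
    } else {
      expect_null(baked$secondary)
      # common additive term commutes with the max
      expect_equal(matrix(baked$primary_flat[1, ], 4, 4),
                   res$vop_matrices[[1]] + 0.1 * model$Z, tolerance = 1e-12)
    }
  }
})

test_that("the witness-pool pre-screen changes the work, not the result", {
  set <- random_sar_set(250, 4, seed = 33)
  model <- overestimation_model("global", 0.08, Z = set$global_matrix)
  cfg <- make_config(0.08)
  res_pool <- compress(set, model, cfg, use_witness_pool = TRUE)
  res_plain <- compress(set, model, cfg, use_witness_pool = FALSE)
  expect_equal(res_pool$vop_indices, res_plain$vop_indices)
  expect_identical(which(res_pool$statuses == "certified"),
                   which(res_plain$statuses == "certified"))
})

test_that("VOP count is nonincreasing in epsilon_g (median over seeds)", {
  set <- small_phantom(grid = c(8L, 8L, 8L))
  eps_grid <- c(0.05, 0.15, 0.45)
  counts <- sapply(1:5, function(seed) {
    sapply(eps_grid, function(eps) {
      model <- overestimation_model("global", eps, Z = set$global_matrix)
      cfg <- compression_config(epsilon_g = eps, seed = seed)
      length(compress(set, model, cfg)$vop_indices)
    })
  })
  med <- apply(counts, 1, median)
  expect_true(all(diff(med) <= 0))
})
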