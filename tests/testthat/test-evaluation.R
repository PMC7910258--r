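# Random-excitation evaluation: probes, reports, safety, curves.

test_that("random_unit_power_vectors are unit power, reproducible and isotropic", {
  B <- random_unit_power_vectors(500, 6, seed = 3)
  expect_equal(colSums(Mod(B)^2), rep(1, 500), tolerance = 1e-12)
  expect_identical(B, random_unit_power_vectors(500, 6, seed = 3))
  expect_false(identical(B, random_unit_power_vectors(500, 6, seed = 4)))

  # isotropy: the SAR distribution under a fixed diagonal matrix is
  # invariant under a fixed unitary rotation of the sampling law
  S <- diag(c(3, 1, 0.5, 0.2, 2, 0.8)) + 0i
  U <- qr.Q(qr(matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6)))
  q1 <- Re(colSums(Conj(B) * (S %*% B)))
  B2 <- random_unit_power_vectors(500, 6, seed = 11)
  q2 <- Re(colSums(Conj(U %*% B2) * (S %*% (U %*% B2))))
  expect_gt(suppressWarnings(ks.test(q1, q2)$p.value), 0.01)
})

test_that("a lossless compression evaluates to zero overestimation", {
  set <- random_sar_set(40, 3, seed = 2)
  model <- overestimation_model("global", 0, Z = 0 * set$global_matrix)
  res <- suppressWarnings(compress(set, model,
                                   compression_config(epsilon_g = 0, seed = 1)))
  # force every voxel into the VOP set: bound == actual exactly
  res$vop_indices <- set$voxel_ids
  res$vop_matrices <- lapply(seq_len(40), function(v) voxel_matrix(set, v))
  res$vop_flat <- set$flat
  B <- random_unit_power_vectors(500, 3, seed = 5)
  rep <- evaluate_compression(set, res, B)
  expect_equal(rep$max_relative_overestimation, 0, tolerance = 1e-9)
  expect_equal(rep$max_absolute_overestimation, 0, tolerance = 1e-12)
  expect_equal(rep$underestimation_count, 0L)
  expect_equal(rep$seed, 5L)
})

test_that("the S_diag overestimation term is exactly constant at unit power", {
  set <- random_sar_set(60, 4, seed = 9)
  d <- worst_case_sar(set)
  model <- overestimation_model("diag", 0.3, Z = build_s_diag(set))
  B <- random_unit_power_vectors(200, 4, seed = 6)
  omega <- sarvop:::evaluate_term_many(model, B)
  expect_equal(omega, rep(0.3 * d, 200), tolerance = 1e-12)
})

test_that("underestimating VOP sets raise a hard safety error", {
  set <- random_sar_set(50, 3, seed = 14)
  # deliberately broken "result": only the weakest voxel kept, no slack
  lam <- sarvop:::lambda_range(set)[, 2]
  weakest <- which.min(lam)
  broken <- structure(
    list(vop_indices = set$voxel_ids[weakest],
         vop_matrices = list(voxel_matrix(set, weakest)),
         vop_flat = set$flat[weakest, , drop = FALSE],
         model = overestimation_model("global", 0, Z = 0 * set$global_matrix),
         config = compression_config(epsilon_g = 0),
         strategy_tag = "global", statuses = NULL, certificates = NULL,
         witnesses = list(), n_voxels_in = 50L),
    class = "vop_result")
  B <- random_unit_power_vectors(100, 3, seed = 2)
  expect_error(evaluate_compression(set, broken, B),
               class = "sarvop_safety_error")
  expect_error(evaluate_compression(set, broken, B), "SAFETY")
})

test_that("relative overestimation is invariant under a global SAR rescale", {
  set <- random_sar_set(80, 3, seed = 21)
  model <- overestimation_model("global", 0.1, Z = set$global_matrix)
  res <- compress(set, model, compression_config(epsilon_g = 0.1, seed = 1))
  B <- random_unit_power_vectors(2000, 3, seed = 7)
  r1 <- evaluate_compression(set, res, B)

  k <- 37.5
  set2 <- sar_matrix_set(structure(k * set$flat, n_channels = 3L),
                         global_matrix = k * set$global_matrix)
  model2 <- overestimation_model("global", 0.1, Z = set2$global_matrix)
  res2 <- compress(set2, model2, compression_config(epsilon_g = 0.1, seed = 1))
  r2 <- evaluate_compression(set2, res2, B)
  expect_equal(r2$max_relative_overestimation, r1$max_relative_overestimation,
               tolerance = 1e-9)
  expect_equal(r2$max_absolute_overestimation, k * r1$max_absolute_overestimation,
               tolerance = 1e-9)
})

test_that("absolute overestimation never exceeds eps_G * lambda_max(Z) at unit power", {
  set <- random_sar_set(100, 4, seed = 23)
  B <- random_unit_power_vectors(3000, 4, seed = 8)
  for (strategy in c("global", "diag")) {
    model <- build_model(set, strategy, epsilon_g = 0.2)
    res <- compress(set, model, compression_config(epsilon_g = 0.2, seed = 1))
    rep <- evaluate_compression(set, res, B)
    lam_z <- max(eigen(model$Z, symmetric = TRUE, only.values = TRUE)$values)
    expect_lte(rep$max_absolute_overestimation, 0.2 * lam_z * (1 + 1e-9))
  }
})

test_that("chunked evaluation is bit-identical across chunk sizes", {
  set <- random_sar_set(64, 4, seed = 27)
  model <- overestimation_model("diag", 0.2, Z = build_s_diag(set))
  res <- compress(set, model, compression_config(epsilon_g = 0.2, seed = 1))
  B <- random_unit_power_vectors(999, 4, seed = 12)
  r_all <- evaluate_compression(set, res, B, chunk_size = 2048L)
  r_tiny <- evaluate_compression(set, res, B, chunk_size = 17L)
  expect_identical(r_all$actual_sar, r_tiny$actual_sar)
  expect_identical(r_all$vop_sar, r_tiny$vop_sar)
  expect_identical(r_all$max_relative_overestimation,
                   r_tiny$max_relative_overestimation)
})

test_that("comparison curves cover the grid and scaled copies need one VOP", {
  S <- random_psd(3)
  copies <- sar_matrix_set(lapply(c(1, 0.8, 0.6, 0.4), function(a) a * S),
                           global_matrix = S)
  curves <- comparison_curve(copies, c("global", "diag"), epsilon_grid = 0.1,
                             n_vectors = 200, probe_seed = 2)
  expect_equal(nrow(curves), 2L)
  expect_true(all(curves$n_vops == 1L))

  set <- small_phantom(grid = c(8L, 8L, 8L))
  curves2 <- comparison_curve(set, "global", epsilon_grid = c(0.05, 0.2, 0.6),
                              seeds = 1:3, n_vectors = 500, probe_seed = 2)
  expect_equal(nrow(curves2), 9L)
  # per curve, rows are sorted by n_vops and counts shrink with epsilon
  for (s in 1:3) {
    cs <- curves2[curves2$seed == s, ]
    expect_false(is.unsorted(cs$n_vops))
    expect_true(all(diff(cs$epsilon_g[order(cs$n_vops)]) <= 0))
  }
  m <- compare_at_matched_vops(curves2, "global", "global")
  expect_equal(m$rel_a, m$rel_b)
})
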