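# Overestimation matrices and terms for the four strategies.

test_that("build_s_diag puts the worst-case SAR on the diagonal", {
  expect_equal(build_s_diag(sar_matrix_set(list(diag(2) + 0i))), diag(2) + 0i)
  expect_equal(build_s_diag(sar_matrix_set(list(diag(c(3, 1)) + 0i,
                                                diag(c(1, 2)) + 0i))),
               diag(c(3, 3)) + 0i)
  rnd <- random_sar_set(40, 4, seed = 2)
  d <- Re(build_s_diag(rnd)[1, 1])
  oracle <- max(vapply(seq_len(40), function(v)
    max(eigen(voxel_matrix(rnd, v), symmetric = TRUE, only.values = TRUE)$values),
    numeric(1)))
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("build_s_global_approx is a weight-normalized sum", {
  S <- random_psd(3)
  two <- sar_matrix_set(list(S, S))
  expect_equal(unname(build_s_global_approx(two)), S, ignore_attr = TRUE,
               tolerance = 1e-14)
  expect_equal(matrix(build_s_global_approx(two, c(0, 1)), 3, 3), S,
               tolerance = 1e-14)
  expect_error(build_s_global_approx(two, c(-1, 2)), "nonnegative")

  rnd <- random_sar_set(25, 4, seed = 3, global = FALSE)
  w <- sarvop:::with_local_seed(4, runif(25))
  oracle <- Reduce(`+`, lapply(seq_len(25), function(v)
    w[v] * voxel_matrix(rnd, v))) / sum(w)
  expect_equal(matrix(build_s_global_approx(rnd, w), 4, 4), oracle,
               tolerance = 1e-12)
})

test_that("select_R uses the closed form and caps the rescaled ratio at 10", {
  expect_equal(select_R(c(2, 2, 2)), 1)
  expect_equal(select_R(c(1, 5)), 1)
  R <- select_R(c(1, 1e4))
  expect_equal(R, 4)
  expect_equal((1e4 / 1)^(1 / R), 10, tolerance = 1e-12)
  expect_error(select_R(c(1, 0)), "positive")
  expect_error(select_R(c(-1, 2)), "positive")
})

test_that("build_s_local reduces to per-axis maxima for commuting diagonal sets", {
  # diagonal matrices: eigenvectors of S_pre are the coordinate axes, so the
  # eigenvector SAR step is an exhaustive per-axis max, verifiable directly
  mats <- list(diag(c(4, 1, 2)) + 0i, diag(c(1, 3, 1)) + 0i,
               diag(c(2, 2, 5)) + 0i)
  set <- sar_matrix_set(mats, global_matrix = Reduce(`+`, mats) / 3)
  bl <- build_s_local(set, subset_fraction = 1, pre_epsilon = 0.2,
                      seed = 1, R = 1)
  axis_max <- apply(vapply(mats, function(m) Re(diag(m)), numeric(3)), 1, max)
  expect_equal(sort(Re(diag(bl$s_local))), sort(axis_max), tolerance = 1e-10)
  expect_lt(max(abs(bl$s_local - diag(diag(bl$s_local)))), 1e-10)
})

test_that("S_local is Hermitian PSD with eigenvalue ratio <= 10 under automatic R", {
  set <- small_phantom()
  bl <- build_s_local(set, subset_fraction = 0.05, seed = 3)
  expect_hermitian(bl$s_local)
  ev <- eigen(bl$s_local, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lte(max(ev) / min(ev), 10 * (1 + 1e-12))
  expect_equal(max(bl$record$d) / min(bl$record$d), max(ev) / min(ev),
               tolerance = 1e-9)
  # eigenvector columns are orthonormal unit-power vectors
  V <- bl$record$eigvecs
  expect_lt(max(abs(Conj(t(V)) %*% V - diag(ncol(V)))), 1e-10)
  expect_equal(bl$record$d, bl$record$eig_sars^(1 / bl$record$R),
               tolerance = 1e-12)
})

test_that("evaluate_term matches direct recomputation for every kind", {
  set.seed(51)
  n <- 4
  Z <- random_psd(n)
  G <- random_psd(n)
  pre <- lapply(1:3, function(i) random_psd(n))
  b <- complex(real = rnorm(n), imaginary = rnorm(n))
  b <- b / sqrt(vector_power(b))

  m_g <- overestimation_model("global", 0.07, Z = Z)
  expect_equal(evaluate_term(m_g, b), 0.07 * quadratic_form(b, Z),
               tolerance = 1e-12)

  # diag: exactly constant for unit-power vectors
  d <- 2.5
  m_d <- overestimation_model("diag", 0.1, Z = diag(rep(d + 0i, n)))
  for (i in 1:5) {
    bb <- random_unit_power_vectors(1, n, seed = i)[, 1]
    expect_equal(evaluate_term(m_d, bb), 0.1 * d, tolerance = 1e-12)
  }

  m_2 <- overestimation_model("double", 0.2, pre_vops = pre,
                              epsilon_g_pre = 0.15, global_matrix = G)
  oracle <- 0.2 * (max(vapply(pre, function(S) quadratic_form(b, S), numeric(1))) +
                   0.15 * quadratic_form(b, G))
  expect_equal(evaluate_term(m_2, b), oracle, tolerance = 1e-12)

  # single pre-VOP with epsilon_g_pre = 0 collapses to a plain scaled max
  m_1 <- overestimation_model("double", 0.2, pre_vops = pre[1],
                              epsilon_g_pre = 0, global_matrix = G)
  expect_equal(evaluate_term(m_1, b), 0.2 * quadratic_form(b, pre[[1]]),
               tolerance = 1e-12)

  # |alpha|^2 scaling for each kind
  for (m in list(m_g, m_d, m_2))
    expect_equal(evaluate_term(m, (1 + 2i) * b), 5 * evaluate_term(m, b),
                 tolerance = 1e-12)
})

test_that("overestimation_model rejects malformed field combinations", {
  Z <- random_psd(3)
  expect_error(overestimation_model("double", 0.1, Z = Z), "pre_vops")
  expect_error(overestimation_model("global", 0.1), "requires the Z matrix")
  expect_error(overestimation_model("global", -0.1, Z = Z), "nonnegative")
  expect_error(overestimation_model("double", 0.1, pre_vops = list(Z)),
               "epsilon_g_pre")
})

test_that("S_local tracks actual local SAR better than S_global on hot-spot fields", {
  # qualitative reproduction: on sets with distinct per-element hot spots
  # the S_local overestimation term correlates more strongly with actual
  # maximum local SAR than the S_global term does
  for (layout in c("local", "remote")) {
    set <- generate_sar_set(array_phantom_spec(layout = layout))
    bl <- build_s_local(set, seed = 1)
    m_loc <- overestimation_model("local", 0.1, Z = bl$s_local)
    m_glo <- overestimation_model("global", 0.1, Z = set$global_matrix)
    B <- random_unit_power_vectors(2000, 8, seed = 9)
    act <- sarvop:::actual_sar_max(set, B)
    r_loc <- cor(sarvop:::evaluate_term_many(m_loc, B), act)
    r_glo <- cor(sarvop:::evaluate_term_many(m_glo, B), act)
    expect_gt(r_loc, r_glo, label = sprintf("%s-layout S_local correlation", layout))
  }
})
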