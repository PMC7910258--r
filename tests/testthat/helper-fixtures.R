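# In-code fixtures shared across the suite.

# one random Hermitian PSD matrix (Wishart-style, scaled)
random_psd <- function(n, scale = 1) {
  A <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  scale * (A %*% Conj(t(A))) / n
}

# a sar_matrix_set of independent random PSD matrices (no spatial structure)
random_sar_set <- function(n_vox, n_ch, seed = 1, scale = 1, global = TRUE) {
  sarvop:::with_local_seed(seed, {
    mats <- lapply(seq_len(n_vox), function(i)
      random_psd(n_ch, scale * runif(1, 0.1, 1)))
    g <- if (global) Reduce(`+`, mats) / n_vox
    sar_matrix_set(mats, global_matrix = g)
  })
}

# small synthetic phantom, cached per test run
small_phantom <- local({
  cache <- list()
  function(layout = "local", n_channels = 4L, grid = c(10L, 10L, 10L), seed = 1L) {
    key <- paste(layout, n_channels, paste(grid, collapse = "x"), seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_sar_set(array_phantom_spec(
        n_channels = n_channels, grid_shape = grid, seed = seed, layout = layout))
    cache[[key]]
  }
})

# a set with known extreme points: n_extreme well-separated PSD matrices
# plus certifiable convex combinations scaled strictly below 1
extreme_point_set <- function(n_extreme = 10, n_fill = 290, n_ch = 4, seed = 7) {
  sarvop:::with_local_seed(seed, {
    H <- lapply(seq_len(n_extreme), function(i) random_psd(n_ch))
    fill <- lapply(seq_len(n_fill), function(i) {
      jk <- sample.int(n_extreme, 2)
      w <- runif(1)
      runif(1, 0.2, 0.8) * (w * H[[jk[1]]] + (1 - w) * H[[jk[2]]])
    })
    mats <- c(H, fill)
    sar_matrix_set(mats, global_matrix = Reduce(`+`, mats) / length(mats))
  })
}

expect_hermitian <- function(S, tol = 1e-10) {
  expect_lt(max(abs(S - Conj(t(S)))), tol * max(abs(S), 1e-300))
}
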