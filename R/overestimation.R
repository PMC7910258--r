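# Overestimation terms omega(b) for the VOP condition
#
#   max_{v in V_all} b' S_v b  <=  max_{w in V_sub} b' S_w b + omega(b)
#
# Four interchangeable strategies:
#   global : omega(b) = eps_G * b' S_Global b          (reference)
#   diag   : omega(b) = eps_G * b' (d I) b, d = worst-case SAR (constant on
#            the unit-power sphere)
#   local  : omega(b) = eps_G * b' S_local b, with S_local a rough
#            local-SAR-tracking matrix built below
#   double : omega(b) = eps_G * (max_u b' S_u b + eps_G_pre * b' S_Global b)
#            over a small pre-calculated VOP set {S_u}

#' Overestimation model
#'
#' Bundles the overestimation term \eqn{\omega(b)} used by the compression
#' and evaluation routines. Matrix-term kinds (`"global"`, `"diag"`,
#' `"local"`) carry a single Hermitian PSD matrix `Z` and evaluate
#' \eqn{\varepsilon_G \, b' Z b}; kind `"double"` carries a small
#' pre-calculated VOP set and evaluates
#' \eqn{\varepsilon_G (\max_u b' S_u b + \varepsilon_{G,pre}\, b' S_{Global} b)}.
#'
#' @param kind one of `"global"`, `"diag"`, `"local"`, `"double"`.
#' @param epsilon_g overestimation factor \eqn{\varepsilon_G \ge 0}.
#' @param Z Hermitian PSD matrix for matrix-term kinds.
#' @param pre_vops list of Hermitian PSD matrices (the pre-calculated VOP
#'   set), required for kind `"double"`.
#' @param epsilon_g_pre overestimation factor used when the pre-calculated
#'   set was compressed, required for kind `"double"`.
#' @param global_matrix global-SAR matrix, required for kind `"double"`.
#' @param build_record optional provenance (e.g. the S_local build record).
#' @export
overestimation_model <- function(kind, epsilon_g, Z = NULL, pre_vops = NULL,
                                 epsilon_g_pre = NULL, global_matrix = NULL,
                                 build_record = NULL) {
  kind <- match.arg(kind, c("global", "diag", "local", "double"))
  if (!is.numeric(epsilon_g) || length(epsilon_g) != 1L || epsilon_g < 0)
    stop("epsilon_g must be a single nonnegative number", call. = FALSE)
  if (kind == "double") {
    if (is.null(pre_vops) || length(pre_vops) == 0L)
      stop("kind 'double' requires a nonempty pre_vops list", call. = FALSE)
    if (is.null(epsilon_g_pre) || epsilon_g_pre < 0)
      stop("kind 'double' requires epsilon_g_pre >= 0", call. = FALSE)
    if (is.null(global_matrix))
      stop("kind 'double' requires the global-SAR matrix", call. = FALSE)
    for (S in pre_vops) check_hermitian_psd(S, "pre-VOP matrix")
    check_hermitian_psd(global_matrix, "global_matrix")
    if (!is.null(Z)) stop("kind 'double' takes no Z matrix", call. = FALSE)
  } else {
    if (is.null(Z)) stop(sprintf("kind '%s' requires the Z matrix", kind), call. = FALSE)
    if (!is.null(pre_vops)) stop("matrix-term kinds take no pre_vops", call. = FALSE)
    check_hermitian_psd(Z, "Z")
  }
  structure(list(kind = kind, epsilon_g = epsilon_g, Z = Z,
                 pre_vops = pre_vops, epsilon_g_pre = epsilon_g_pre,
                 global_matrix = global_matrix, build_record = build_record),
            class = "overestimation_model")
}

#' @export
print.overestimation_model <- function(x, ...) {
  cat(sprintf("<overestimation_model> kind = %s, epsilon_g = %g", x$kind, x$epsilon_g))
  if (x$kind == "double")
    cat(sprintf(", %d pre-VOPs, epsilon_g_pre = %g", length(x$pre_vops), x$epsilon_g_pre))
  cat("\n")
  invisible(x)
}

#' Constant (diagonal) overestimation matrix
#'
#' Returns \eqn{d I} with `d` the worst-case SAR of the set, so that for any
#' unit-power excitation vector the overestimation term is exactly
#' \eqn{\varepsilon_G d}, independent of the vector.
#'
#' @param set a `sar_matrix_set`.
#' @return a diagonal SAR matrix.
#' @export
build_s_diag <- function(set) {
  if (n_voxels(set) == 0L) stop("empty SAR matrix set", call. = FALSE)
  d <- worst_case_sar(set)
  diag(complex(real = rep(d, set$n_channels)), set$n_channels)
}

#' Approximate global-SAR matrix from a set
#'
#' Weight-normalized sum of the members (uniform weights by default). Used
#' only when the container supplies no true global-SAR matrix; the result is
#' flagged `"approximate"`.
#'
#' @param set a `sar_matrix_set`.
#' @param weights optional nonnegative weights, one per voxel.
#' @export
build_s_global_approx <- function(set, weights = NULL) {
  nv <- n_voxels(set)
  if (is.null(weights)) weights <- rep(1, nv)
  if (length(weights) != nv) stop("weights length mismatch", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  w <- weights / sum(weights)
  v <- drop(crossprod(set$flat, as.complex(w)))
  out <- matrix(v, set$n_channels, set$n_channels)
  attr(out, "approximate") <- TRUE
  out
}

#' Exponential-scaling exponent for the S_local spectrum
#'
#' The eigenvector SAR values that become the eigenvalues of `S_local` can
#' span orders of magnitude; they are compressed by the power `1/R`. This
#' picks the smallest `R >= 1` such that the rescaled max/min ratio is at
#' most 10: in closed form `R = max(1, log10(max/min))`.
#'
#' @param eig_sars positive SAR values, one per eigenvector.
#' @return the exponent `R` (real, `>= 1`).
#' @export
select_R <- function(eig_sars) {
  if (length(eig_sars) == 0L || any(!is.finite(eig_sars)) || any(eig_sars <= 0))
    stop("eig_sars must be finite and strictly positive", call. = FALSE)
  max(1, log10(max(eig_sars) / min(eig_sars)))
}

#' Build the local-SAR-approximating overestimation matrix
#'
#' Pipeline: (i) draw a seeded random sample of `ceiling(subset_fraction *
#' n_vox)` voxels without replacement; (ii) compress the sample with the
#' global-SAR strategy at `pre_epsilon`; (iii) sum the resulting VOP matrices
#' into `S_pre`; (iv) eigendecompose `S_pre`; (v) for each eigenvector
#' compute the maximum local SAR over the *full* set; (vi) rescale those SAR
#' values by the power `1/R` with `R` from [select_R()] (or a forced value);
#' (vii) reassemble \eqn{S_{local} = V D V'}, Hermitian PSD with eigenvalue
#' ratio at most 10 under automatic `R`.
#'
#' Eigen-SAR values of (numerically) zero are floored at `1e-6` times the
#' maximum before rescaling; the build record flags when this happened.
#'
#' @param set a `sar_matrix_set` (with a global matrix, or one is
#'   approximated from the sample with a warning).
#' @param subset_fraction fraction of voxels to sample, in `(0, 1]`
#'   (default 0.01, i.e. the "1 % subsample").
#' @param pre_epsilon overestimation factor for the inner compression
#'   (default 0.2).
#' @param seed seed for the subsample and the inner compression.
#' @param R force the exponent instead of selecting it automatically.
#' @param config optional [compression_config()] overriding the inner
#'   compression settings (its `epsilon_g` is replaced by `pre_epsilon`).
#' @return list with `s_local` (the matrix) and `record` (an
#'   `s_local_build_record` with fields `subset_fraction`, `pre_epsilon`,
#'   `s_pre`, `eigvecs`, `eig_sars`, `R`, `d`, `floored`, `sample_ids`).
#' @export
build_s_local <- function(set, subset_fraction = 0.01, pre_epsilon = 0.2,
                          seed = 1L, R = NULL, config = NULL) {
  nv <- n_voxels(set)
  if (nv == 0L) stop("empty SAR matrix set", call. = FALSE)
  if (subset_fraction <= 0 || subset_fraction > 1)
    stop("subset_fraction must be in (0, 1]", call. = FALSE)
  if (pre_epsilon <= 0) stop("pre_epsilon must be > 0", call. = FALSE)
  m <- ceiling(subset_fraction * nv)
  if (m < 1L) stop("subsample smaller than one voxel", call. = FALSE)
  idx <- with_local_seed(seed, sample.int(nv, m))

  sub <- sar_matrix_set(structure(set$flat[idx, , drop = FALSE],
                                  n_channels = set$n_channels),
                        voxel_ids = set$voxel_ids[idx],
                        global_matrix = set$global_matrix,
                        validate = FALSE)
  sub$lambda <- lambda_range(set)[idx, , drop = FALSE]

  Zg <- if (!is.null(set$global_matrix)) set$global_matrix else {
    warning("set has no global-SAR matrix; using a uniform-weight approximation for the inner compression")
    build_s_global_approx(set)
  }
  if (is.null(config)) config <- compression_config(epsilon_g = pre_epsilon, seed = seed)
  config$epsilon_g <- pre_epsilon
  inner_model <- overestimation_model("global", epsilon_g = pre_epsilon, Z = Zg)
  inner <- compress(sub, inner_model, config)
  if (length(inner$vop_indices) == 0L)
    stop("inner compression yielded no VOPs", call. = FALSE)

  s_pre <- Reduce(`+`, inner$vop_matrices)
  s_pre <- (s_pre + Conj(t(s_pre))) / 2
  eg <- eigen(s_pre, symmetric = TRUE)
  V <- eg$vectors

  eig_sars <- vapply(seq_len(ncol(V)),
                     function(i) max_sar_over_set(V[, i], set)$value, numeric(1))
  floored <- eig_sars < 1e-6 * max(eig_sars)
  eig_sars_f <- pmax(eig_sars, 1e-6 * max(eig_sars))
  if (is.null(R)) R <- select_R(eig_sars_f)
  if (R < 1) stop("R must be >= 1", call. = FALSE)
  d <- eig_sars_f^(1 / R)

  s_local <- V %*% (d * Conj(t(V)))
  s_local <- (s_local + Conj(t(s_local))) / 2

  record <- structure(
    list(subset_fraction = subset_fraction, pre_epsilon = pre_epsilon,
         s_pre = s_pre, eigvecs = V, eig_sars = eig_sars_f, R = R, d = d,
         floored = any(floored), sample_ids = set$voxel_ids[idx],
         n_inner_vops = length(inner$vop_indices), seed = seed),
    class = "s_local_build_record")
  list(s_local = s_local, record = record)
}

#' Evaluate the overestimation term
#'
#' \eqn{\omega(b)}: for matrix-term kinds \eqn{\varepsilon_G b' Z b}; for the
#' Double VOP model \eqn{\varepsilon_G (\max_u b' S_u b +
#' \varepsilon_{G,pre} b' S_{Global} b)}. Always nonnegative.
#'
#' @param model an [overestimation_model()].
#' @param b complex excitation vector.
#' @return the real overestimation value (W/kg).
#' @export
evaluate_term <- function(model, b) {
  if (!inherits(model, "overestimation_model"))
    stop("model must be an overestimation_model", call. = FALSE)
  drop(evaluate_term_many(model, matrix(as.complex(b), ncol = 1L)))
}

# vectorized omega over the columns of B (channels x m)
evaluate_term_many <- function(model, B) {
  W <- qf_weights(B)
  if (model$kind == "double") {
    pre_flat <- flat_from_list(model$pre_vops)
    qu <- colmax(Re(pre_flat %*% W))
    qg <- Re(as.vector(as.vector(model$global_matrix) %*% W))
    model$epsilon_g * (qu + model$epsilon_g_pre * qg)
  } else {
    model$epsilon_g * Re(as.vector(as.vector(model$Z) %*% W))
  }
}
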