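# Core algebra on excitation vectors and Hermitian SAR matrices.
#
# A "SAR matrix" S_v is the Hermitian positive-semidefinite n_ch x n_ch
# matrix such that b' S_v b is the 10 g-averaged SAR (W/kg per unit input
# power) at voxel v for the complex excitation vector b. Internally a set of
# such matrices is stored as a flat stack: one column-major vectorised matrix
# per row (n_vox x n_ch^2), which turns bulk quadratic-form evaluation into a
# single complex matrix product.

HERMITIAN_RTOL <- 1e-10
PSD_RTOL <- 1e-10

# permutation mapping vec(S) -> vec(t(S)) for n x n matrices
transpose_perm <- function(n) as.vector(t(matrix(seq_len(n * n), n, n)))

flat_from_list <- function(matrices) {
  n <- nrow(matrices[[1L]])
  flat <- matrix(0i, length(matrices), n * n)
  for (v in seq_along(matrices)) {
    m <- matrices[[v]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop("all SAR matrices must be square with a common channel count", call. = FALSE)
    flat[v, ] <- as.vector(m)
  }
  storage.mode(flat) <- "complex"
  flat
}

#' Construct a set of 10 g-averaged SAR matrices
#'
#' The central data container: the uncompressed collection of per-voxel
#' Hermitian positive-semidefinite (PSD) SAR matrices of a multi-channel
#' transmit array, optionally together with the global-SAR matrix of the same
#' shape.
#'
#' Matrices are validated (and optionally symmetrized) on construction:
#' each matrix must be Hermitian within a relative tolerance of `1e-10` and
#' PSD in the sense that its smallest eigenvalue is at least
#' `-1e-10` times its largest. With `symmetrize = TRUE` each matrix is
#' replaced by `(S + S^H)/2` first, with a warning if the asymmetry exceeds
#' the tolerance; this is used when reading containers so that file
#' round-trip noise cannot break the PSD checks.
#'
#' @param matrices a list of complex `n_ch x n_ch` matrices, or a 3-D complex
#'   array with dimensions `c(n_ch, n_ch, n_vox)`.
#' @param voxel_ids integer identifiers, unique, one per matrix
#'   (default `seq_len(n_vox)`).
#' @param global_matrix optional Hermitian PSD `n_ch x n_ch` matrix giving
#'   global SAR as a quadratic form of the excitation vector.
#' @param metadata free-form provenance list.
#' @param symmetrize replace each matrix by its Hermitian part on input.
#' @param validate run the Hermitian/PSD invariant checks (default `TRUE`).
#' @return an object of class `sar_matrix_set`.
#' @export
sar_matrix_set <- function(matrices, voxel_ids = NULL, global_matrix = NULL,
                           metadata = list(), symmetrize = FALSE,
                           validate = TRUE) {
  if (is.array(matrices) && length(dim(matrices)) == 3L) {
    d <- dim(matrices)
    if (d[1L] != d[2L]) stop("matrix array must be n_ch x n_ch x n_vox", call. = FALSE)
    flat <- t(matrix(matrices, d[1L] * d[2L], d[3L]))
    n <- d[1L]
  } else if (is.list(matrices) && length(matrices) > 0L) {
    n <- nrow(matrices[[1L]])
    flat <- flat_from_list(matrices)
  } else if (is.matrix(matrices) && !is.null(attr(matrices, "n_channels"))) {
    n <- attr(matrices, "n_channels")
    flat <- matrices
    attr(flat, "n_channels") <- NULL
  } else {
    stop("matrices must be a nonempty list or a 3-D array", call. = FALSE)
  }
  storage.mode(flat) <- "complex"
  n_vox <- nrow(flat)
  if (is.null(voxel_ids)) voxel_ids <- seq_len(n_vox)
  voxel_ids <- as.integer(voxel_ids)
  if (length(voxel_ids) != n_vox) stop("voxel_ids length mismatch", call. = FALSE)
  if (anyDuplicated(voxel_ids)) stop("voxel_ids must be unique", call. = FALSE)

  tp <- transpose_perm(n)
  herm_flat <- Conj(flat[, tp, drop = FALSE])
  asym <- max(abs(flat - herm_flat))
  scale <- max(abs(flat), 1e-300)
  if (symmetrize) {
    if (asym > HERMITIAN_RTOL * scale)
      warning(sprintf("symmetrizing SAR matrices: relative asymmetry %.3g exceeds tolerance %.1g",
                      asym / scale, HERMITIAN_RTOL))
    flat <- (flat + herm_flat) / 2
  } else if (validate && asym > HERMITIAN_RTOL * scale) {
    stop(sprintf("SAR matrices are not Hermitian: relative asymmetry %.3g (tolerance %.1g)",
                 asym / scale, HERMITIAN_RTOL), call. = FALSE)
  }

  lambda <- NULL
  if (validate) {
    lambda <- cpp_lambda_range(flat, n)
    bad <- lambda[, 1L] < -PSD_RTOL * pmax(lambda[, 2L], 1e-300)
    if (any(bad))
      stop(sprintf("%d SAR matrices are not positive semidefinite (first offending voxel_id %d, lambda_min %.3g)",
                   sum(bad), voxel_ids[which(bad)[1L]], min(lambda[bad, 1L])), call. = FALSE)
  }

  if (!is.null(global_matrix)) {
    global_matrix <- as.matrix(global_matrix)
    storage.mode(global_matrix) <- "complex"
    if (nrow(global_matrix) != n || ncol(global_matrix) != n)
      stop("global_matrix has the wrong channel count", call. = FALSE)
    check_hermitian_psd(global_matrix, "global_matrix")
  }

  structure(
    list(flat = flat, n_channels = n, voxel_ids = voxel_ids,
         global_matrix = global_matrix, lambda = lambda, metadata = metadata),
    class = "sar_matrix_set")
}

check_hermitian_psd <- function(S, what = "matrix") {
  scale <- max(abs(S), 1e-300)
  if (max(abs(S - Conj(t(S)))) > HERMITIAN_RTOL * scale)
    stop(sprintf("%s is not Hermitian", what), call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -PSD_RTOL * max(max(ev), 1e-300))
    stop(sprintf("%s is not positive semidefinite (lambda_min = %.3g)", what, min(ev)),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.sar_matrix_set <- function(x, ...) {
  cat(sprintf("<sar_matrix_set> %d voxels x %d channels%s\n",
              n_voxels(x), x$n_channels,
              if (is.null(x$global_matrix)) "" else ", with global-SAR matrix"))
  if (!is.null(x$lambda))
    cat(sprintf("  worst-case SAR: %.6g W/kg per unit power\n", max(x$lambda[, 2L])))
  invisible(x)
}

#' Number of voxels in a SAR matrix set
#' @param set a `sar_matrix_set`.
#' @export
n_voxels <- function(set) nrow(set$flat)

#' Extract one SAR matrix by position
#' @param set a `sar_matrix_set`.
#' @param i position (row index) in the set.
#' @return a complex `n_ch x n_ch` matrix.
#' @export
voxel_matrix <- function(set, i) {
  matrix(set$flat[i, ], set$n_channels, set$n_channels)
}

# per-voxel smallest/largest eigenvalues, cached on the set
lambda_range <- function(set) {
  if (!is.null(set$lambda)) return(set$lambda)
  cpp_lambda_range(set$flat, set$n_channels)
}

#' Power of an excitation vector
#'
#' The squared 2-norm of the complex channel weights. "Unit power"
#' excitation vectors have power 1; all constant-overestimation statements
#' in the package are relative to this normalization.
#'
#' @param b complex excitation vector.
#' @export
vector_power <- function(b) sum(Mod(b)^2)

#' SAR quadratic form
#'
#' Evaluates `Re(b' S b)` (with `b'` the conjugate transpose), the SAR in
#' W/kg delivered by excitation vector `b` at the voxel described by `S`.
#' For a Hermitian `S` the form is real; the imaginary residue is asserted
#' to be numerical noise (`< 1e-9` relative) before being discarded.
#'
#' @param b complex excitation vector of length `n_ch`.
#' @param S complex Hermitian `n_ch x n_ch` SAR matrix.
#' @return the real SAR value.
#' @export
quadratic_form <- function(b, S) {
  b <- as.complex(b)
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("S must be a square matrix", call. = FALSE)
  if (length(b) != nrow(S))
    stop(sprintf("dimension mismatch: vector of length %d vs %d-channel matrix",
                 length(b), nrow(S)), call. = FALSE)
  val <- drop(Conj(b) %*% S %*% b)
  if (abs(Im(val)) >= 1e-9 * (abs(val) + .Machine$double.eps))
    stop("quadratic form has a non-negligible imaginary part; S is not Hermitian",
         call. = FALSE)
  Re(val)
}

# Quadratic-form weight vectors: column j of the result is
# vec(Conj(b_j) %o% b_j), so that Re(flat %*% qf_weights(B)) gives the SAR of
# every matrix in the stack at every excitation vector in B (channels x m).
qf_weights <- function(B) {
  if (!is.matrix(B)) B <- matrix(B, ncol = 1L)
  n <- nrow(B)
  Conj(B)[rep(seq_len(n), times = n), , drop = FALSE] *
    B[rep(seq_len(n), each = n), , drop = FALSE]
}

#' Maximum SAR over a matrix set
#'
#' The largest quadratic-form SAR over all voxels in the set for a given
#' excitation vector, together with the voxel at which it is attained (ties
#' broken toward the smallest `voxel_id` for deterministic reports).
#'
#' @param b complex excitation vector.
#' @param set a `sar_matrix_set`.
#' @return list with `value` (W/kg) and `voxel_id`.
#' @export
max_sar_over_set <- function(b, set) {
  if (n_voxels(set) == 0L) stop("empty SAR matrix set", call. = FALSE)
  if (length(b) != set$n_channels)
    stop(sprintf("dimension mismatch: vector of length %d vs %d channels",
                 length(b), set$n_channels), call. = FALSE)
  q <- Re(set$flat %*% qf_weights(b))
  m <- max(q)
  list(value = m, voxel_id = min(set$voxel_ids[q == m]))
}

#' Worst-case SAR of a matrix set
#'
#' The supremum over unit-power excitation vectors of the maximum local SAR,
#' i.e. the largest eigenvalue over all matrices in the set.
#'
#' @param set a `sar_matrix_set`.
#' @return real worst-case SAR (W/kg per unit power).
#' @export
worst_case_sar <- function(set) {
  if (n_voxels(set) == 0L) stop("empty SAR matrix set", call. = FALSE)
  max(lambda_range(set)[, 2L])
}

#' Arithmetic cost of one VOP SAR evaluation
#'
#' Complex-scalar operation counts for evaluating `b'(S b)` as a dense
#' matrix-vector product followed by an inner product: `n^2 + n`
#' multiplications and `n^2 - 1` additions. This two-stage dense convention
#' (no Hermitian-symmetry tricks) is the one used when quoting per-VOP
#' supervision cost.
#'
#' @param n_channels number of transmit channels (>= 1).
#' @return list with integer `multiplications` and `additions`.
#' @export
op_count <- function(n_channels) {
  n <- as.integer(n_channels)
  if (is.na(n) || n < 1L) stop("n_channels must be >= 1", call. = FALSE)
  list(multiplications = n * n + n, additions = n * n - 1L)
}
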