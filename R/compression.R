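# Greedy VOP compression with interchangeable overestimation terms.
#
# Voxels are visited in descending order of largest eigenvalue. The first
# voxel always becomes a VOP; each later voxel is either certified dominated
# (a nonnegative, L1-normalized coefficient vector c proving
# S_v <= sum_w c_w S_w + overestimation matrix as a PSD inequality) and
# discarded, or added to the VOP set. Certified voxels stay certified as the
# VOP set grows (new coefficients default to zero), so no re-checking is
# needed; safety of the final bound follows voxel by voxel.

#' Compression configuration
#'
#' @param epsilon_g overestimation factor \eqn{\varepsilon_G > 0} (0 is
#'   allowed but degenerates to exact-domination pruning when the term
#'   matrix is zero).
#' @param max_coef_iterations cap on outer iterations of the per-voxel
#'   coefficient search (PSD check / witness check / coefficient update);
#'   when exceeded the voxel is added to the VOP set, preserving safety.
#' @param psd_tolerance relative floor for the smallest eigenvalue of the
#'   certificate matrix `P`: a voxel is accepted as dominated when
#'   `lambda_min(P) >= -psd_tolerance * lambda_max(S_v)`. Must lie in
#'   `[0, 1e-6]`.
#' @param seed base seed; each voxel's randomized search runs on its own
#'   substream derived from this and the voxel id, so results do not depend
#'   on how much work earlier voxels needed.
#' @param coef_update_rule `"paper_random"` perturbs one random coefficient
#'   at a time (uniform on `[0, 2c + 1/len]`, then L1 renormalization),
#'   alternating between the VOP and pre-VOP coefficient sets;
#'   `"greedy_argmax"` instead jumps all mass onto the currently most
#'   violated member, which resolves the failed witness check in one
#'   deterministic move and is faster.
#' @param inner_factor randomized proposals per coefficient per outer
#'   iteration (the inner loop length is `inner_factor * length(c)`).
#' @export
compression_config <- function(epsilon_g, max_coef_iterations = 30L,
                               psd_tolerance = 1e-9, seed = 1L,
                               coef_update_rule = c("paper_random", "greedy_argmax"),
                               inner_factor = 5L) {
  coef_update_rule <- match.arg(coef_update_rule)
  if (!is.numeric(epsilon_g) || epsilon_g < 0)
    stop("epsilon_g must be >= 0", call. = FALSE)
  if (psd_tolerance < 0 || psd_tolerance > 1e-6)
    stop("psd_tolerance must lie in [0, 1e-6]", call. = FALSE)
  if (max_coef_iterations < 0) stop("max_coef_iterations must be >= 0", call. = FALSE)
  structure(list(epsilon_g = epsilon_g,
                 max_coef_iterations = as.integer(max_coef_iterations),
                 psd_tolerance = psd_tolerance, seed = as.integer(seed),
                 coef_update_rule = coef_update_rule,
                 inner_factor = as.integer(inner_factor)),
            class = "compression_config")
}

# Fixed pieces of the overestimation term for the dominance kernel:
# matrix kinds -> Tmat = eps_G * Z; double -> pre_flat rows
# A_u = eps_G * (S_u + eps_G_pre * S_Global), Tmat unused.
term_pieces <- function(model, n) {
  if (model$kind == "double") {
    g <- as.vector(model$global_matrix)
    pre_flat <- flat_from_list(model$pre_vops)
    pre_flat <- model$epsilon_g *
      (pre_flat + matrix(model$epsilon_g_pre * g, nrow(pre_flat), n * n, byrow = TRUE))
    list(Tmat = matrix(0i, n, n), pre_flat = pre_flat)
  } else {
    list(Tmat = model$epsilon_g * model$Z, pre_flat = matrix(0i, 0L, n * n))
  }
}

voxel_seed <- function(config_seed, voxel_id) {
  (as.numeric(config_seed) * 7919 + as.numeric(voxel_id) * 104729) %% 2147483647
}

#' Dominance test of one voxel against a VOP set
#'
#' Runs the iterative certificate search for a single candidate matrix:
#' (1) initialize each coefficient set to equal values with L1 norm 1;
#' (2) if `P = sum_w c_w S_w + term - S_v` is PSD (within tolerance), the
#' voxel is `"bounded"` and `c` is its certificate; (3) otherwise take the
#' eigenvector `b` of the smallest eigenvalue of `P`; if `b` violates the
#' scalar VOP condition the voxel is `"unbounded"` with witness `b`;
#' (4) otherwise re-weight the coefficients to make `b' P b` nonnegative and
#' iterate; (5) after `max_coef_iterations` outer iterations the result is
#' `"inconclusive"` (the caller should add the voxel, which preserves
#' safety).
#'
#' @param S_v candidate Hermitian PSD matrix.
#' @param vops list of current VOP matrices (nonempty).
#' @param model an [overestimation_model()].
#' @param config a [compression_config()].
#' @param seed RNG seed for the randomized search (default: derived from the
#'   config seed).
#' @return list with `status` (`"bounded"`, `"unbounded"`, `"inconclusive"`),
#'   `c_vop`, `c_pre`, `witness`, `iterations`.
#' @export
dominance_test <- function(S_v, vops, model, config, seed = NULL) {
  if (length(vops) == 0L) stop("vops must be nonempty", call. = FALSE)
  n <- nrow(S_v)
  pieces <- term_pieces(model, n)
  vop_flat <- flat_from_list(vops)
  lam_ref <- max(eigen(S_v, symmetric = TRUE, only.values = TRUE)$values)
  if (is.null(seed)) seed <- voxel_seed(config$seed, 1L)
  res <- cpp_dominance_search(S_v, vop_flat, pieces$pre_flat, pieces$Tmat,
                              lam_ref, config$psd_tolerance,
                              config$max_coef_iterations, config$inner_factor,
                              if (config$coef_update_rule == "greedy_argmax") 1L else 0L,
                              seed)
  list(status = c("bounded", "unbounded", "inconclusive")[res$status + 1L],
       c_vop = as.numeric(res$c_vop), c_pre = as.numeric(res$c_pre),
       witness = if (!is.null(res$witness)) drop(res$witness),
       iterations = res$iterations)
}

#' Compress a SAR matrix set into virtual observation points
#'
#' The greedy compression: voxels are visited in descending order of largest
#' eigenvalue (ties toward the smaller voxel id); each voxel is either
#' certified dominated by the current VOPs plus the overestimation term and
#' discarded, or enters the VOP set. The returned bound
#' `max_w b' S_w b + omega(b)` upper-bounds `max_v b' S_v b` for every
#' excitation vector.
#'
#' A growing pool of witness vectors from previously added VOPs is used as a
#' cheap scalar pre-screen: a voxel whose SAR at any pooled witness already
#' exceeds the bound there can have no PSD certificate and is added
#' directly. Because every voxel's randomized search runs on its own RNG
#' substream, the pre-screen changes only the work done, never which voxels
#' end up certified.
#'
#' @param set a `sar_matrix_set`.
#' @param model an [overestimation_model()].
#' @param config a [compression_config()]; its `epsilon_g` must match the
#'   model's.
#' @param keep_certificates store the per-voxel dominance certificates
#'   (off by default for size).
#' @param use_witness_pool enable the scalar pre-screen (default `TRUE`).
#' @param abort_above stop early (returning a result flagged `aborted`) as
#'   soon as more than this many VOPs have been found; used by the
#'   pre-VOP auto-tuner, which only needs to know that a factor is too
#'   small.
#' @param verbose print progress.
#' @return an object of class `vop_result`: `vop_indices` (voxel ids),
#'   `vop_matrices`, `model`, `config`, `strategy_tag`, `statuses`,
#'   `certificates` (when requested), `witnesses`.
#' @export
compress <- function(set, model, config, keep_certificates = FALSE,
                     use_witness_pool = TRUE, abort_above = Inf,
                     verbose = FALSE) {
  nv <- n_voxels(set)
  if (nv == 0L) stop("empty SAR matrix set", call. = FALSE)
  n <- set$n_channels
  if (model$kind != "double" && nrow(model$Z) != n)
    stop("model and set have incompatible channel counts", call. = FALSE)
  if (model$kind == "double" && nrow(model$pre_vops[[1L]]) != n)
    stop("model and set have incompatible channel counts", call. = FALSE)
  if (abs(model$epsilon_g - config$epsilon_g) > 1e-12 * max(model$epsilon_g, 1))
    stop("config$epsilon_g does not match model$epsilon_g", call. = FALSE)
  if (model$kind != "double" && model$epsilon_g * max(abs(model$Z)) == 0)
    warning("zero overestimation term: compression degenerates to exact-domination pruning")

  pieces <- term_pieces(model, n)
  lam <- lambda_range(set)
  ord <- order(-lam[, 2L], set$voxel_ids)
  rule <- if (config$coef_update_rule == "greedy_argmax") 1L else 0L

  vop_rows <- integer(0)              # row indices into set$flat
  vop_flat <- matrix(0i, 0L, n * n)
  statuses <- character(nv)
  certificates <- if (keep_certificates) vector("list", nv)
  witnesses <- list()

  # witness pool: weight vectors, fixed omega at each witness, running max
  # of b' S_w b over the current VOPs at each witness
  pool_W <- matrix(0i, n * n, 0L)
  pool_omega <- numeric(0)
  pool_maxq <- numeric(0)
  tol_abs_of <- function(l) config$psd_tolerance * max(l, 0)

  add_vop <- function(row) {
    vop_rows[length(vop_rows) + 1L] <<- row
    vop_flat <<- rbind(vop_flat, set$flat[row, , drop = FALSE])
    if (ncol(pool_W) > 0L)
      pool_maxq <<- pmax(pool_maxq, Re(as.vector(set$flat[row, , drop = FALSE] %*% pool_W)))
  }
  add_witness <- function(b) {
    w <- qf_weights(b)
    pool_W <<- cbind(pool_W, w)
    om <- if (model$kind == "double") {
      max(Re(pieces$pre_flat %*% w))
    } else Re(drop(as.vector(pieces$Tmat) %*% w))
    pool_omega <<- c(pool_omega, om)
    pool_maxq <<- c(pool_maxq, if (length(vop_rows))
      max(Re(vop_flat %*% w)) else -Inf)
  }

  aborted <- FALSE
  for (k in seq_len(nv)) {
    if (length(vop_rows) > abort_above) { aborted <- TRUE; break }
    row <- ord[k]
    vid <- set$voxel_ids[row]
    if (length(vop_rows) == 0L) {
      add_vop(row)
      statuses[row] <- "vop_first"
      next
    }
    if (use_witness_pool && ncol(pool_W) > 0L) {
      qv <- Re(as.vector(set$flat[row, , drop = FALSE] %*% pool_W))
      hit <- qv > pool_maxq + pool_omega + tol_abs_of(lam[row, 2L])
      if (any(hit)) {
        # no PSD certificate can exist: the scalar condition already fails
        b <- NULL
        add_vop(row)
        statuses[row] <- "vop_pool"
        next
      }
    }
    res <- cpp_dominance_search(voxel_matrix(set, row), vop_flat,
                                pieces$pre_flat, pieces$Tmat,
                                lam[row, 2L], config$psd_tolerance,
                                config$max_coef_iterations, config$inner_factor,
                                rule, voxel_seed(config$seed, vid))
    if (res$status == 0L) {
      statuses[row] <- "certified"
      if (keep_certificates)
        certificates[[row]] <- list(voxel_id = vid,
                                    c_vop = as.numeric(res$c_vop),
                                    c_pre = as.numeric(res$c_pre),
                                    n_vops_at_cert = length(vop_rows))
    } else {
      add_vop(row)
      if (res$status == 1L) {
        statuses[row] <- "vop_witness"
        b <- drop(res$witness)
        witnesses[[as.character(vid)]] <- b
        add_witness(b)
      } else {
        statuses[row] <- "vop_inconclusive"
      }
    }
    if (verbose && k %% 1000L == 0L)
      message(sprintf("  %d/%d voxels, %d VOPs", k, nv, length(vop_rows)))
  }

  structure(
    list(vop_indices = set$voxel_ids[vop_rows],
         vop_matrices = lapply(vop_rows, function(r) voxel_matrix(set, r)),
         vop_flat = vop_flat,
         model = model, config = config,
         strategy_tag = model$kind,
         statuses = statuses,
         certificates = if (keep_certificates) {
           certificates[!vapply(certificates, is.null, logical(1))]
         },
         witnesses = witnesses,
         aborted = aborted,
         n_voxels_in = nv),
    class = "vop_result")
}

#' @export
print.vop_result <- function(x, ...) {
  cat(sprintf("<vop_result> %d VOPs from %d voxels (strategy %s, epsilon_g = %g)\n",
              length(x$vop_indices), x$n_voxels_in, x$strategy_tag,
              x$model$epsilon_g))
  invisible(x)
}

#' Pre-compute a small VOP set for the Double VOP overestimation term
#'
#' Compresses the set with the global-SAR strategy at `epsilon_g_pre`; with
#' `auto_tune` the factor is doubled (up to 12 times) until the VOP count is
#' at most `target_count` — mirroring the choice of the factor "to obtain 10
#' or fewer" pre-calculated VOPs.
#'
#' @param set a `sar_matrix_set`.
#' @param epsilon_g_pre starting overestimation factor (> 0).
#' @param target_count maximum acceptable pre-VOP count (default 10).
#' @param auto_tune double `epsilon_g_pre` until the target is met.
#' @param config optional [compression_config()] template.
#' @return list with `pre_vops` (matrices), `epsilon_g_pre` (the factor
#'   actually used), `result` (the `vop_result`), and `trace`
#'   (a data frame of the doubling trace).
#' @export
precompute_vops <- function(set, epsilon_g_pre = 0.2, target_count = 10L,
                            auto_tune = TRUE, config = NULL) {
  if (n_voxels(set) == 0L) stop("empty SAR matrix set", call. = FALSE)
  if (epsilon_g_pre <= 0) stop("epsilon_g_pre must be > 0", call. = FALSE)
  Zg <- if (!is.null(set$global_matrix)) set$global_matrix else {
    warning("set has no global-SAR matrix; using a uniform-weight approximation")
    build_s_global_approx(set)
  }
  if (is.null(config)) config <- compression_config(epsilon_g = epsilon_g_pre)
  eps <- epsilon_g_pre
  trace <- data.frame(epsilon_g_pre = numeric(0), n_vops = integer(0))
  for (i in seq_len(13L)) {
    config$epsilon_g <- eps
    model <- overestimation_model("global", epsilon_g = eps, Z = Zg)
    res <- compress(set, model, config,
                    abort_above = if (auto_tune) target_count else Inf)
    trace <- rbind(trace, data.frame(epsilon_g_pre = eps,
                                     n_vops = length(res$vop_indices)))
    if (!auto_tune || (!res$aborted && length(res$vop_indices) <= target_count))
      return(list(pre_vops = res$vop_matrices, epsilon_g_pre = eps,
                  result = res, trace = trace))
    eps <- eps * 2
  }
  stop(sprintf("auto-tune failed: still more than %d pre-VOPs after 12 doublings",
               target_count), call. = FALSE)
}

#' Bake VOPs into directly evaluable matrix collections
#'
#' For matrix-term strategies the overestimation matrix is folded into each
#' VOP (`S_w + eps_G Z`), so a supervision system evaluates a single
#' collection whose per-vector maximum equals the full bound exactly. For
#' the Double VOP strategy two collections are returned — `primary = {S_w}`
#' and `secondary = {eps_G (S_u + eps_G_pre S_Global)}` — whose per-vector
#' maxima are added up.
#'
#' @param result a `vop_result`.
#' @return an object of class `baked_vops` with elements `primary`,
#'   `secondary` (possibly `NULL`), and the flat stacks used by
#'   [bound_sar()].
#' @export
bake_vops <- function(result) {
  n <- nrow(result$vop_matrices[[1L]])
  model <- result$model
  if (model$kind == "double") {
    pieces <- term_pieces(model, n)
    secondary_flat <- pieces$pre_flat
    primary_flat <- result$vop_flat
    secondary <- lapply(seq_len(nrow(secondary_flat)),
                        function(i) matrix(secondary_flat[i, ], n, n))
    primary <- result$vop_matrices
  } else {
    Tv <- as.vector(model$epsilon_g * model$Z)
    primary_flat <- result$vop_flat +
      matrix(Tv, nrow(result$vop_flat), n * n, byrow = TRUE)
    primary <- lapply(seq_len(nrow(primary_flat)),
                      function(i) matrix(primary_flat[i, ], n, n))
    secondary <- NULL
    secondary_flat <- NULL
  }
  structure(list(primary = primary, secondary = secondary,
                 primary_flat = primary_flat, secondary_flat = secondary_flat,
                 n_channels = n, kind = model$kind),
            class = "baked_vops")
}

#' VOP-bounded SAR at a batch of excitation vectors
#'
#' Evaluates the baked bound `max_w b'(S_w + term) b` (plus the secondary
#' maximum for Double VOP) for every column of `B`.
#'
#' @param baked a [bake_vops()] result.
#' @param B complex matrix `n_ch x m` of excitation vectors (or one vector).
#' @return numeric vector of length `m` (W/kg).
#' @export
bound_sar <- function(baked, B) {
  if (!is.matrix(B)) B <- matrix(as.complex(B), ncol = 1L)
  W <- qf_weights(B)
  out <- colmax(Re(baked$primary_flat %*% W))
  if (!is.null(baked$secondary_flat))
    out <- out + colmax(Re(baked$secondary_flat %*% W))
  out
}

#' Re-verify stored dominance certificates against the final VOP set
#'
#' Reassembles `P = sum_w c_w S_w + overestimation - S_v` for every stored
#' certificate (coefficients for VOPs added after certification default to
#' zero) and checks PSD-ness by an independent eigendecomposition.
#'
#' @param set the original `sar_matrix_set`.
#' @param result a `vop_result` produced with `keep_certificates = TRUE`.
#' @return logical vector, one entry per certificate.
#' @export
verify_certificates <- function(set, result) {
  if (is.null(result$certificates))
    stop("result carries no certificates; rerun compress(keep_certificates = TRUE)",
         call. = FALSE)
  n <- set$n_channels
  model <- result$model
  pieces <- term_pieces(model, n)
  lam <- lambda_range(set)
  row_of <- match(result$vop_indices, set$voxel_ids)
  vapply(result$certificates, function(cert) {
    v_row <- match(cert$voxel_id, set$voxel_ids)
    c_full <- c(cert$c_vop, rep(0, length(result$vop_indices) - length(cert$c_vop)))
    P <- matrix(drop(crossprod(result$vop_flat, as.complex(c_full))), n, n)
    if (model$kind == "double") {
      P <- P + matrix(drop(crossprod(pieces$pre_flat, as.complex(cert$c_pre))), n, n)
    } else {
      P <- P + pieces$Tmat
    }
    P <- P - voxel_matrix(set, v_row)
    P <- (P + Conj(t(P))) / 2
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    min(ev) >= -result$config$psd_tolerance * max(lam[v_row, 2L], 0)
  }, logical(1))
}
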