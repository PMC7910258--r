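# Random-excitation evaluation of compressed sets: safety verification,
# overestimation statistics, and strategy-comparison curves.

#' Random unit-power excitation vectors
#'
#' Entries are drawn as independent standard complex Gaussians (isotropic in
#' phase) and each vector is normalized to unit power (squared 2-norm 1).
#' Reproducible under `seed`; the seed is recorded as an attribute and
#' propagated into evaluation reports.
#'
#' @param n number of vectors (>= 1).
#' @param channels number of transmit channels.
#' @param seed RNG seed.
#' @return complex matrix `channels x n`, one vector per column.
#' @export
random_unit_power_vectors <- function(n, channels, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  B <- with_local_seed(seed, {
    matrix(complex(real = rnorm(channels * n), imaginary = rnorm(channels * n)),
           channels, n) / sqrt(2)
  })
  B <- sweep(B, 2L, sqrt(colSums(Mod(B)^2)), `/`)
  attr(B, "seed") <- as.integer(seed)
  B
}

# maximum actual SAR over the full set at each column of B, chunked so the
# intermediate n_vox x chunk product stays small; chunking does not change
# the maxima (they are per-vector)
actual_sar_max <- function(set, B, chunk_size = 1024L) {
  m <- ncol(B)
  out <- numeric(m)
  for (s in seq(1L, m, by = chunk_size)) {
    e <- min(s + chunk_size - 1L, m)
    W <- qf_weights(B[, s:e, drop = FALSE])
    out[s:e] <- colmax(Re(set$flat %*% W))
  }
  out
}

#' Evaluate a compression against the uncompressed set
#'
#' For every excitation vector, computes the actual maximum local SAR over
#' the full set and the VOP-bounded SAR from the baked matrices, and
#' summarizes the overestimation. Any underestimation beyond a `1e-9`
#' relative tolerance raises a hard safety error (condition class
#' `sarvop_safety_error`) naming the offending vector and voxel.
#'
#' @param set the uncompressed `sar_matrix_set`.
#' @param result a `vop_result` (or a `baked_vops`).
#' @param vectors complex matrix `n_ch x m` of excitation vectors, e.g. from
#'   [random_unit_power_vectors()].
#' @param chunk_size vectors per evaluation chunk.
#' @return an `evaluation_report`: `n_vectors`, `actual_sar`, `vop_sar`,
#'   `max_relative_overestimation` (percent), `max_absolute_overestimation`
#'   (W/kg), `argmax_vector_index`, `underestimation_count`, `seed`.
#' @export
evaluate_compression <- function(set, result, vectors, chunk_size = 1024L) {
  if (nrow(vectors) != set$n_channels)
    stop("channel counts of set and vectors do not match", call. = FALSE)
  baked <- if (inherits(result, "baked_vops")) result else bake_vops(result)
  if (baked$n_channels != set$n_channels)
    stop("channel counts of set and VOPs do not match", call. = FALSE)

  actual <- actual_sar_max(set, vectors, chunk_size)
  vop <- numeric(ncol(vectors))
  for (s in seq(1L, ncol(vectors), by = chunk_size)) {
    e <- min(s + chunk_size - 1L, ncol(vectors))
    vop[s:e] <- bound_sar(baked, vectors[, s:e, drop = FALSE])
  }

  under <- (actual - vop) > 1e-9 * actual
  if (any(under)) {
    i <- which(under)[1L]
    vox <- max_sar_over_set(vectors[, i], set)$voxel_id
    stop(structure(
      class = c("sarvop_safety_error", "error", "condition"),
      list(message = sprintf(
             "SAFETY violation: VOP bound %.6g < actual SAR %.6g at vector %d (voxel %d); %d vectors affected",
             vop[i], actual[i], i, vox, sum(under)),
           call = sys.call(-1))))
  }

  rel <- 100 * (vop - actual) / actual
  structure(
    list(n_vectors = ncol(vectors),
         actual_sar = actual, vop_sar = vop,
         max_relative_overestimation = max(rel),
         max_absolute_overestimation = max(vop - actual),
         argmax_vector_index = which.max(rel),
         underestimation_count = sum(under),
         seed = if (!is.null(attr(vectors, "seed"))) attr(vectors, "seed") else NA_integer_,
         strategy_tag = if (inherits(result, "vop_result")) result$strategy_tag else baked$kind,
         n_vops = nrow(baked$primary_flat),
         n_pre_vops = if (is.null(baked$secondary_flat)) 0L else nrow(baked$secondary_flat)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<evaluation_report> %d vectors, strategy %s, %d VOPs%s\n",
    "  max relative overestimation: %.3f %%\n",
    "  max absolute overestimation: %.6g W/kg\n",
    "  underestimations: %d\n"),
    x$n_vectors, x$strategy_tag, x$n_vops,
    if (x$n_pre_vops > 0L) sprintf(" (+%d pre-VOPs)", x$n_pre_vops) else "",
    x$max_relative_overestimation, x$max_absolute_overestimation,
    x$underestimation_count))
  invisible(x)
}

#' Tidy evaluation summary
#' @param report an `evaluation_report`.
#' @return a one-row data frame.
#' @export
report_summary <- function(report) {
  data.frame(strategy = report$strategy_tag,
             n_vops = report$n_vops, n_pre_vops = report$n_pre_vops,
             n_vectors = report$n_vectors,
             max_relative_overestimation = report$max_relative_overestimation,
             max_absolute_overestimation = report$max_absolute_overestimation,
             underestimation_count = report$underestimation_count,
             seed = report$seed)
}

#' Build an overestimation model for a named strategy
#'
#' Convenience wrapper used by the curve harness and the command line: for
#' `"global"` uses the set's global-SAR matrix (falling back to
#' [build_s_global_approx()] with a warning); for `"diag"` builds the
#' constant matrix; for `"local"` runs the full [build_s_local()] pipeline;
#' for `"double"` runs [precompute_vops()].
#'
#' @param set a `sar_matrix_set`.
#' @param strategy one of `"global"`, `"diag"`, `"local"`, `"double"`.
#' @param epsilon_g overestimation factor.
#' @param seed seed for the stochastic build steps.
#' @param subset_fraction,pre_epsilon passed to [build_s_local()].
#' @param epsilon_g_pre,target_pre passed to [precompute_vops()].
#' @export
build_model <- function(set, strategy = c("global", "diag", "local", "double"),
                        epsilon_g, seed = 1L,
                        subset_fraction = 0.01, pre_epsilon = 0.2,
                        epsilon_g_pre = 0.2, target_pre = 10L) {
  strategy <- match.arg(strategy)
  switch(strategy,
    global = {
      Z <- if (!is.null(set$global_matrix)) set$global_matrix else {
        warning("set has no global-SAR matrix; using a uniform-weight approximation")
        build_s_global_approx(set)
      }
      overestimation_model("global", epsilon_g, Z = Z)
    },
    diag = overestimation_model("diag", epsilon_g, Z = build_s_diag(set)),
    local = {
      bl <- build_s_local(set, subset_fraction = subset_fraction,
                          pre_epsilon = pre_epsilon, seed = seed)
      overestimation_model("local", epsilon_g, Z = bl$s_local,
                           build_record = bl$record)
    },
    double = {
      pre <- precompute_vops(set, epsilon_g_pre = epsilon_g_pre,
                             target_count = target_pre)
      Zg <- if (!is.null(set$global_matrix)) set$global_matrix else
        build_s_global_approx(set)
      overestimation_model("double", epsilon_g, pre_vops = pre$pre_vops,
                           epsilon_g_pre = pre$epsilon_g_pre,
                           global_matrix = Zg)
    })
}

#' Overestimation factor for a target term size
#'
#' Converts a target size of the overestimation term — expressed as a
#' fraction of the worst-case SAR, the scale at which compression operating
#' points are usually quoted (e.g. "an overestimation term of around 2 % of
#' the worst-case local SAR") — into the factor \eqn{\varepsilon_G} for a
#' given model. The term is evaluated at `epsilon_g = 1` on a batch of
#' random unit-power probes and the factor is chosen so that the *median*
#' term equals `fraction * worst_case_sar(set)`. For the constant (`diag`)
#' strategy this reduces to `epsilon_g = fraction` exactly; the median (not
#' the minimum) is used because strongly coupled arrays can have
#' near-singular overestimation matrices whose minimum term is not
#' representative.
#'
#' @param set a `sar_matrix_set`.
#' @param model an [overestimation_model()] (its `epsilon_g` is ignored).
#' @param fraction target term size as a fraction of worst-case SAR.
#' @param n_probes number of probe vectors for the median.
#' @param seed probe seed.
#' @return the overestimation factor (scalar).
#' @export
epsilon_for_term_fraction <- function(set, model, fraction,
                                      n_probes = 2000L, seed = 1L) {
  stopifnot(fraction > 0)
  B <- random_unit_power_vectors(n_probes, set$n_channels, seed)
  model$epsilon_g <- 1
  med <- median(evaluate_term_many(model, B))
  if (med <= 0) stop("overestimation term is identically zero", call. = FALSE)
  fraction * worst_case_sar(set) / med
}

#' Strategy-comparison curves
#'
#' For each strategy and each overestimation factor on the grid (and each
#' seed), compresses the set, evaluates it on a common batch of random
#' unit-power vectors, and records the VOP count and the maximum relative
#' overestimation — the methodology behind "maximum relative overestimation
#' versus number of VOPs" comparisons. For the Double VOP strategy the VOP
#' count includes the pre-calculated VOPs.
#'
#' The actual (uncompressed) SAR of the probe batch is computed once and
#' shared across all grid points, as is each strategy's per-seed model
#' build.
#'
#' @param set a `sar_matrix_set`.
#' @param strategies character vector of strategy names.
#' @param epsilon_grid numeric vector of overestimation factors, or a named
#'   list with one vector per strategy (different terms make a common raw
#'   factor meaningless across strategies).
#' @param term_fractions alternative to `epsilon_grid`: target sizes of the
#'   overestimation term as fractions of worst-case SAR (scalar vector or
#'   named list per strategy); factors are derived per strategy and seed
#'   with [epsilon_for_term_fraction()].
#' @param seeds integer vector of compression seeds (one curve per
#'   strategy x seed).
#' @param n_vectors number of probe vectors.
#' @param probe_seed seed for the probe batch.
#' @param ... passed to [build_model()].
#' @return a data frame of class `comparison_curves` with columns
#'   `strategy`, `seed`, `epsilon_g`, `term_fraction` (`NA` when a raw grid
#'   was given), `n_vops` (pre-VOPs included), `n_compression_vops`,
#'   `max_relative_overestimation`, `max_absolute_overestimation`; rows
#'   sorted by `n_vops` within each curve.
#' @export
comparison_curve <- function(set, strategies, epsilon_grid = NULL,
                             term_fractions = NULL, seeds = 1L,
                             n_vectors = 1e4, probe_seed = 1L, ...) {
  if (is.null(epsilon_grid) && is.null(term_fractions))
    stop("one of epsilon_grid or term_fractions is required", call. = FALSE)
  grid_for <- function(spec, strategy) {
    g <- if (is.list(spec)) spec[[strategy]] else spec
    if (is.null(g) || length(g) == 0L)
      stop(sprintf("empty grid for strategy '%s'", strategy), call. = FALSE)
    g
  }
  B <- random_unit_power_vectors(n_vectors, set$n_channels, probe_seed)
  actual <- actual_sar_max(set, B)
  rows <- list()
  for (strategy in strategies) {
    for (seed in seeds) {
      model0 <- build_model(set, strategy, epsilon_g = 1, seed = seed, ...)
      if (is.null(term_fractions)) {
        eps_grid <- grid_for(epsilon_grid, strategy)
        fr_grid <- rep(NA_real_, length(eps_grid))
      } else {
        fr_grid <- grid_for(term_fractions, strategy)
        eps_grid <- vapply(fr_grid, function(f)
          epsilon_for_term_fraction(set, model0, f, seed = probe_seed),
          numeric(1))
      }
      for (i in seq_along(eps_grid)) {
        eps <- eps_grid[i]
        model <- model0
        model$epsilon_g <- eps
        config <- compression_config(epsilon_g = eps, seed = seed)
        res <- compress(set, model, config)
        baked <- bake_vops(res)
        vop <- bound_sar(baked, B)
        under <- (actual - vop) > 1e-9 * actual
        if (any(under))
          stop(structure(class = c("sarvop_safety_error", "error", "condition"),
                         list(message = "SAFETY violation in comparison curve",
                              call = sys.call(-1))))
        n_pre <- if (strategy == "double") length(model$pre_vops) else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strategy, seed = seed, epsilon_g = eps,
          term_fraction = fr_grid[i],
          n_vops = length(res$vop_indices) + n_pre,
          n_compression_vops = length(res$vop_indices),
          max_relative_overestimation = max(100 * (vop - actual) / actual),
          max_absolute_overestimation = max(vop - actual))
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$strategy, out$seed, out$n_vops), ]
  rownames(out) <- NULL
  class(out) <- c("comparison_curves", "data.frame")
  out
}

#' Read a curve off at a given VOP budget or overestimation level
#'
#' Log-log linear interpolation along one strategy's (n_vops, max relative
#' overestimation) curve — the way values "between the grid points" are
#' read off a compression-comparison figure. Values outside the curve's
#' range return `NA` rather than extrapolating.
#'
#' @param curves a `comparison_curves` data frame.
#' @param strategy,seed selects one curve.
#' @param n_vops,max_rel exactly one of the two: the abscissa to read at.
#' @return interpolated max relative overestimation (given `n_vops`) or
#'   VOP count (given `max_rel`).
#' @export
curve_interpolate <- function(curves, strategy, seed, n_vops = NULL,
                              max_rel = NULL) {
  cs <- curves[curves$strategy == strategy & curves$seed == seed, ]
  if (nrow(cs) < 2L) stop("need at least two grid points per curve", call. = FALSE)
  cs <- cs[order(cs$n_vops), ]
  lx <- log(cs$n_vops)
  ly <- log(cs$max_relative_overestimation)
  if (!is.null(n_vops)) {
    if (n_vops < min(cs$n_vops) || n_vops > max(cs$n_vops)) return(NA_real_)
    exp(stats::approx(lx, ly, xout = log(n_vops), ties = "ordered")$y)
  } else {
    if (max_rel > max(cs$max_relative_overestimation) ||
        max_rel < min(cs$max_relative_overestimation)) return(NA_real_)
    o <- order(ly)
    exp(stats::approx(ly[o], lx[o], xout = log(max_rel), ties = "ordered")$y)
  }
}

#' Compare two strategies at matched VOP budgets
#'
#' For each seed and each grid point of strategy `a`, finds the grid point
#' of strategy `b` (same seed) with the nearest VOP count and pairs their
#' maximum relative overestimations. Cross-strategy claims of the form "at a
#' matched number of VOPs, strategy b overestimates no more than strategy a"
#' are read off the paired columns.
#'
#' @param curves a `comparison_curves` data frame.
#' @param a,b strategy names present in `curves`.
#' @return data frame with one row per (seed, point of `a`).
#' @export
compare_at_matched_vops <- function(curves, a, b) {
  ca <- curves[curves$strategy == a, ]
  cb <- curves[curves$strategy == b, ]
  if (nrow(ca) == 0L || nrow(cb) == 0L)
    stop("both strategies must be present in the curves", call. = FALSE)
  rows <- lapply(seq_len(nrow(ca)), function(i) {
    sb <- cb[cb$seed == ca$seed[i], ]
    j <- which.min(abs(sb$n_vops - ca$n_vops[i]))
    data.frame(seed = ca$seed[i],
               n_vops_a = ca$n_vops[i], n_vops_b = sb$n_vops[j],
               rel_a = ca$max_relative_overestimation[i],
               rel_b = sb$max_relative_overestimation[j])
  })
  do.call(rbind, rows)
}
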