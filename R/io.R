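# HDF5 container for SAR matrix sets and derived results.
#
# Layout (format_version 1.0):
#   /matrices/{re,im}        n_ch x n_ch x n_vox
#   /voxel_ids               integer vector
#   /global_matrix/{re,im}   n_ch x n_ch (optional)
#   /vops/<tag>/...          compression results (appended)
#   /overestimation/<tag>/   S_local build records (appended)
#   /evaluation/<tag>/...    evaluation summaries (appended)
#   root attributes: format_version, n_channels, units, provenance
#
# Complex arrays are stored as paired re/im float64 datasets (HDF5 has no
# portable complex type in this toolchain); both are read back and
# recombined, so write -> read round trips are bit-exact.

CONTAINER_VERSION <- "1.0"

h5_has <- function(ls_df, path) {
  full <- file.path(ls_df$group, ls_df$name)
  full <- sub("^//", "/", full)
  path %in% full
}

ensure_group <- function(path, group) {
  ls_df <- rhdf5::h5ls(path, recursive = TRUE)
  parts <- strsplit(group, "/")[[1L]]
  parts <- parts[nzchar(parts)]
  cur <- ""
  for (p in parts) {
    cur <- paste0(cur, "/", p)
    if (!h5_has(ls_df, cur)) rhdf5::h5createGroup(path, cur)
  }
}

h5_write_complex <- function(x, file, name) {
  ensure_group(file, name)
  rhdf5::h5write(Re(x), file, paste0(name, "/re"))
  rhdf5::h5write(Im(x), file, paste0(name, "/im"))
}

h5_read_complex <- function(file, name) {
  re <- rhdf5::h5read(file, paste0(name, "/re"))
  im <- rhdf5::h5read(file, paste0(name, "/im"))
  array(complex(real = re, imaginary = im), dim = dim(re))
}

#' Write a SAR matrix set to an HDF5 container
#'
#' Matrices are written chunked over voxels so large sets stream to disk in
#' slabs rather than as one allocation.
#'
#' @param path output file (overwritten if it exists).
#' @param set a `sar_matrix_set`.
#' @param chunk_voxels voxels per HDF5 chunk / write slab.
#' @export
write_container <- function(path, set, chunk_voxels = 4096L) {
  stopifnot(inherits(set, "sar_matrix_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  n <- set$n_channels
  nv <- n_voxels(set)
  chunk <- c(n, n, min(chunk_voxels, nv))
  rhdf5::h5createGroup(path, "matrices")
  for (part in c("re", "im")) {
    rhdf5::h5createDataset(path, paste0("matrices/", part), dims = c(n, n, nv),
                           storage.mode = "double", chunk = chunk, level = 4L)
  }
  for (s in seq(1L, nv, by = chunk_voxels)) {
    e <- min(s + chunk_voxels - 1L, nv)
    slab <- array(t(set$flat[s:e, , drop = FALSE]), dim = c(n, n, e - s + 1L))
    rhdf5::h5write(Re(slab), path, "matrices/re", index = list(NULL, NULL, s:e))
    rhdf5::h5write(Im(slab), path, "matrices/im", index = list(NULL, NULL, s:e))
  }
  rhdf5::h5write(set$voxel_ids, path, "voxel_ids")
  if (!is.null(set$global_matrix))
    h5_write_complex(set$global_matrix, path, "global_matrix")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(CONTAINER_VERSION, fid, "format_version")
  rhdf5::h5writeAttribute(as.integer(n), fid, "n_channels")
  rhdf5::h5writeAttribute("W/kg per unit power", fid, "units")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(set$metadata, auto_unbox = TRUE, digits = NA,
                                  force = TRUE)),
    fid, "provenance")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a SAR matrix set from an HDF5 container
#'
#' Matrices are symmetrized on load (with a warning if the asymmetry exceeds
#' tolerance) and all set invariants are validated; validation failures are
#' errors, not warnings.
#'
#' @param path container file.
#' @return a `sar_matrix_set`; available result tags are attached as
#'   attributes `vop_tags` and `evaluation_tags`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls_df <- tryCatch(rhdf5::h5ls(path, recursive = TRUE),
                    error = function(e)
                      stop(sprintf("cannot open '%s' as an HDF5 container: %s",
                                   path, conditionMessage(e)), call. = FALSE))
  for (need in c("/matrices/re", "/matrices/im", "/voxel_ids"))
    if (!h5_has(ls_df, need))
      stop(sprintf("container is missing dataset %s", need), call. = FALSE)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (is.null(attrs$format_version))
    stop("container has no format_version attribute", call. = FALSE)
  if (as.character(attrs$format_version) != CONTAINER_VERSION)
    stop(sprintf("unsupported container format_version '%s'",
                 attrs$format_version), call. = FALSE)
  arr <- h5_read_complex(path, "matrices")
  if (length(dim(arr)) != 3L || dim(arr)[1L] != dim(arr)[2L])
    stop("shape mismatch in /matrices", call. = FALSE)
  voxel_ids <- as.integer(rhdf5::h5read(path, "voxel_ids"))
  if (length(voxel_ids) != dim(arr)[3L])
    stop("shape mismatch between /matrices and /voxel_ids", call. = FALSE)
  global <- if (h5_has(ls_df, "/global_matrix/re"))
    h5_read_complex(path, "global_matrix")
  metadata <- if (!is.null(attrs$provenance))
    jsonlite::fromJSON(as.character(attrs$provenance)) else list()
  set <- sar_matrix_set(arr, voxel_ids = voxel_ids, global_matrix = global,
                        metadata = metadata, symmetrize = TRUE, validate = TRUE)
  attr(set, "vop_tags") <- unique(ls_df$name[ls_df$group == "/vops"])
  attr(set, "evaluation_tags") <- unique(ls_df$name[ls_df$group == "/evaluation"])
  set
}

#' Append a compression result to a container
#'
#' Writes VOP indices, matrices, baked matrices, the overestimation model,
#' and the configuration under `/vops/<tag>`; an S_local build record, when
#' present on the model, goes under `/overestimation/<tag>`. The `/matrices`
#' datasets are untouched.
#'
#' @param path container file.
#' @param result a `vop_result`.
#' @param tag group name (default: the strategy tag).
#' @export
append_vop_result <- function(path, result, tag = result$strategy_tag) {
  stopifnot(inherits(result, "vop_result"))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  g <- paste0("/vops/", tag)
  ensure_group(path, g)
  n <- nrow(result$vop_matrices[[1L]])
  rhdf5::h5write(as.integer(result$vop_indices), path, paste0(g, "/indices"))
  arr <- array(t(result$vop_flat), dim = c(n, n, length(result$vop_indices)))
  h5_write_complex(arr, path, paste0(g, "/matrices"))
  baked <- bake_vops(result)
  h5_write_complex(array(t(baked$primary_flat),
                         dim = c(n, n, nrow(baked$primary_flat))),
                   path, paste0(g, "/baked_primary"))
  if (!is.null(baked$secondary_flat))
    h5_write_complex(array(t(baked$secondary_flat),
                           dim = c(n, n, nrow(baked$secondary_flat))),
                     path, paste0(g, "/baked_secondary"))
  model <- result$model
  rhdf5::h5write(model$kind, path, paste0(g, "/kind"))
  rhdf5::h5write(model$epsilon_g, path, paste0(g, "/epsilon_g"))
  if (model$kind == "double") {
    rhdf5::h5write(model$epsilon_g_pre, path, paste0(g, "/epsilon_g_pre"))
    pre_arr <- array(unlist(model$pre_vops), dim = c(n, n, length(model$pre_vops)))
    h5_write_complex(pre_arr, path, paste0(g, "/pre_vops"))
    h5_write_complex(model$global_matrix, path, paste0(g, "/global_matrix"))
  } else {
    h5_write_complex(model$Z, path, paste0(g, "/Z"))
  }
  rhdf5::h5write(as.character(jsonlite::toJSON(unclass(result$config),
                                               auto_unbox = TRUE)),
                 path, paste0(g, "/config_json"))
  rec <- model$build_record
  if (!is.null(rec)) {
    og <- paste0("/overestimation/", tag)
    ensure_group(path, og)
    rhdf5::h5write(rec$subset_fraction, path, paste0(og, "/subset_fraction"))
    rhdf5::h5write(rec$pre_epsilon, path, paste0(og, "/pre_epsilon"))
    rhdf5::h5write(rec$R, path, paste0(og, "/R"))
    rhdf5::h5write(rec$eig_sars, path, paste0(og, "/eig_sars"))
    rhdf5::h5write(rec$d, path, paste0(og, "/d"))
    h5_write_complex(rec$s_pre, path, paste0(og, "/s_pre"))
    h5_write_complex(rec$eigvecs, path, paste0(og, "/eigvecs"))
  }
  invisible(path)
}

#' Read a compression result back from a container
#'
#' @param path container file.
#' @param tag group name under `/vops`.
#' @return a `vop_result` (without per-voxel statuses or certificates, which
#'   are not serialized).
#' @export
read_vop_result <- function(path, tag) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls_df <- rhdf5::h5ls(path, recursive = TRUE)
  g <- paste0("/vops/", tag)
  if (!h5_has(ls_df, g)) stop(sprintf("no result '%s' in container", tag), call. = FALSE)
  n_read <- function(name) rhdf5::h5read(path, paste0(g, "/", name))
  kind <- as.character(n_read("kind"))
  eps <- as.numeric(n_read("epsilon_g"))
  arr <- h5_read_complex(path, paste0(g, "/matrices"))
  n <- dim(arr)[1L]
  mats <- lapply(seq_len(dim(arr)[3L]), function(i) arr[, , i])
  model <- if (kind == "double") {
    pre_arr <- h5_read_complex(path, paste0(g, "/pre_vops"))
    overestimation_model("double", eps,
                         pre_vops = lapply(seq_len(dim(pre_arr)[3L]),
                                           function(i) pre_arr[, , i]),
                         epsilon_g_pre = as.numeric(n_read("epsilon_g_pre")),
                         global_matrix = h5_read_complex(path, paste0(g, "/global_matrix")))
  } else {
    overestimation_model(kind, eps, Z = h5_read_complex(path, paste0(g, "/Z")))
  }
  cfg <- jsonlite::fromJSON(as.character(n_read("config_json")))
  config <- compression_config(epsilon_g = cfg$epsilon_g,
                               max_coef_iterations = cfg$max_coef_iterations,
                               psd_tolerance = cfg$psd_tolerance,
                               seed = cfg$seed,
                               coef_update_rule = cfg$coef_update_rule,
                               inner_factor = cfg$inner_factor)
  structure(list(vop_indices = as.integer(n_read("indices")),
                 vop_matrices = mats,
                 vop_flat = t(matrix(arr, n * n, dim(arr)[3L])),
                 model = model, config = config, strategy_tag = kind,
                 statuses = NULL, certificates = NULL, witnesses = list(),
                 n_voxels_in = NA_integer_),
            class = "vop_result")
}

#' Append an evaluation report to a container
#' @param path container file.
#' @param report an `evaluation_report`.
#' @param tag group name under `/evaluation`.
#' @param keep_vectors also store the per-vector actual and bounded SAR.
#' @export
append_evaluation <- function(path, report, tag = report$strategy_tag,
                              keep_vectors = FALSE) {
  stopifnot(inherits(report, "evaluation_report"))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  g <- paste0("/evaluation/", tag)
  ensure_group(path, g)
  s <- report_summary(report)
  rhdf5::h5write(as.character(jsonlite::toJSON(as.list(s), auto_unbox = TRUE,
                                               digits = NA)),
                 path, paste0(g, "/summary_json"))
  if (keep_vectors) {
    rhdf5::h5write(report$actual_sar, path, paste0(g, "/actual_sar"))
    rhdf5::h5write(report$vop_sar, path, paste0(g, "/vop_sar"))
  }
  invisible(path)
}

#' Export baked VOP matrices for supervision-system consumption
#'
#' Writes the one or two baked collections to a standalone HDF5 file
#' (`/baked_primary`, `/baked_secondary`), with the evaluation convention
#' (single maximum, or sum of two maxima) recorded as an attribute.
#'
#' @param path output file.
#' @param result a `vop_result` or `baked_vops`.
#' @export
export_baked <- function(path, result) {
  baked <- if (inherits(result, "baked_vops")) result else bake_vops(result)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  n <- baked$n_channels
  h5_write_complex(array(t(baked$primary_flat),
                         dim = c(n, n, nrow(baked$primary_flat))),
                   path, "baked_primary")
  if (!is.null(baked$secondary_flat))
    h5_write_complex(array(t(baked$secondary_flat),
                           dim = c(n, n, nrow(baked$secondary_flat))),
                     path, "baked_secondary")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(
    if (is.null(baked$secondary_flat)) "max(primary)" else "max(primary) + max(secondary)",
    fid, "bound_convention")
  rhdf5::h5writeAttribute(as.integer(n), fid, "n_channels")
  rhdf5::H5Fclose(fid)
  invisible(path)
}
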