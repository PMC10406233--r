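#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FC matrix into an edge table
#'
#' @param x an `fc_matrix`.
#' @param ... unused.
#' @return Tibble with one row per edge (upper triangle): `region_i`,
#'   `region_j`, `value`.
#' @export
tidy.fc_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    region_i = x$region_ids[ut[, 1]],
    region_j = x$region_ids[ut[, 2]],
    value = x$values[ut]
  )
}

#' @rdname tidy.fc_matrix
#' @export
glance.fc_matrix <- function(x, ...) {
  e <- fc_edges(x)
  tibble::tibble(
    n_regions = nrow(x$values),
    n_edges = length(e),
    fisher_z = x$fisher_z,
    mean_edge = mean(e, na.rm = TRUE),
    n_undefined_edges = x$n_undefined_edges
  )
}

#' Tidy a QC-FC result into an edge table
#'
#' @param x a `qcfc_result`.
#' @param ... unused.
#' @return Tibble `region_i`, `region_j`, `qcfc_r`, and `distance_mm` when
#'   centroids were supplied.
#' @export
tidy.qcfc_result <- function(x, ...) {
  out <- tibble::tibble(
    region_i = x$edge_index[, 1],
    region_j = x$edge_index[, 2],
    qcfc_r = x$edge_r
  )
  if (!is.null(x$distance_mm)) out$distance_mm <- x$distance_mm
  out
}

#' @rdname tidy.qcfc_result
#' @export
glance.qcfc_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_edges = length(x$edge_r),
    mean_qcfc = x$mean_r,
    distance_dependence_r = x$distance_dependence_r %||% NA_real_,
    distance_ci_low = if (is.null(x$distance_ci95)) NA_real_ else x$distance_ci95[1],
    distance_ci_high = if (is.null(x$distance_ci95)) NA_real_ else x$distance_ci95[2],
    n_excluded_edges = x$n_excluded_edges
  )
}

#' Glance at a design matrix
#'
#' @param x a `qc_design`.
#' @param ... unused.
#' @return One-row tibble with column counts per category, retained rows,
#'   rank and residual degrees of freedom.
#' @export
glance.qc_design <- function(x, ...) {
  counts <- table(factor(x$category, levels = c("polynomial", "nuisance",
                                                "derivative",
                                                "bandpass_stop")))
  tibble::tibble(
    n_timepoints = nrow(x$X),
    n_retained = sum(x$keep),
    n_polynomial = as.integer(counts[["polynomial"]]),
    n_nuisance = as.integer(counts[["nuisance"]]),
    n_derivative = as.integer(counts[["derivative"]]),
    n_bandpass_stop = as.integer(counts[["bandpass_stop"]]),
    rank = design_rank(x),
    dof = as.integer(residual_dof(x))
  )
}

#' Export a design matrix as CSV with a category header row
#'
#' @param design a `qc_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("category", design$category), collapse = ","), con)
  utils::write.csv(cbind(retained = as.integer(design$keep), design$X),
                   con, row.names = FALSE)
  invisible(path)
}

#' Export an FC matrix as CSV (region ids as header)
#'
#' @param fc an `fc_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fc_csv <- function(fc, path) {
  m <- fc$values
  dimnames(m) <- list(fc$region_ids, fc$region_ids)
  utils::write.csv(m, path)
  invisible(path)
}

#' @rdname write_fc_csv
#' @export
read_fc_csv <- function(path, fisher_z = TRUE) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  new_fc_matrix(unname(m), fisher_z, colnames(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
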