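#' Build the nuisance / drift / band-pass design matrix
#'
#' Assembles the regressor bank projected out of the data: polynomial drift
#' terms of degree 0..`poly_order`; each nuisance time course together with
#' its backward-difference temporal derivative (first element 0); and, when a
#' pass band is given, a sine and cosine column at every DFT frequency
#' k/(T*tr_s), 1 <= k <= T/2, lying outside the band. Regressing those
#' stop-band sinusoids out band-passes the data while keeping the
#' degrees-of-freedom accounting exact under censoring — unlike a
#' frequency-domain filter. Band limits are inclusive: frequencies with
#' f_lo <= f <= f_hi are retained. The zero frequency is carried by the
#' polynomial constant, and at the Nyquist frequency (T even) only the
#' cosine column exists.
#'
#' @param n_timepoints number of time points T.
#' @param tr_s repetition time (s).
#' @param nuisance named list / data frame of length-T nuisance time courses
#'   (may be empty).
#' @param poly_order polynomial drift order (>= 0); `poly_order = 2` yields
#'   3 columns (constant, linear, quadratic).
#' @param band_hz length-2 pass band in Hz, or NULL for no band-pass.
#' @param mask optional `censor_mask`; defaults to all-retained.
#' @param derivatives add backward-difference derivatives of the nuisance
#'   columns (default TRUE).
#' @return A `qc_design` object: list with `X` (T x p matrix), `category`
#'   (one of `"polynomial"`, `"nuisance"`, `"derivative"`,
#'   `"bandpass_stop"` per column), `keep` (logical retained-row mask),
#'   `tr_s`.
#' @export
build_design <- function(n_timepoints, tr_s, nuisance = list(),
                         poly_order = 2, band_hz = NULL, mask = NULL,
                         derivatives = TRUE) {
  T <- as.integer(n_timepoints)
  stopifnot(T >= 2L, tr_s > 0, poly_order >= 0)
  if (is.null(mask)) {
    keep <- rep(TRUE, T)
  } else {
    stopifnot(nrow(mask) == T)
    keep <- mask$keep
  }

  cols <- list()
  category <- character()

  tt <- seq(-1, 1, length.out = T)
  for (d in 0:poly_order) {
    cols[[paste0("poly_", d)]] <- tt^d
    category <- c(category, "polynomial")
  }

  nuisance <- as.list(nuisance)
  if (length(nuisance)) {
    if (is.null(names(nuisance)) || any(!nzchar(names(nuisance)))) {
      stop("nuisance series must be named", call. = FALSE)
    }
    for (nm in names(nuisance)) {
      v <- as.numeric(nuisance[[nm]])
      if (length(v) != T) stop("nuisance series '", nm, "' has length ",
                               length(v), ", expected ", T, call. = FALSE)
      if (!all(is.finite(v))) stop("nuisance series '", nm, "' is not finite",
                                   call. = FALSE)
      cols[[nm]] <- v
      category <- c(category, "nuisance")
    }
    if (derivatives) {
      for (nm in names(nuisance)) {
        v <- as.numeric(nuisance[[nm]])
        cols[[paste0("d_", nm)]] <- c(0, diff(v))
        category <- c(category, "derivative")
      }
    }
  }

  if (!is.null(band_hz)) {
    nyq <- 1 / (2 * tr_s)
    if (length(band_hz) != 2L || band_hz[1] < 0 || band_hz[2] <= band_hz[1] ||
        band_hz[1] >= nyq) {
      stop("band must lie within (0, Nyquist = ", format(nyq), " Hz)",
           call. = FALSE)
    }
    total_s <- T * tr_s
    tol <- 1e-9
    for (k in seq_len(floor(T / 2))) {
      f <- k / total_s
      if (f >= band_hz[1] - tol && f <= band_hz[2] + tol) next
      ang <- 2 * pi * f * tr_s * (seq_len(T) - 1)
      cols[[sprintf("cos_k%d", k)]] <- cos(ang)
      category <- c(category, "bandpass_stop")
      if (k < T / 2) {  # Nyquist sine is identically 0 on the grid
        cols[[sprintf("sin_k%d", k)]] <- sin(ang)
        category <- c(category, "bandpass_stop")
      }
    }
  }

  if (anyDuplicated(names(cols))) {
    stop("duplicate design column names: ",
         paste(unique(names(cols)[duplicated(names(cols))]), collapse = ", "),
         call. = FALSE)
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = T, ncol = 0)
  structure(list(X = X, category = category, keep = keep, tr_s = tr_s),
            class = "qc_design")
}

#' @export
print.qc_design <- function(x, ...) {
  counts <- table(factor(x$category, levels = c("polynomial", "nuisance",
                                                "derivative", "bandpass_stop")))
  cat(sprintf("<qc_design> %d time points (%d retained), %d columns\n",
              nrow(x$X), sum(x$keep), ncol(x$X)))
  cat(" ", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  cat("  rank on retained rows =", design_rank(x),
      " dof =", residual_dof(x), "\n")
  invisible(x)
}

design_rank <- function(design) {
  Xk <- design$X[design$keep, , drop = FALSE]
  if (ncol(Xk) == 0L) return(0L)
  qr(Xk, tol = 1e-9)$rank
}

#' Residual degrees of freedom
#'
#' The number of retained time points minus the rank of the design matrix
#' restricted to retained rows. This is the exact count of independent
#' observations left after censoring, nuisance regression and band-pass
#' projection; subjects are commonly excluded below 15.
#'
#' @param design a `qc_design`.
#' @param mask optional `censor_mask` overriding the one stored in the
#'   design.
#' @return Integer degrees of freedom (never negative). When the design
#'   saturates the retained rows (rank = retained rows) the result is 0 and
#'   carries attribute `over_determined = TRUE` — the "not enough degrees of
#'   freedom" condition.
#' @export
residual_dof <- function(design, mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(nrow(mask) == nrow(design$X))
    design$keep <- mask$keep
  }
  n_keep <- sum(design$keep)
  r <- design_rank(design)
  dof <- as.integer(n_keep - r)
  if (dof <= 0L) {
    dof <- 0L
    attr(dof, "over_determined") <- TRUE
  }
  dof
}

#' Project the design out of time series (censored least squares)
#'
#' Fits the design to each series by least squares on the retained rows only
#' and returns the residuals on those rows. Censored rows take no part in
#' the fit and are excluded from every downstream correlation. Rank-deficient
#' designs are handled by pivoted QR (the projection onto the column-space
#' complement is unique even when coefficients are not); the effective rank
#' is reported.
#'
#' @param series numeric vector or T x V matrix of time courses (voxels or
#'   regions as columns).
#' @param design a `qc_design`.
#' @return A `qc_residuals` object: list with `values` (retained rows x V
#'   residual matrix), `kept` (indices of retained rows), `dof`, `rank`,
#'   `meta` (threshold, band, tr_s).
#' @export
project_nuisance <- function(series, design) {
  Y <- as.matrix(series)
  if (nrow(Y) != nrow(design$X)) {
    stop("series has ", nrow(Y), " rows; design expects ", nrow(design$X),
         call. = FALSE)
  }
  kept <- which(design$keep)
  Yk <- Y[kept, , drop = FALSE]
  Xk <- design$X[design$keep, , drop = FALSE]
  if (ncol(Xk) == 0L) {
    res <- Yk
    r <- 0L
  } else {
    qrx <- qr(Xk, tol = 1e-9)
    res <- qr.resid(qrx, Yk)
    r <- qrx$rank
  }
  structure(list(values = res, kept = kept,
                 dof = as.integer(length(kept) - r), rank = r,
                 meta = list(tr_s = design$tr_s)),
            class = "qc_residuals")
}

#' Extract nuisance time courses from a 4D volume
#'
#' Spatial means over the whole-brain, eroded white-matter and CSF masks,
#' plus the six realignment parameters. The whole-brain (global) column is
#' omitted when `global = FALSE`, reproducing the no-GSR variant of the
#' pipeline. Temporal derivatives are added later, at design-build time.
#'
#' @param volume a [vol4d].
#' @param masks named list of [brain_mask] objects; recognised names are
#'   `global`, `wm`, `csf`. Masks must be nonempty and on the volume grid.
#' @param motion a [motion_trace] with one row per volume, or NULL.
#' @param global,wm,csf,motion_params logical toggles for each regressor
#'   group.
#' @return A named list of length-T numeric vectors, ready for
#'   [build_design()].
#' @export
extract_nuisance_series <- function(volume, masks = list(), motion = NULL,
                                    global = TRUE, wm = TRUE, csf = TRUE,
                                    motion_params = TRUE) {
  out <- list()
  want <- c(global = global, wm = wm, csf = csf)
  for (nm in names(want)[want]) {
    m <- masks[[nm]]
    if (is.null(m)) stop("mask '", nm, "' required but not supplied", call. = FALSE)
    if (!any(m$values)) stop("mask '", nm, "' is empty", call. = FALSE)
    out[[nm]] <- rowMeans(vol_matrix(volume, m))
  }
  if (motion_params) {
    if (is.null(motion)) stop("motion trace required when motion_params = TRUE",
                              call. = FALSE)
    if (nrow(motion) != n_timepoints(volume)) {
      stop("motion trace has ", nrow(motion), " rows; volume has ",
           n_timepoints(volume), " time points", call. = FALSE)
    }
    p <- trace_params(motion)
    for (i in 1:6) out[[colnames(p)[i]]] <- p[, i]
  }
  out
}
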