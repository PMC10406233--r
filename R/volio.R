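#' Read a 4D NIfTI volume
#'
#' Loads a NIfTI-1 image and wraps it as a [vol4d]. By default the array is
#' reoriented to the canonical `"RAS"` axis order so that seed coordinates and
#' flip checks are unambiguous; set `reorient = FALSE` to keep the stored
#' orientation. Non-finite voxels do not abort the load but are flagged.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param reorient reorient the array to `"RAS"` on load (default TRUE).
#' @return A [vol4d] with attributes `oblique` (TRUE when the stored affine
#'   is not axis-aligned) and `nonfinite` (TRUE when any voxel is NA/NaN/Inf,
#'   reported with a warning).
#' @export
read_volume4d <- function(path, reorient = TRUE) {
  img <- read_nifti_obj(path, reorient)
  if (length(dim(img$data)) != 4L) {
    stop("expected a 4D volume but '", path, "' has ", length(dim(img$data)),
         " dimensions; use read_mask()/read_volume3d() for 3D images",
         call. = FALSE)
  }
  out <- vol4d(img$data, img$voxel_mm, img$origin_mm, img$orientation)
  attr(out, "oblique") <- img$oblique
  attr(out, "nonfinite") <- !all(is.finite(img$data))
  if (attr(out, "nonfinite")) {
    warning("volume '", path, "' contains non-finite voxels", call. = FALSE)
  }
  out
}

#' Read a 3D NIfTI volume, mask or parcellation
#'
#' @inheritParams read_volume4d
#' @return `read_volume3d()` a [vol3d]; `read_mask()` a [brain_mask]
#'   (nonzero voxels are members); `read_parcellation()` a [parcellation].
#' @export
read_volume3d <- function(path, reorient = TRUE) {
  img <- read_nifti_obj(path, reorient)
  dat <- drop_trailing_singleton(img$data)
  if (length(dim(dat)) != 3L) {
    stop("expected a 3D volume but '", path, "' has ", length(dim(dat)),
         " dimensions", call. = FALSE)
  }
  out <- vol3d(dat, img$voxel_mm, img$origin_mm, img$orientation)
  attr(out, "oblique") <- img$oblique
  out
}

#' @rdname read_volume3d
#' @export
read_mask <- function(path, reorient = TRUE) {
  v <- read_volume3d(path, reorient)
  brain_mask(v$values != 0, v$voxel_mm, v$origin_mm, v$orientation)
}

#' @rdname read_volume3d
#' @export
read_parcellation <- function(path, reorient = TRUE) {
  v <- read_volume3d(path, reorient)
  parcellation(round(v$values), v$voxel_mm, v$origin_mm, v$orientation)
}

drop_trailing_singleton <- function(a) {
  d <- dim(a)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(a) <- d
  }
  a
}

read_nifti_obj <- function(path, reorient) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  scl <- sqrt(colSums(rot^2))
  # oblique when any affine column has more than one non-negligible entry
  oblique <- any(colSums(abs(rot) > 1e-3 * max(scl)) > 1L)
  if (reorient) RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  dat <- array(as.numeric(img), dim = dim(img))
  list(
    data = dat,
    voxel_mm = sqrt(colSums(aff[1:3, 1:3]^2)),
    origin_mm = as.numeric(aff[1:3, 4]),
    orientation = RNifti::orientation(img),
    oblique = oblique
  )
}

#' Write a gridded object as NIfTI-1
#'
#' Builds the affine from the object's orientation code, voxel sizes and
#' origin; round-trip through [read_volume4d()] preserves dims, voxel sizes,
#' orientation and values to stored precision.
#'
#' @param vol a [vol4d], [vol3d], [brain_mask] or [parcellation].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$values
  if (is.logical(dat)) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- if (length(dim(dat)) == 4L) c(vol$voxel_mm, 1)
                         else vol$voxel_mm
  aff <- diag(4)
  letters3 <- strsplit(vol$orientation, "")[[1]]
  for (i in 1:3) {
    world_axis <- ORIENT_AXES[[letters3[i]]]
    aff[world_axis, i] <- ORIENT_SIGN[[letters3[i]]] * vol$voxel_mm[i]
  }
  aff[1:3, 4] <- vol$origin_mm
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_volume4d <- write_volume

#' Read and write motion-parameter files
#'
#' Motion files are whitespace-delimited text with 6 numeric columns and one
#' row per volume. The default dialect stores the 3 rotations (degrees) in
#' columns 1-3 and the 3 translations (mm) in columns 4-6; files with the
#' opposite order are handled via `convention = "translations-first"`.
#'
#' @param path path to the text file.
#' @param tr_s repetition time in seconds, attached to the trace.
#' @param convention column order of the file, `"rotations-first"` (default)
#'   or `"translations-first"`.
#' @return A `motion_trace` tibble with columns `rot_1..rot_3` (degrees) and
#'   `trans_1..trans_3` (mm) and attribute `tr_s`.
#' @export
read_motion <- function(path, tr_s, convention = c("rotations-first",
                                                   "translations-first")) {
  convention <- match.arg(convention)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("motion file needs at least 2 rows", call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 6L) {
      stop("motion file line ", i, " has ", length(tok),
           " columns; expected 6", call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(tok))
    if (anyNA(val)) {
      stop("motion file line ", i, " has a non-numeric token: '",
           tok[which(is.na(val))[1]], "'", call. = FALSE)
    }
    val
  })
  params <- do.call(rbind, rows)
  if (convention == "translations-first") params <- params[, c(4:6, 1:3)]
  motion_trace(params, tr_s)
}

#' @rdname read_motion
#' @param trace a `motion_trace`.
#' @export
write_motion <- function(trace, path, convention = c("rotations-first",
                                                     "translations-first")) {
  convention <- match.arg(convention)
  params <- as.matrix(trace[, c("rot_1", "rot_2", "rot_3",
                                "trans_1", "trans_2", "trans_3")])
  if (convention == "translations-first") params <- params[, c(4:6, 1:3)]
  utils::write.table(format(params, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write censor files
#'
#' One line per time point: `1` = retained, `0` = censored.
#'
#' @param mask a `censor_mask` tibble (from [censor_mask()]).
#' @param path file path.
#' @return `read_censor()` returns a `censor_mask` tibble (threshold unknown,
#'   recorded as `NA`).
#' @export
write_censor <- function(mask, path) {
  writeLines(as.character(as.integer(mask$keep)), path)
  invisible(path)
}

#' @rdname write_censor
#' @export
read_censor <- function(path) {
  tok <- trimws(readLines(path))
  tok <- tok[nzchar(tok)]
  bad <- setdiff(unique(tok), c("0", "1"))
  if (length(bad)) {
    stop("censor file contains token(s) other than 0/1: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  new_censor_mask(tok == "1", threshold_mm = NA_real_)
}

#' Run configuration
#'
#' Bundles the processing parameters of a QC run: repetition time, censoring
#' threshold, band limits, polynomial drift order, nuisance toggles, the
#' blur target, and the subject inclusion cutoffs (minimum residual degrees
#' of freedom, minimum seconds of good data, maximum volume-to-volume
#' motion).
#'
#' @param tr_s repetition time (s).
#' @param censor_threshold_mm motion censoring threshold (mm); default 0.4.
#' @param band_hz length-2 pass band in Hz, or NULL for no band-pass;
#'   default `c(0.01, 0.1)`.
#' @param poly_order polynomial drift order (default 2: constant, linear,
#'   quadratic).
#' @param nuisance named logical toggles `global`, `wm`, `csf`, `motion`,
#'   `derivatives`.
#' @param fwhm_target_mm target smoothness for blur-to-target, or NULL.
#' @param dof_cutoff exclude below this many residual degrees of freedom
#'   (default 15).
#' @param min_good_seconds exclude below this much retained data (default
#'   240 s).
#' @param max_enorm_mm flag subjects whose maximum volume-to-volume motion
#'   exceeds this (default 3 mm).
#' @return A `run_config` list.
#' @export
run_config <- function(tr_s, censor_threshold_mm = 0.4,
                       band_hz = c(0.01, 0.1), poly_order = 2,
                       nuisance = list(global = TRUE, wm = TRUE, csf = TRUE,
                                       motion = TRUE, derivatives = TRUE),
                       fwhm_target_mm = 8, dof_cutoff = 15,
                       min_good_seconds = 240, max_enorm_mm = 3) {
  stopifnot(is.numeric(tr_s), tr_s > 0, censor_threshold_mm > 0,
            poly_order >= 0, dof_cutoff > 0, min_good_seconds > 0,
            max_enorm_mm > 0)
  if (!is.null(band_hz)) {
    nyq <- 1 / (2 * tr_s)
    if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] <= band_hz[1] ||
        band_hz[2] >= nyq) {
      stop("band_hz must satisfy 0 < low < high < Nyquist = ",
           format(nyq), " Hz", call. = FALSE)
    }
  }
  defaults <- list(global = TRUE, wm = TRUE, csf = TRUE, motion = TRUE,
                   derivatives = TRUE)
  defaults[names(nuisance)] <- nuisance
  structure(list(tr_s = tr_s, censor_threshold_mm = censor_threshold_mm,
                 band_hz = band_hz, poly_order = as.integer(poly_order),
                 nuisance = defaults, fwhm_target_mm = fwhm_target_mm,
                 dof_cutoff = dof_cutoff, min_good_seconds = min_good_seconds,
                 max_enorm_mm = max_enorm_mm),
            class = "run_config")
}

#' @rdname run_config
#' @param path file path for the YAML key-value config.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  band <- if (is.null(x$band_hz)) NULL else as.numeric(unlist(x$band_hz))
  run_config(tr_s = x$tr_s, censor_threshold_mm = x$censor_threshold_mm,
             band_hz = band, poly_order = x$poly_order,
             nuisance = x$nuisance, fwhm_target_mm = x$fwhm_target_mm,
             dof_cutoff = x$dof_cutoff,
             min_good_seconds = x$min_good_seconds,
             max_enorm_mm = x$max_enorm_mm)
}

#' Flag acquisition-parameter deviations within sites
#'
#' Multi-site studies should acquire with consistent parameters within each
#' site; a subject whose matrix size, voxel size, TR, obliquity or run length
#' differs from its site's modal value is a red flag (data re-gridded after
#' acquisition, protocol drift, export error). Every parameter column is
#' compared against the within-site mode.
#'
#' @param param_table data frame with columns `subject`, `site`, and one or
#'   more parameter columns (e.g. `matrix_size`, `voxel_size_mm`, `tr_s`,
#'   `oblique`, `n_timepoints`).
#' @return A tibble of flags with columns `site`, `subject`, `parameter`,
#'   `modal_value`, `observed_value`; zero rows when every subject matches
#'   its site mode.
#' @export
check_acquisition_consistency <- function(param_table) {
  if (is.null(param_table) || nrow(param_table) == 0L) {
    stop("empty acquisition parameter table", call. = FALSE)
  }
  stopifnot(all(c("subject", "site") %in% names(param_table)))
  params <- setdiff(names(param_table), c("subject", "site"))
  tab <- tibble::as_tibble(param_table)
  purrr::map_dfr(params, function(p) {
    tab |>
      dplyr::group_by(.data$site) |>
      dplyr::filter(dplyr::n() >= 2L) |>
      dplyr::mutate(.modal = modal_value(.data[[p]])) |>
      dplyr::ungroup() |>
      dplyr::filter(.data[[p]] != .data$.modal) |>
      dplyr::transmute(site = .data$site, subject = .data$subject,
                       parameter = p,
                       modal_value = as.character(.data$.modal),
                       observed_value = as.character(.data[[p]]))
  })
}

modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  val <- names(tab)[1]
  if (is.numeric(x)) val <- as.numeric(val)
  if (is.logical(x)) val <- as.logical(val)
  val
}
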