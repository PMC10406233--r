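#' Motion traces
#'
#' A motion trace holds the six rigid-body realignment parameters per volume:
#' three rotations in degrees and three translations in mm. Degrees and mm
#' are deliberately combined at unit weight downstream — a 1 degree rotation
#' corresponds to about 1 mm of displacement at a radius of 57 mm, roughly
#' the distance from the centre of the head to the edge of the brain — so no
#' rescaling is applied when the two are mixed in the Euclidean norm.
#'
#' @param params numeric matrix with T rows and 6 columns: rotations
#'   (degrees) then translations (mm).
#' @param tr_s repetition time in seconds.
#' @return A `motion_trace` tibble with columns `rot_1..rot_3`,
#'   `trans_1..trans_3` and attribute `tr_s`.
#' @export
motion_trace <- function(params, tr_s) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion trace needs 6 columns", call. = FALSE)
  if (nrow(params) < 2L) stop("motion trace needs at least 2 time points", call. = FALSE)
  if (!all(is.finite(params))) stop("motion parameters must be finite", call. = FALSE)
  stopifnot(is.numeric(tr_s), tr_s > 0)
  out <- tibble::as_tibble(params, .name_repair = "minimal")
  names(out) <- c("rot_1", "rot_2", "rot_3", "trans_1", "trans_2", "trans_3")
  attr(out, "tr_s") <- tr_s
  class(out) <- c("motion_trace", class(out))
  out
}

trace_params <- function(trace) {
  as.matrix(trace[, c("rot_1", "rot_2", "rot_3",
                      "trans_1", "trans_2", "trans_3")])
}

#' Volume-to-volume motion (Euclidean norm of parameter differences)
#'
#' For each time point t >= 2, the Euclidean norm of the backward differences
#' of the six realignment parameters:
#' \deqn{E_t = \sqrt{\sum_{i=1}^{6} (p_{t,i} - p_{t-1,i})^2}}
#' with rotations in degrees and translations in mm entering at unit weight.
#' The first value is fixed at 0 (no preceding volume).
#'
#' @param trace a [motion_trace].
#' @return An `enorm_series` tibble with columns `t` (1-based volume index)
#'   and `enorm` (mm-equivalent), attribute `tr_s`.
#' @export
compute_enorm <- function(trace) {
  p <- trace_params(trace)
  d <- diff(p)
  e <- c(0, sqrt(rowSums(d^2)))
  out <- tibble::tibble(t = seq_len(nrow(p)), enorm = e)
  attr(out, "tr_s") <- attr(trace, "tr_s")
  class(out) <- c("enorm_series", class(out))
  out
}

new_censor_mask <- function(keep, threshold_mm) {
  out <- tibble::tibble(t = seq_along(keep), keep = as.logical(keep))
  attr(out, "threshold_mm") <- threshold_mm
  class(out) <- c("censor_mask", class(out))
  out
}

#' Motion censoring mask
#'
#' Censors every time point whose volume-to-volume motion strictly exceeds
#' the threshold, together with the time point preceding each violation (the
#' difference implicates both volumes). A point exactly at the threshold is
#' kept. Overlapping censoring windows collapse.
#'
#' @param enorm an `enorm_series` from [compute_enorm()].
#' @param threshold_mm censoring threshold in mm; must be positive.
#' @return A `censor_mask` tibble with columns `t` and `keep` (TRUE =
#'   retained) and attribute `threshold_mm`.
#' @export
censor_mask <- function(enorm, threshold_mm) {
  if (!is.numeric(threshold_mm) || length(threshold_mm) != 1L ||
      !is.finite(threshold_mm) || threshold_mm <= 0) {
    stop("censoring threshold must be a single positive number", call. = FALSE)
  }
  e <- enorm$enorm
  keep <- rep(TRUE, length(e))
  viol <- which(e > threshold_mm)
  keep[viol] <- FALSE
  keep[pmax(viol - 1L, 1L)] <- FALSE
  new_censor_mask(keep, threshold_mm)
}

#' Subject-level motion summary
#'
#' Mean and maximum of the volume-to-volume motion series (over the defined
#' differences, i.e. excluding the leading structural zero), and the amount
#' of data surviving censoring. Mean/max are computed over all differences
#' regardless of censoring so that the motion summary is a property of the
#' acquisition, not of the censoring threshold.
#'
#' @param enorm an `enorm_series`.
#' @param mask a `censor_mask` of matching length.
#' @param tr_s repetition time (s); defaults to the trace TR carried on
#'   `enorm`.
#' @return A one-row tibble: `mean_enorm_mm`, `max_enorm_mm`, `n_good`,
#'   `good_seconds`.
#' @export
motion_summary <- function(enorm, mask, tr_s = attr(enorm, "tr_s")) {
  stopifnot(nrow(enorm) == nrow(mask), is.numeric(tr_s), tr_s > 0)
  e <- enorm$enorm[-1]
  n_good <- sum(mask$keep)
  tibble::tibble(
    mean_enorm_mm = mean(e),
    max_enorm_mm = max(e),
    n_good = n_good,
    good_seconds = n_good * tr_s
  )
}
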