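#' Apply per-cell quality-control filtering
#'
#' Intensity cells whose QC flag is `FALSE` become missing; probes failing
#' QC in every sample are dropped. The control flag is preserved.
#'
#' @param pm a [probe_matrix()].
#' @return a `probe_matrix` with failed cells set to `NA`.
#' @export
qc_filter <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (nrow(pm$intensity) == 0) stop("empty probe matrix")
  x <- pm$intensity
  x[!pm$qc_pass] <- NA_real_
  keep <- rowSums(pm$qc_pass) > 0
  if (!any(keep)) stop("empty matrix after QC: every probe failed in all samples")
  out <- pm
  out$intensity <- x[keep, , drop = FALSE]
  out$qc_pass <- pm$qc_pass[keep, , drop = FALSE]
  out$is_control <- pm$is_control[keep]
  out
}

#' Two-stage median normalization and log2 transform
#'
#' Stage 1 divides every intensity on an array by the median intensity of
#' that array's control probes (cells failing QC are excluded from the
#' median). Stage 2 divides each stage-1 value by that probe's median
#' across all arrays. Probes with any remaining missing value are then
#' removed and a log2 transform is applied. Both divisors are recorded in
#' the provenance, together with the stage-1 control-probe values, so the
#' two median contracts can be verified: on the stage-1 scale every
#' array's control-probe median is exactly 1, and on the final pre-log
#' scale every retained probe's across-array median is exactly 1 (the
#' second division rescales each probe individually, so the array-level
#' control median is exact on the stage-1 scale, where it is defined).
#'
#' The output is scale-invariant per array: multiplying all intensities
#' of one array by a constant leaves it unchanged.
#'
#' @param pm a [probe_matrix()], typically after [qc_filter()].
#' @param drop_controls drop control probes from the output (default);
#'   they carry no biological signal and are only needed for the stage-1
#'   divisor.
#' @return an object of class `normalized_matrix`: `log2_value` (matrix),
#'   `probe_id`, `is_control`, `design`, and `provenance` with
#'   `array_control_median`, `probe_median`, `stage1_control`.
#' @export
normalize_probes <- function(pm, drop_controls = TRUE) {
  stopifnot(inherits(pm, "probe_matrix"))
  x <- pm$intensity
  x[!pm$qc_pass] <- NA_real_
  ctrl <- pm$is_control
  if (!any(ctrl)) stop("no control probes available for normalization")

  ctrl_med <- apply(x[ctrl, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  if (any(is.na(ctrl_med))) {
    bad <- colnames(x)[is.na(ctrl_med)]
    stop(sprintf("no usable control probes on array(s): %s",
                 paste(bad, collapse = ", ")))
  }
  x1 <- sweep(x, 2, ctrl_med, "/")
  probe_med <- apply(x1, 1, stats::median, na.rm = TRUE)
  x2 <- sweep(x1, 1, probe_med, "/")

  complete <- rowSums(is.na(x2)) == 0 & !is.na(probe_med)
  keep <- complete & (!ctrl | !drop_controls)
  if (!any(keep)) stop("no probes left after normalization")

  structure(list(
    log2_value = log2(x2[keep, , drop = FALSE]),
    probe_id = rownames(x)[keep],
    is_control = ctrl[keep],
    design = pm$design,
    provenance = list(
      array_control_median = ctrl_med,
      probe_median = probe_med,
      stage1_control = x1[ctrl, , drop = FALSE])),
    class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d probes x %d arrays (log2 scale)\n",
              nrow(x$log2_value), ncol(x$log2_value)))
  invisible(x)
}

#' Verify the normalization median contracts
#'
#' Recomputes, from a `normalized_matrix`, the per-array control-probe
#' median on the stage-1 (control-normalized) scale and the per-probe
#' across-array median on the final pre-log scale. Both must equal 1.
#'
#' @param nm a `normalized_matrix`.
#' @return list with `array_control_median` (one value per array) and
#'   `probe_median` (one value per retained probe).
#' @export
check_normalization <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  acm <- apply(nm$provenance$stage1_control, 2, stats::median, na.rm = TRUE)
  pmed <- apply(2^nm$log2_value, 1, stats::median)
  list(array_control_median = acm, probe_median = pmed)
}
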