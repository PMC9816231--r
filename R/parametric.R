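#' Parametric image container
#'
#' Holds a 3D voxel map of either tumor-to-background ratios (`"TBR"`,
#' non-negative reals) or time-to-peak groups (`"TTP"`, ordinal 1-6), with
#' provenance metadata.
#'
#' @param data 3D array.
#' @param kind `"TBR"` or `"TTP"`.
#' @param voxel_size mm per axis.
#' @param provenance Named list (background mean, schedule, ...).
#' @return Object of class `parametric_image`.
#' @export
parametric_image <- function(data, kind = c("TBR", "TTP"), voxel_size,
                             provenance = list()) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3) abort("data must be a 3D array")
  v <- data[!is.na(data)]
  if (kind == "TTP" && length(v) && !all(v %in% 1:6))
    abort("TTP values must be in 1..6")
  if (kind == "TBR" && length(v) && any(v < 0))
    abort("TBR values must be >= 0")
  structure(list(data = data, kind = kind,
                 voxel_size = rep_len(as.numeric(voxel_size), 3),
                 provenance = provenance),
            class = "parametric_image")
}

#' @export
print.parametric_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<parametric_image:%s> %d x %d x %d voxels\n",
              x$kind, d[1], d[2], d[3]))
  invisible(x)
}

#' Static summation image over a time window
#'
#' Duration-weighted mean of the frames whose intervals tile `window`. The
#' window boundaries must coincide with frame boundaries; a misaligned
#' boundary is an error naming the offending value.
#'
#' @param dyn A [dynamic_image()].
#' @param window `c(start, end)` in minutes (default the 20-40 min window
#'   used for static TBR imaging).
#' @return 3D numeric array.
#' @export
summation_image <- function(dyn, window = c(20, 40)) {
  stopifnot(inherits(dyn, "dynamic_image"))
  sch <- dyn$schedule
  for (b in window) {
    if (min(abs(c(sch$start, sch$end) - b)) > 1e-9)
      abort(sprintf("window boundary %g min does not align with any frame boundary", b),
            class = "fetrad_alignment_error")
  }
  sel <- which(sch$start >= window[1] - 1e-9 & sch$end <= window[2] + 1e-9)
  if (!length(sel)) abort("window contains no frames",
                          class = "fetrad_alignment_error")
  w <- sch$duration[sel] / sum(sch$duration[sel])
  d <- dim(dyn$data)
  out <- array(0, d[1:3])
  for (i in seq_along(sel)) out <- out + w[i] * dyn$data[, , , sel[i]]
  out
}

#' Mean background activity under a crescent VOI
#'
#' @param volume 3D numeric array (typically a 20-40 min summation image).
#' @param crescent_mask Logical array on the same grid.
#' @return Scalar mean activity; an error if the mask is empty or the mean
#'   is not positive (a positive mean is required for TBR normalisation).
#' @export
background_mean <- function(volume, crescent_mask) {
  if (!any(crescent_mask)) abort("background mask is empty")
  if (!identical(dim(volume), dim(crescent_mask)))
    abort("volume and mask grids differ")
  m <- mean(volume[crescent_mask])
  if (!is.finite(m) || m <= 0)
    abort("background mean must be > 0", class = "fetrad_normalization_error")
  m
}

#' Tumor-to-background ratio image
#'
#' Voxel-wise division of a summation image by the mean background activity.
#'
#' @param sum_20_40 3D array, the static summation image.
#' @param bg_mean Positive background mean.
#' @param voxel_size mm per axis.
#' @return A `parametric_image` of kind `"TBR"`.
#' @export
tbr_image <- function(sum_20_40, bg_mean, voxel_size = c(1, 1, 1)) {
  if (!is.numeric(bg_mean) || bg_mean <= 0)
    abort("bg_mean must be > 0", class = "fetrad_normalization_error")
  parametric_image(sum_20_40 / bg_mean, "TBR", voxel_size,
                   provenance = list(background_mean = bg_mean))
}

#' Map a peak time (minutes) to its time-to-peak group
#'
#' Groups: \[0,5) -> 1, \[5,10) -> 2, \[10,15) -> 3, \[15,20) -> 4,
#' \[20,30) -> 5, \[30,40\] -> 6.
#'
#' @param t Peak times in minutes (0 < t <= 40).
#' @return Integer group 1-6.
#' @export
ttp_group <- function(t) {
  if (any(t < 0 | t > 40)) abort("peak time must be within (0, 40] minutes")
  g <- findInterval(t, c(0, 5, 10, 15, 20, 30), rightmost.closed = FALSE)
  as.integer(pmin(g, 6L))
}

# vectorised classification: rows of `m` are voxel TACs
classify_ttp_matrix <- function(m, schedule, exclude_before = 2.7,
                                late_window = c(15, 40)) {
  mid <- schedule$mid
  keep <- mid >= exclude_before
  if (!any(keep))
    abort("all frames excluded by the early-time cut",
          class = "fetrad_degenerate_schedule")
  late <- mid >= late_window[1] & mid <= late_window[2]
  grp <- rep(NA_integer_, nrow(m))
  if (sum(late) >= 2) {
    ml <- mid[late]
    w <- (ml - mean(ml)) / sum((ml - mean(ml))^2)  # OLS slope weights
    slope <- as.numeric(m[, late, drop = FALSE] %*% w)
  } else {
    slope <- rep(0, nrow(m))
  }
  mk <- m[, keep, drop = FALSE]
  peak <- max.col(mk, ties.method = "first")  # earliest maximal frame
  grp <- ttp_group(mid[keep][peak])
  grp[slope > 0] <- 6L
  grp
}

#' Classify one time-activity curve into a time-to-peak group
#'
#' Frames whose midpoints fall before `exclude_before` minutes (default
#' 2.7 min, avoiding the early blood flush) are excluded. If the
#' least-squares slope of frame value against frame midpoint over the late
#' window (midpoints within 15-40 min) is positive, the curve is assigned
#' group 6. Otherwise the group is read off the midpoint of the earliest
#' remaining frame attaining the maximum.
#'
#' @param tac Numeric vector of frame activities.
#' @param schedule Matching [frame_schedule()].
#' @param exclude_before Minutes; frames with earlier midpoints are ignored.
#' @param late_window `c(start, end)` minutes for the late-slope test.
#' @return Integer group in 1..6.
#' @examples
#' classify_ttp(simulate_tac(kinetic_phenotype(1, 7), default_schedule()),
#'              default_schedule())
#' @export
classify_ttp <- function(tac, schedule, exclude_before = 2.7,
                         late_window = c(15, 40)) {
  if (length(tac) != nrow(schedule))
    abort("tac length must equal the number of frames")
  classify_ttp_matrix(matrix(tac, 1), schedule, exclude_before, late_window)
}

#' Time-to-peak parametric image
#'
#' Applies [classify_ttp()] to every voxel (or to the voxels of `roi_mask`
#' when given; voxels outside the mask are set to `NA`, the documented fill
#' value, and are excluded from feature extraction).
#'
#' @param dyn A [dynamic_image()].
#' @param roi_mask Optional logical array on the image grid.
#' @inheritParams classify_ttp
#' @return A `parametric_image` of kind `"TTP"`.
#' @export
ttp_image <- function(dyn, roi_mask = NULL, exclude_before = 2.7,
                      late_window = c(15, 40)) {
  stopifnot(inherits(dyn, "dynamic_image"))
  d <- dim(dyn$data)
  nv <- prod(d[1:3])
  m <- matrix(dyn$data, nv, d[4])
  if (is.null(roi_mask)) {
    grp <- classify_ttp_matrix(m, dyn$schedule, exclude_before, late_window)
  } else {
    if (!identical(dim(roi_mask), d[1:3])) abort("mask grid mismatch")
    grp <- rep(NA_integer_, nv)
    grp[roi_mask] <- classify_ttp_matrix(
      m[as.vector(roi_mask), , drop = FALSE], dyn$schedule,
      exclude_before, late_window)
  }
  parametric_image(array(as.numeric(grp), d[1:3]), "TTP", dyn$voxel_size,
                   provenance = list(schedule = dyn$schedule,
                                     exclude_before = exclude_before,
                                     late_window = late_window))
}

#' Threshold-based tumor segmentation on a TBR image
#'
#' Voxels with TBR at or above the threshold (default 1.6) form the
#' candidate mask, optionally restricted to its largest 26-connected
#' component (a tumor VOI is a single lesion; isolated suprathreshold specks
#' are discarded). An all-below-threshold image yields an empty mask, which
#' is reported distinctly via the `"empty"` attribute.
#'
#' @param tbr A `parametric_image` of kind `"TBR"`.
#' @param threshold TBR cut-off; voxels with `TBR >= threshold` are included.
#' @param largest_component Keep only the largest 26-connected component.
#' @return Logical array with attribute `empty`.
#' @export
segment_tumor <- function(tbr, threshold = 1.6, largest_component = TRUE) {
  stopifnot(inherits(tbr, "parametric_image"), tbr$kind == "TBR")
  mask <- !is.na(tbr$data) & tbr$data >= threshold
  if (!any(mask)) {
    attr(mask, "empty") <- TRUE
    return(mask)
  }
  if (largest_component) {
    lab <- cpp_label3d(as.logical(mask), dim(mask), 26L)
    tab <- tabulate(lab[lab > 0])
    keep <- which.max(tab)
    mask <- array(lab == keep, dim(mask))
  }
  attr(mask, "empty") <- FALSE
  mask
}
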