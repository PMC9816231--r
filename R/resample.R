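#' Resample an image and mask to an isotropic grid
#'
#' Trilinear interpolation for intensities and nearest-neighbour for the mask
#' (binary masks must stay binary). Voxel `i` (0-based) is centred at
#' `i * voxel_size`; the output grid starts at the same origin and covers the
#' input bounding box with `spacing`-mm isotropic voxels.
#'
#' @param image 3D numeric array or a [parametric_image()].
#' @param mask Logical 3D array on the same grid.
#' @param voxel_size Input mm per axis (taken from the image if it is a
#'   `parametric_image`).
#' @param spacing Output isotropic voxel edge in mm (default 2.03).
#' @return A list of class `fet_roi`: `image` (3D array), `mask` (logical),
#'   `spacing`, and interpolation provenance. Empty resampled masks are an
#'   error.
#' @export
resample_isotropic <- function(image, mask, voxel_size = NULL,
                               spacing = 2.03) {
  if (inherits(image, "parametric_image")) {
    if (is.null(voxel_size)) voxel_size <- image$voxel_size
    image <- image$data
  }
  if (is.null(voxel_size)) abort("voxel_size required for plain arrays")
  if (spacing <= 0) abort("spacing must be > 0")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  d <- dim(image)
  if (!identical(dim(mask), d)) abort("image and mask grids differ")

  ext <- (d - 1) * voxel_size
  nd <- pmax(floor(ext / spacing) + 1, 1)
  coords <- lapply(1:3, function(a) {
    x <- (seq_len(nd[a]) - 1) * spacing / voxel_size[a]  # input index units
    pmin(pmax(x, 0), d[a] - 1)
  })
  ix <- coords[[1]]; iy <- coords[[2]]; iz <- coords[[3]]

  i0 <- pmin(floor(ix), d[1] - 2); fx <- ix - i0
  j0 <- pmin(floor(iy), d[2] - 2); fy <- iy - j0
  k0 <- pmin(floor(iz), d[3] - 2); fz <- iz - k0
  if (d[1] == 1) { i0 <- rep(0, nd[1]); fx <- rep(0, nd[1]) }
  if (d[2] == 1) { j0 <- rep(0, nd[2]); fy <- rep(0, nd[2]) }
  if (d[3] == 1) { k0 <- rep(0, nd[3]); fz <- rep(0, nd[3]) }

  G <- expand.grid(i = seq_len(nd[1]), j = seq_len(nd[2]), k = seq_len(nd[3]))
  a0 <- i0[G$i]; b0 <- j0[G$j]; c0 <- k0[G$k]
  wx <- fx[G$i]; wy <- fy[G$j]; wz <- fz[G$k]
  val <- numeric(nrow(G))
  get <- function(da, db, dc) {
    image[cbind(pmin(a0 + da, d[1] - 1) + 1,
                pmin(b0 + db, d[2] - 1) + 1,
                pmin(c0 + dc, d[3] - 1) + 1)]
  }
  for (da in 0:1) for (db in 0:1) for (dc in 0:1) {
    w <- (if (da == 1) wx else 1 - wx) *
         (if (db == 1) wy else 1 - wy) *
         (if (dc == 1) wz else 1 - wz)
    val <- val + w * get(da, db, dc)
  }
  out_img <- array(val, nd)

  ni <- pmin(pmax(round(ix), 0), d[1] - 1) + 1
  nj <- pmin(pmax(round(iy), 0), d[2] - 1) + 1
  nk <- pmin(pmax(round(iz), 0), d[3] - 1) + 1
  out_mask <- array(mask[cbind(ni[G$i], nj[G$j], nk[G$k])], nd)

  if (!any(out_mask)) abort("resampled mask is empty")
  structure(list(image = out_img, mask = out_mask, spacing = spacing,
                 provenance = list(input_voxel_size = voxel_size,
                                   interpolation = "trilinear/nearest")),
            class = "fet_roi")
}

#' Fixed bin width from the cohort-average interquartile range
#'
#' The fixed intensity bin width is the mean over patients of the
#' interquartile range of in-ROI intensities, divided by 4. Quartiles use
#' linear interpolation of order statistics.
#'
#' @param cohort_roi_values List of numeric vectors, one per patient.
#' @return Scalar bin width; constant ROIs in every patient are an error.
#' @examples
#' compute_bin_width_iqr4(list(c(1, 2, 3, 4))) # IQR 1.5 -> 0.375
#' @export
compute_bin_width_iqr4 <- function(cohort_roi_values) {
  if (!length(cohort_roi_values)) abort("need at least one patient")
  iqrs <- vapply(cohort_roi_values, function(v) {
    if (!length(v)) abort("empty ROI")
    diff(quantile(v, c(0.25, 0.75), names = FALSE, type = 7))
  }, numeric(1))
  bw <- mean(iqrs) / 4
  if (bw <= 0) abort("all ROIs constant: zero bin width",
                     class = "fetrad_zero_width_error")
  bw
}

#' Discretize ROI intensities with a fixed bin width
#'
#' Gray level of voxel value `x` is `floor((x - min) / bin_width) + 1`, with
#' the minimum referenced to the ROI minimum and the maximum clamped to the
#' highest level. The level count is the level of the ROI maximum.
#'
#' @param roi A `fet_roi` from [resample_isotropic()].
#' @param bin_width Positive intensity width per gray level.
#' @return A list of class `fet_disc`: `levels` (integer array, `NA` outside
#'   the mask), `n_levels`, `bin_width`, plus the raw masked values.
#' @export
discretize_roi <- function(roi, bin_width) {
  stopifnot(inherits(roi, "fet_roi"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    abort("bin_width must be > 0")
  vals <- roi$image[roi$mask]
  lev <- floor((vals - min(vals)) / bin_width) + 1
  ng <- max(lev)
  lev <- pmin(lev, ng)
  arr <- array(NA_integer_, dim(roi$image))
  arr[roi$mask] <- as.integer(lev)
  structure(list(levels = arr, n_levels = as.integer(ng),
                 bin_width = bin_width, values = vals,
                 spacing = roi$spacing, mask = roi$mask),
            class = "fet_disc")
}
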