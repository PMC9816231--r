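feature_count_by_class <- c(firstorder = 18, shape = 14, glcm = 24,
                            glrlm = 16, glszm = 16, gldm = 14, ngtdm = 5)

crop_to_mask <- function(image, mask, margin = 2) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) abort("mask is empty")
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - margin, 1)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(image = image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

#' Extract the full 107-feature radiomic vector from one image
#'
#' The canonical pipeline: resample image and mask to the isotropic grid,
#' discretize with the fixed bin width, then run every feature class
#' (18 first-order + 14 shape + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
#' 5 NGTDM = 107). No image filters are applied.
#'
#' @param image A [parametric_image()] or 3D array.
#' @param mask Logical 3D array on the image grid.
#' @param bin_width Fixed intensity bin width (0.13 for TBR maps, 5 for TTP
#'   maps by convention).
#' @param spacing Isotropic resampling spacing in mm (default 2.03).
#' @param voxel_size Input voxel size (needed for plain arrays).
#' @param glcm_distance Co-occurrence distance (default 1).
#' @param gldm_alpha Dependence similarity tolerance (default 0).
#' @return A one-row tibble with 107 named feature columns.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(noise_sd = 0, seed = 2))
#' tbr <- tbr_image(summation_image(ph$image),
#'                  background_mean(summation_image(ph$image),
#'                                  ph$background_mask),
#'                  ph$image$voxel_size)
#' extract_all(tbr, ph$tumor_mask, bin_width = 0.13)
#' }
#' @export
extract_all <- function(image, mask, bin_width, spacing = 2.03,
                        voxel_size = NULL, glcm_distance = 1,
                        gldm_alpha = 0) {
  if (inherits(image, "parametric_image")) {
    if (is.null(voxel_size)) voxel_size <- image$voxel_size
    image <- image$data
  }
  # crop to the mask bounding box (2-voxel margin for interpolation support);
  # every feature is local to the mask, so this only fixes the grid origin
  bb <- crop_to_mask(image, mask, margin = 2)
  roi <- resample_isotropic(bb$image, bb$mask, voxel_size, spacing)
  disc <- discretize_roi(roi, bin_width)
  out <- c(
    first_order_features(disc),
    shape_features(roi$mask, roi$spacing),
    glcm_features(disc, glcm_distance),
    glrlm_features(disc),
    glszm_features(disc),
    gldm_features(disc, gldm_alpha),
    ngtdm_features(disc)
  )
  if (length(out) != 107 || !all(is.finite(out)))
    abort("feature extraction must yield 107 finite features")
  tibble::as_tibble(as.list(out))
}

#' Extract TBR and TTP feature tables for a whole simulated cohort
#'
#' For each patient: the 20-40 min summation image is normalised by the
#' crescent background mean into a TBR map, the voxel-wise TTP map is
#' classified from the dynamic frames, and both parametric images are fed
#' through [extract_all()] within the tumor mask. Feature columns are
#' prefixed by image kind (`TBR_`, `TTP_`).
#'
#' @param cohort Cohort tibble from [generate_cohort()] with images.
#' @param kinds Image kinds to extract, subset of `c("TBR", "TTP")`.
#' @param bin_width_tbr,bin_width_ttp Fixed bin widths per image kind.
#' @param spacing Isotropic resampling spacing in mm.
#' @return The cohort tibble (clinical columns and label, image list-columns
#'   dropped) joined with the prefixed feature columns.
#' @export
extract_cohort_features <- function(cohort, kinds = c("TBR", "TTP"),
                                    bin_width_tbr = 0.13, bin_width_ttp = 5,
                                    spacing = 2.03) {
  stopifnot(all(kinds %in% c("TBR", "TTP")))
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    img <- cohort$image[[i]]
    tm <- cohort$tumor_mask[[i]]
    feats <- list()
    if ("TBR" %in% kinds) {
      s2040 <- summation_image(img, c(20, 40))
      bg <- background_mean(s2040, cohort$background_mask[[i]])
      tbr <- tbr_image(s2040, bg, img$voxel_size)
      f <- extract_all(tbr, tm, bin_width_tbr, spacing)
      names(f) <- paste0("TBR_", names(f))
      feats <- c(feats, f)
    }
    if ("TTP" %in% kinds) {
      ttp <- ttp_image(img)
      f <- extract_all(ttp, tm, bin_width_ttp, spacing)
      names(f) <- paste0("TTP_", names(f))
      feats <- c(feats, f)
    }
    tibble::as_tibble(feats)
  })
  clin <- dplyr::select(cohort, !dplyr::any_of(
    c("image", "tumor_mask", "background_mask")))
  dplyr::bind_cols(clin, dplyr::bind_rows(rows))
}
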