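#' Dynamic PET image container
#'
#' A thin wrapper around a 4D activity array (x, y, z, frame) together with
#' its voxel size and frame schedule. Voxel indices follow the 0-based
#' convention used throughout: voxel `i` (0-based) is centred at physical
#' position `i * voxel_size`.
#'
#' @param data 4D numeric array, frame axis last.
#' @param voxel_size Length-3 numeric, mm per axis.
#' @param schedule A [frame_schedule()] whose length matches the frame axis.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, voxel_size, schedule) {
  if (length(dim(data)) != 4) abort("data must be a 4D array")
  if (dim(data)[4] != nrow(schedule))
    abort("frame axis length must equal the schedule length")
  if (!all(is.finite(data))) abort("activity values must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  structure(list(data = data, voxel_size = voxel_size, schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %d x %d x %d voxels, %d frames, %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Spherical tumor mask
#'
#' Voxels whose centre lies within `radius` mm of `center` (0-based voxel
#' coordinates).
#'
#' @param grid_shape Integer length-3 voxel counts.
#' @param voxel_size Length-3 mm per axis.
#' @param center 0-based voxel coordinates of the sphere centre.
#' @param radius Radius in mm.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(grid_shape, voxel_size, center, radius) {
  voxel_size <- rep_len(voxel_size, 3)
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1) * voxel_size[a])
  cd <- center * voxel_size
  dx2 <- outer(ax[[1]] - cd[1], ax[[2]] - cd[2],
               function(u, v) u^2 + v^2)
  arr <- outer(dx2, (ax[[3]] - cd[3])^2, `+`)
  array(arr <= radius^2, grid_shape)
}

# Analytic crescent-shaped background VOI in the contralateral (+x) half of
# the grid: a spherical shell restricted to that half, emulating the manually
# drawn healthy-hemisphere background region of clinical practice.
crescent_mask <- function(grid_shape, voxel_size) {
  voxel_size <- rep_len(voxel_size, 3)
  ext <- (grid_shape - 1) * voxel_size
  centre <- c(0.55 * ext[1], 0.5 * ext[2], 0.5 * ext[3])
  r_out <- 0.38 * min(ext)
  r_in <- 0.55 * r_out
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1) * voxel_size[a])
  d2 <- outer(outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, `+`),
              (ax[[3]] - centre[3])^2, `+`)
  shell <- d2 <= r_out^2 & d2 >= r_in^2
  xpos <- array(rep(ax[[1]] > 0.62 * ext[1], times = prod(grid_shape[2:3])),
                grid_shape)
  array(shell & xpos, grid_shape)
}

#' Specification of a dynamic PET phantom
#'
#' Defines the voxel grid, the homogeneous background kinetics, a spherical
#' tumor with a per-voxel kinetic phenotype field, and the relative Gaussian
#' noise level. The tumor sphere is placed in the left half of the grid and
#' the background crescent in the contralateral half, so the two are disjoint
#' by construction (validated).
#'
#' @param grid_shape Integer length-3 voxel counts (default 32^3).
#' @param voxel_size mm per axis (default 2 mm isotropic).
#' @param background_phenotype [kinetic_phenotype()] shared by all
#'   non-tumor voxels.
#' @param tumor_center 0-based voxel coordinates of the tumor centre.
#' @param tumor_radius Tumor radius in mm.
#' @param tumor_phenotype_field Either the name of a built-in field
#'   (`"aggressive"`, early peaks 6-8.8 min; `"indolent"`, late peaks
#'   28-36 min), a single [kinetic_phenotype()] applied uniformly, or a
#'   `function(n)` returning a data frame with columns `amplitude`,
#'   `peak_time`, `onset_time`, `shape` for `n` voxels.
#' @param noise_sd Relative Gaussian noise level (fraction of each voxel's
#'   amplitude).
#' @param schedule A [frame_schedule()].
#' @param seed Integer seed making the phantom reproducible.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32),
                         voxel_size = c(2, 2, 2),
                         background_phenotype =
                           kinetic_phenotype(1, 15, 0.5, 0.5),
                         tumor_center = NULL,
                         tumor_radius = 10,
                         tumor_phenotype_field = "aggressive",
                         noise_sd = 0.05,
                         schedule = default_schedule(),
                         seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (is.null(tumor_center)) tumor_center <- c(0.28, 0.5, 0.5) * (grid_shape - 1)
  r_vox <- tumor_radius / voxel_size
  lo <- tumor_center - r_vox
  hi <- tumor_center + r_vox
  if (any(lo < 0) || any(hi > grid_shape - 1))
    abort("tumor sphere must lie fully inside the grid",
          class = "fetrad_geometry_error")
  spec <- structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         background_phenotype = background_phenotype,
         tumor_center = tumor_center, tumor_radius = tumor_radius,
         tumor_phenotype_field = tumor_phenotype_field,
         noise_sd = noise_sd, schedule = schedule, seed = seed),
    class = "phantom_spec"
  )
  tm <- sphere_mask(grid_shape, voxel_size, tumor_center, tumor_radius)
  bm <- crescent_mask(grid_shape, voxel_size)
  if (any(tm & bm))
    abort("tumor sphere and background crescent must be disjoint",
          class = "fetrad_geometry_error")
  spec
}

# resolve a phenotype field to per-voxel parameter draws
phenotype_field_fun <- function(field) {
  if (inherits(field, "kinetic_phenotype")) {
    return(function(n) tibble::tibble(
      amplitude = rep(field$amplitude, n), peak_time = rep(field$peak_time, n),
      onset_time = rep(field$onset_time, n), shape = rep(field$shape, n)))
  }
  if (is.function(field)) return(field)
  if (is.character(field) && length(field) == 1) {
    return(switch(
      field,
      aggressive = function(n) tibble::tibble(
        amplitude = 5, peak_time = runif(n, 6, 8.8),
        onset_time = 0.5, shape = 1),
      indolent = function(n) tibble::tibble(
        amplitude = 3, peak_time = runif(n, 28, 36),
        onset_time = 0.5, shape = 2),
      abort(paste0("unknown phenotype field '", field, "'"))
    ))
  }
  abort("tumor_phenotype_field must be a phenotype, preset name or function")
}

#' Generate a dynamic PET phantom
#'
#' Every voxel's frame sequence is the frame-averaged gamma-variate of its
#' assigned phenotype: the shared background phenotype outside the tumor, and
#' a per-voxel draw from the tumor phenotype field inside it (the default
#' fields create intratumoral heterogeneity of peak times). Gaussian noise of
#' sd `noise_sd * amplitude` is added voxel-wise. Bit-identical for a fixed
#' spec and seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` ([dynamic_image()]), `tumor_mask`
#'   and `background_mask` (logical 3D arrays), and `tumor_phenotypes`
#'   (tibble of per-voxel ground-truth parameters).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(spec$seed)
  gs <- spec$grid_shape
  sch <- spec$schedule
  nf <- nrow(sch)
  nv <- prod(gs)
  tm <- sphere_mask(gs, spec$voxel_size, spec$tumor_center, spec$tumor_radius)
  bm <- crescent_mask(gs, spec$voxel_size)

  bg <- spec$background_phenotype
  bg_tac <- tac_frame_means(bg$amplitude, bg$peak_time, bg$onset_time,
                            bg$shape, sch$start, sch$end)[1, ]
  arr <- array(rep(bg_tac, each = nv), c(gs, nf))

  tum_idx <- which(tm)
  ph <- phenotype_field_fun(spec$tumor_phenotype_field)(length(tum_idx))
  if (any(ph$peak_time <= ph$onset_time))
    abort("phenotype field produced peak_time <= onset_time",
          class = "fetrad_invalid_phenotype")
  tum_tac <- tac_frame_means(ph$amplitude, ph$peak_time, ph$onset_time,
                             ph$shape, sch$start, sch$end)
  for (f in seq_len(nf)) arr[tum_idx + (f - 1) * nv] <- tum_tac[, f]

  if (spec$noise_sd > 0) {
    amp <- array(bg$amplitude, gs)
    amp[tum_idx] <- ph$amplitude
    arr <- arr + rnorm(nv * nf, sd = spec$noise_sd * as.numeric(amp))
    arr[arr < 0] <- 0
  }

  list(
    image = dynamic_image(arr, spec$voxel_size, sch),
    tumor_mask = tm,
    background_mask = bm,
    tumor_phenotypes = tibble::as_tibble(cbind(voxel = tum_idx, ph))
  )
}
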