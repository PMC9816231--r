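#' Default clinical covariate effect sizes (log-odds)
#'
#' Directions follow the established prognostic factors in IDH-wildtype
#' glioblastoma: older age, lower Karnofsky score, WHO grade 4, unmethylated
#' MGMT promoter and TERTp mutation increase short-term-survival risk; gender
#' carries a small weight. Units: log-odds per year (age), per Karnofsky
#' point (kps), and per category switch for the binary covariates.
#'
#' @return Named numeric vector.
#' @export
default_effect_sizes <- function() {
  c(age = 0.03, gender = 0.1, kps = -0.02, who_grade = 0.5,
    mgmt = -0.7, tertp = 0.6)
}

# marginal covariate distributions, defaults matched to the cohort margins of
# the target population (about 60% male, 68% WHO grade 4, 47% MGMT
# methylated, 78% TERTp mutant, median age about 59)
draw_covariates <- function(n) {
  kps_levels <- seq(40, 100, by = 10)
  kps_probs <- c(0.03, 0.05, 0.09, 0.18, 0.30, 0.23, 0.12)
  age <- rnorm(n, 59, 12)
  age <- pmin(pmax(age, 19), 78)
  tibble::tibble(
    age = round(age, 1),
    gender = rbinom(n, 1, 0.60),
    kps = sample(kps_levels, n, replace = TRUE, prob = kps_probs),
    who_grade = ifelse(rbinom(n, 1, 0.677) == 1, 4L, 3L),
    mgmt = rbinom(n, 1, 0.47),
    tertp = rbinom(n, 1, 0.78)
  )
}

# calibrate the logistic intercept so that mean event probability equals the
# target prevalence, by bisection to tolerance 1e-6
calibrate_intercept <- function(eta, prevalence, tol = 1e-6) {
  f <- function(b0) mean(plogis(b0 + eta)) - prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) abort("prevalence not reachable")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a cohort of dynamic PET patients with known ground truth
#'
#' Clinical covariates are drawn from documented marginal distributions; each
#' patient carries an aggressive (early-peaking) or indolent (late-peaking)
#' tumor kinetic phenotype, assigned independently of the outcome label. The
#' short-term-survival label is then drawn as
#' `Bernoulli(sigmoid(latent_risk))` with
#' `latent_risk = intercept + sum(effect_sizes * covariates) +
#' kinetic_effect * aggressive`, the intercept calibrated by bisection so
#' the mean event probability equals `sts_prevalence`. The kinetic phenotype
#' therefore influences the label, never the reverse.
#'
#' @param n Number of patients (>= 10).
#' @param sts_prevalence Target short-term-survivor fraction (0-1;
#'   default 0.284, forty events per 141 patients).
#' @param effect_sizes Named log-odds per covariate; see
#'   [default_effect_sizes()]. Unknown names are an error.
#' @param kinetic_effect Log-odds added for the aggressive phenotype.
#' @param aggressive_prob Marginal probability of the aggressive phenotype.
#' @param images If `TRUE`, simulate a dynamic phantom per patient
#'   (list-columns `image`, `tumor_mask`, `background_mask`); if `FALSE`
#'   return covariates, phenotypes and labels only (useful for large
#'   calibration studies).
#' @param grid_shape,voxel_size,noise_sd,schedule Passed to [phantom_spec()].
#' @param seed Integer master seed; the cohort is bit-reproducible given it.
#' @return A tibble with one row per patient: `patient_id`, the six clinical
#'   covariates, `phenotype` (`"aggressive"`/`"indolent"`), `latent_risk`,
#'   `sts_label`, and image list-columns when `images = TRUE`.
#' @examples
#' generate_cohort(20, images = FALSE, seed = 1)
#' @export
generate_cohort <- function(n, sts_prevalence = 0.284,
                            effect_sizes = default_effect_sizes(),
                            kinetic_effect = 1.5,
                            aggressive_prob = 0.45,
                            images = TRUE,
                            grid_shape = c(32, 32, 32),
                            voxel_size = c(2, 2, 2),
                            noise_sd = 0.05,
                            schedule = default_schedule(),
                            seed = 1L) {
  if (n < 10) abort("n must be >= 10")
  if (sts_prevalence <= 0 || sts_prevalence >= 1)
    abort("sts_prevalence must be in (0, 1)")
  known <- names(default_effect_sizes())
  if (is.null(names(effect_sizes)) || !all(names(effect_sizes) %in% known))
    abort(paste("unknown covariate in effect_sizes; allowed:",
                paste(known, collapse = ", ")),
          class = "fetrad_config_error")
  local_seed(seed)

  cov <- draw_covariates(n)
  phen <- ifelse(rbinom(n, 1, aggressive_prob) == 1, "aggressive", "indolent")

  beta <- setNames(numeric(length(known)), known)
  beta[names(effect_sizes)] <- effect_sizes
  x <- cbind(age = cov$age, gender = cov$gender, kps = cov$kps,
             who_grade = as.numeric(cov$who_grade == 4),
             mgmt = cov$mgmt, tertp = cov$tertp)
  eta <- as.numeric(x %*% beta[colnames(x)]) +
    kinetic_effect * (phen == "aggressive")
  b0 <- calibrate_intercept(eta, sts_prevalence)
  latent <- b0 + eta
  label <- rbinom(n, 1, plogis(latent))

  out <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    cov,
    phenotype = phen,
    latent_risk = latent,
    sts_label = label
  )

  if (images) {
    # per-patient tumor size so shape and texture features vary across the
    # cohort as they do in real lesions; the range scales with the grid so
    # every sphere fits (8-14 mm at the default 32-voxel, 2-mm grid)
    ext_x <- (grid_shape[1] - 1) * rep_len(voxel_size, 3)[1]
    radii <- runif(n, 0.13, 0.225) * ext_x
    pseeds <- sample.int(.Machine$integer.max, n)
    phantoms <- purrr::map(seq_len(n), function(i) {
      generate_phantom(phantom_spec(
        grid_shape = grid_shape, voxel_size = voxel_size,
        tumor_radius = radii[i],
        tumor_phenotype_field = phen[i], noise_sd = noise_sd,
        schedule = schedule, seed = pseeds[i]))
    })
    out$tumor_radius <- radii
    out$image <- purrr::map(phantoms, "image")
    out$tumor_mask <- purrr::map(phantoms, "tumor_mask")
    out$background_mask <- purrr::map(phantoms, "background_mask")
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Per patient: the 4D dynamic image as NIfTI with a JSON frame-timing
#' sidecar, and the tumor/background masks as 3D NIfTI. Cohort-level:
#' covariates plus labels as `covariates.csv` and the ground-truth phenotype
#' class per patient as `ground_truth.csv`.
#'
#' @param cohort A cohort tibble from [generate_cohort()] with images.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!all(c("image", "tumor_mask") %in% names(cohort)))
    abort("cohort must carry image list-columns (images = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$patient_id[i]
    img <- cohort$image[[i]]
    RNifti::writeNifti(
      RNifti::asNifti(img$data, pixdim = c(img$voxel_size, 1)),
      file.path(dir, paste0(id, "_dynamic.nii.gz")))
    write_schedule(img$schedule, file.path(dir, paste0(id, "_frames.json")))
    RNifti::writeNifti(
      RNifti::asNifti(cohort$tumor_mask[[i]] + 0L,
                      pixdim = img$voxel_size),
      file.path(dir, paste0(id, "_tumor_mask.nii.gz")))
    RNifti::writeNifti(
      RNifti::asNifti(cohort$background_mask[[i]] + 0L,
                      pixdim = img$voxel_size),
      file.path(dir, paste0(id, "_background_mask.nii.gz")))
  }
  covs <- dplyr::select(cohort, !dplyr::any_of(
    c("image", "tumor_mask", "background_mask", "phenotype", "latent_risk")))
  readr::write_csv(covs, file.path(dir, "covariates.csv"))
  readr::write_csv(
    dplyr::select(cohort, "patient_id", "phenotype", "latent_risk"),
    file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read a dynamic image written by [write_cohort()]
#'
#' @param image_path Path to a 4D NIfTI file.
#' @param sidecar_path Path to the JSON frame-timing sidecar.
#' @return A [dynamic_image()].
#' @export
read_dynamic_image <- function(image_path, sidecar_path) {
  nii <- RNifti::readNifti(image_path)
  sch <- read_schedule(sidecar_path)
  dynamic_image(array(as.numeric(nii), dim(nii)),
                RNifti::pixdim(nii)[1:3], sch)
}
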