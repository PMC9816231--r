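# The 13 unique 3D direction offsets (one per antipodal pair), distance 1.
texture_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# dispatch helper: gray-level array + dims from a fet_disc
disc_input <- function(disc) {
  list(lv = as.integer(disc$levels), dims = dim(disc$levels),
       ng = disc$n_levels, np = sum(!is.na(disc$levels)))
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- seq_len(ng)
  px <- rowSums(P)
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  I <- matrix(i, ng, ng)
  J <- t(I)
  diffk <- 0:(ng - 1)
  pd <- vapply(diffk, function(k) sum(P[abs(I - J) == k]), numeric(1))
  sumk <- 2:(2 * ng)
  ps <- vapply(sumk, function(k) sum(P[(I + J) == k]), numeric(1))
  H <- -sum(P[P > 0] * log2(P[P > 0]))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  pij <- outer(px, px)
  HXY1 <- -sum(P[P > 0] * log2(pij[P > 0]))
  HXY2 <- -sum(pij[pij > 0] * log2(pij[pij > 0]))
  da <- sum(diffk * pd)
  imc1 <- if (HX > 0) (H - HXY1) / HX else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - H)), 0))
  # maximal correlation coefficient: second eigenvalue of the transition-like
  # matrix Q over levels that occur
  pres <- which(px > 0)
  mcc <- 1
  if (length(pres) >= 2) {
    Pp <- P[pres, pres, drop = FALSE]
    pxp <- px[pres]
    Q <- matrix(0, length(pres), length(pres))
    for (kk in seq_along(pres)) {
      Q <- Q + outer(Pp[, kk], Pp[, kk]) / outer(pxp, rep(pxp[kk],
                                                          length(pres)))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(ev[2], 0))
  }
  c(
    Autocorrelation = sum(I * J * P),
    ClusterProminence = sum((I + J - 2 * mu)^4 * P),
    ClusterShade = sum((I + J - 2 * mu)^3 * P),
    ClusterTendency = sum((I + J - 2 * mu)^2 * P),
    Contrast = sum((I - J)^2 * P),
    Correlation = if (sig2 > 0) (sum(I * J * P) - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum((diffk - da)^2 * pd),
    Id = sum(P / (1 + abs(I - J))),
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + ((I - J) / ng)^2)),
    Idn = sum(P / (1 + abs(I - J) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum((P / (I - J)^2)[I != J]),
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = H,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(sumk * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = sig2
  )
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric, probability-normalised GLCMs are built for the 13 unique 3D
#' directions at the given Chebyshev distance; the 24 features are computed
#' per direction and averaged. Directions with no in-mask voxel pairs are
#' dropped from the average. Degenerate single-gray-level conventions:
#' Contrast 0, Correlation 1, ClusterProminence 0, MCC 1, Imc1 0, Imc2 0.
#'
#' @param disc A `fet_disc` from [discretize_roi()].
#' @param distance Co-occurrence offset length in voxels (default 1).
#' @return Named numeric vector of 24 features (`glcm_*`).
#' @export
glcm_features <- function(disc, distance = 1) {
  di <- disc_input(disc)
  dirs <- texture_directions() * as.integer(distance)
  counts <- cpp_glcm(di$lv, di$dims, di$ng, dirs)
  counts <- array(counts, c(di$ng, di$ng, nrow(dirs)))
  acc <- NULL
  used <- 0
  for (a in seq_len(nrow(dirs))) {
    C <- matrix(counts[, , a], di$ng, di$ng)
    S <- C + t(C)
    tot <- sum(S)
    if (tot == 0) next
    f <- glcm_features_one(S / tot)
    acc <- if (is.null(acc)) f else acc + f
    used <- used + 1
  }
  if (used == 0) {
    # single-voxel region: single-entry co-occurrence conventions
    acc <- glcm_features_one(matrix(1, 1, 1))
    used <- 1
  }
  setNames(acc / used, paste0("glcm_", names(acc)))
}

rlm_features_one <- function(P, np) {
  ng <- nrow(P); L <- ncol(P)
  nr <- sum(P)
  p <- P / nr
  i <- seq_len(ng); l <- seq_len(L)
  pg <- rowSums(p); pr <- colSums(p)
  mug <- sum(i * pg); mul <- sum(l * pr)
  Im <- matrix(i, ng, L); Lm <- matrix(l, ng, L, byrow = TRUE)
  c(
    ShortRunEmphasis = sum(p / Lm^2),
    LongRunEmphasis = sum(p * Lm^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(pr^2),
    RunPercentage = nr / np,
    GrayLevelVariance = sum(p * (Im - mug)^2),
    RunVariance = sum(p * (Lm - mul)^2),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelRunEmphasis = sum(p / Im^2),
    HighGrayLevelRunEmphasis = sum(p * Im^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (Im^2 * Lm^2)),
    ShortRunHighGrayLevelEmphasis = sum(p * Im^2 / Lm^2),
    LongRunLowGrayLevelEmphasis = sum(p * Lm^2 / Im^2),
    LongRunHighGrayLevelEmphasis = sum(p * Im^2 * Lm^2)
  )
}

#' Gray-level run-length matrix features
#'
#' Runs are maximal same-level voxel sequences along each of the 13 unique
#' 3D directions; the 16 features are computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features (`glrlm_*`).
#' @export
glrlm_features <- function(disc) {
  di <- disc_input(disc)
  dirs <- texture_directions()
  lmax <- max(di$dims)
  counts <- array(cpp_glrlm(di$lv, di$dims, di$ng, dirs),
                  c(di$ng, lmax, nrow(dirs)))
  acc <- NULL
  for (a in seq_len(nrow(dirs))) {
    f <- rlm_features_one(matrix(counts[, , a], di$ng, lmax), di$np)
    acc <- if (is.null(acc)) f else acc + f
  }
  setNames(acc / nrow(dirs), paste0("glrlm_", names(acc)))
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level; a single matrix of
#' (level, zone size) counts yields the 16 features.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features (`glszm_*`).
#' @export
glszm_features <- function(disc) {
  di <- disc_input(disc)
  z <- cpp_glszm(di$lv, di$dims)
  smax <- max(z[, 2])
  P <- matrix(0, di$ng, smax)
  for (r in seq_len(nrow(z))) P[z[r, 1], z[r, 2]] <- P[z[r, 1], z[r, 2]] + 1
  nz <- sum(P)
  p <- P / nz
  i <- seq_len(di$ng); s <- seq_len(smax)
  pg <- rowSums(p); psz <- colSums(p)
  mug <- sum(i * pg); mus <- sum(s * psz)
  Im <- matrix(i, di$ng, smax); Sm <- matrix(s, di$ng, smax, byrow = TRUE)
  out <- c(
    SmallAreaEmphasis = sum(p / Sm^2),
    LargeAreaEmphasis = sum(p * Sm^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    SizeZoneNonUniformity = sum(colSums(P)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(psz^2),
    ZonePercentage = nz / di$np,
    GrayLevelVariance = sum(p * (Im - mug)^2),
    ZoneVariance = sum(p * (Sm - mus)^2),
    ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelZoneEmphasis = sum(p / Im^2),
    HighGrayLevelZoneEmphasis = sum(p * Im^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (Im^2 * Sm^2)),
    SmallAreaHighGrayLevelEmphasis = sum(p * Im^2 / Sm^2),
    LargeAreaLowGrayLevelEmphasis = sum(p * Sm^2 / Im^2),
    LargeAreaHighGrayLevelEmphasis = sum(p * Im^2 * Sm^2)
  )
  setNames(out, paste0("glszm_", names(out)))
}

#' Gray-level dependence matrix features
#'
#' A voxel's dependence is the number of its 26-neighbours whose gray level
#' differs by at most `alpha`; the matrix counts (level, dependence) pairs
#' with dependence size `j = count + 1`.
#'
#' @inheritParams glcm_features
#' @param alpha Similarity tolerance in gray levels (default 0).
#' @return Named numeric vector of 14 features (`gldm_*`).
#' @export
gldm_features <- function(disc, alpha = 0) {
  di <- disc_input(disc)
  P <- cpp_gldm(di$lv, di$dims, di$ng, alpha)
  nd <- sum(P)
  p <- P / nd
  i <- seq_len(di$ng); j <- seq_len(ncol(P))  # dependence size = count + 1
  pg <- rowSums(p); pdep <- colSums(p)
  mug <- sum(i * pg); mud <- sum(j * pdep)
  Im <- matrix(i, di$ng, ncol(P)); Jm <- matrix(j, di$ng, ncol(P),
                                                byrow = TRUE)
  out <- c(
    SmallDependenceEmphasis = sum(p / Jm^2),
    LargeDependenceEmphasis = sum(p * Jm^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nd,
    DependenceNonUniformity = sum(colSums(P)^2) / nd,
    DependenceNonUniformityNormalized = sum(pdep^2),
    GrayLevelVariance = sum(p * (Im - mug)^2),
    DependenceVariance = sum(p * (Jm - mud)^2),
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(p / Im^2),
    HighGrayLevelEmphasis = sum(p * Im^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (Im^2 * Jm^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * Im^2 / Jm^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * Jm^2 / Im^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * Im^2 * Jm^2)
  )
  setNames(out, paste0("gldm_", names(out)))
}

#' Neighbourhood gray-tone difference matrix features
#'
#' Each in-mask voxel contributes the absolute difference between its gray
#' level and the mean level of its in-mask 26-neighbours; voxels with no
#' valid neighbour are excluded.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features (`ngtdm_*`).
#' @export
ngtdm_features <- function(disc) {
  di <- disc_input(disc)
  m <- cpp_ngtdm(di$lv, di$dims, di$ng)
  nvp <- sum(m[, 1])
  pres <- which(m[, 1] > 0)
  p <- m[, 1] / nvp
  s <- m[, 2]
  i <- seq_len(di$ng)
  ngp <- length(pres)
  pi_ <- p[pres]; si <- s[pres]; gi <- i[pres]
  denom_c <- sum(pi_ * si)
  coarseness <- if (denom_c > 0) 1 / denom_c else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(pi_, pi_) * outer(gi, gi, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(si) / nvp)
  } else 0
  # the double sums below run over ordered level pairs, as in the standard
  # definitions
  busy_den <- sum(abs(outer(gi * pi_, gi * pi_, `-`)))
  busyness <- if (busy_den > 0) denom_c / busy_den else 0
  complexity <- sum(outer(gi, gi, function(a, b) abs(a - b)) *
                      (outer(pi_ * si, pi_ * si, `+`) /
                         outer(pi_, pi_, `+`))) / nvp
  strength_den <- sum(si)
  strength <- if (strength_den > 0) {
    sum(outer(pi_, pi_, `+`) * outer(gi, gi, function(a, b) (a - b)^2)) /
      strength_den
  } else 0
  out <- c(Busyness = busyness, Coarseness = coarseness,
           Complexity = complexity, Contrast = contrast,
           Strength = strength)
  setNames(out, paste0("ngtdm_", names(out)))
}
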