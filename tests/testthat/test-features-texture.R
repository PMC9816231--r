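test_that("constant regions give the degenerate texture conventions", {
  lv <- array(1L, c(3, 3, 3))
  disc <- as_disc(lv)
  g <- glcm_features(disc)
  expect_equal(unname(g["glcm_JointEnergy"]), 1)
  expect_equal(unname(g["glcm_Contrast"]), 0)
  expect_equal(unname(g["glcm_ClusterProminence"]), 0)
  expect_equal(unname(g["glcm_Correlation"]), 1)
  expect_equal(unname(g["glcm_MCC"]), 1)
  expect_equal(unname(g["glcm_Imc1"]), 0)
  z <- glszm_features(disc)
  expect_equal(unname(z["glszm_ZoneEntropy"]), 0)
  expect_equal(unname(z["glszm_LargeAreaEmphasis"]), 27^2)
  expect_equal(unname(z["glszm_ZonePercentage"]), 1 / 27)
})

test_that("constant-region runs decompose per direction as enumerated", {
  lv <- array(1L, c(3, 3, 3))
  disc <- as_disc(lv)
  dirs <- fetrad:::texture_directions()
  # axis directions: 9 runs of length 3; plane diagonals: runs 1,2,3,2,1...
  for (a in seq_len(nrow(dirs))) {
    M <- oracle_glrlm(lv, dirs[a, ], 1, 3)
    expect_equal(sum(M %*% (1:3)), 27)  # runs tile all 27 voxels
  }
  f <- glrlm_features(disc)
  # among equal-size regions, a constant one maximises long-run emphasis:
  # every direction's runs are maximal
  set.seed(1)
  lv2 <- array(sample(1:3, 27, TRUE), c(3, 3, 3))
  f2 <- glrlm_features(as_disc(lv2))
  expect_gt(f[["glrlm_LongRunEmphasis"]], f2[["glrlm_LongRunEmphasis"]])
})

test_that("a two-level checkerboard matches the hand-built co-occurrence", {
  # 4 x 4 x 1 grid alternating along x only
  lv <- array(rep(c(1L, 2L), 8), c(4, 4, 1))
  disc <- as_disc(lv)
  # hand count for offset (1,0,0): 12 ordered pairs, all discordant ->
  # symmetric P has zero diagonal, contrast = sum p (i-j)^2 = 1
  M <- oracle_glcm(lv, c(1, 0, 0), 2)
  expect_equal(M, matrix(c(0, 12, 12, 0), 2))
  P <- M / sum(M)
  expect_equal(sum(P * (row(P) - col(P))^2), 1)
  # offset (0,1,0): all concordant pairs
  M2 <- oracle_glcm(lv, c(0, 1, 0), 2)
  expect_equal(M2, matrix(c(12, 0, 0, 12), 2))
})

test_that("an alternating two-level pattern matches a manual neighbourhood table", {
  # 3 x 3 x 1 grid, levels alternate along x
  lv <- array(c(1L, 2L, 1L, 1L, 2L, 1L, 1L, 2L, 1L), c(3, 3, 1))
  m <- oracle_ngtdm(lv, 2)
  f <- ngtdm_features(as_disc(lv))
  nvp <- sum(m[, 1])
  p <- m[, 1] / nvp
  s <- m[, 2]
  coarse <- 1 / sum(p * s)
  contrast <- (p[1] * p[2] * 2 / (2 * 1)) * (sum(s) / nvp)
  expect_equal(f[["ngtdm_Coarseness"]], coarse)
  expect_equal(f[["ngtdm_Contrast"]], contrast)
})

test_that("all texture families match brute-force oracles on random regions", {
  dirs <- fetrad:::texture_directions()
  for (seed in c(2, 5, 11)) {
    lv <- random_disc_array(c(6, 5, 6), ng = 4, seed = seed)
    disc <- as_disc(lv)
    ng <- disc$n_levels
    np <- sum(!is.na(lv))

    # GLCM: average the loop-style features over oracle matrices
    acc <- NULL; used <- 0
    for (a in seq_len(nrow(dirs))) {
      M <- oracle_glcm(lv, dirs[a, ], ng)
      if (sum(M) == 0) next
      f <- oracle_glcm_features(M / sum(M))
      acc <- if (is.null(acc)) f else acc + f
      used <- used + 1
    }
    expect_equal(unname(glcm_features(disc)), unname(acc / used),
                 tolerance = 1e-9)

    # GLRLM
    lmax <- max(dim(lv))
    acc <- NULL
    for (a in seq_len(nrow(dirs))) {
      M <- oracle_glrlm(lv, dirs[a, ], ng, lmax)
      f <- oracle_rlm_style_features(M, np, "run")
      acc <- if (is.null(acc)) f else acc + f
    }
    expect_equal(unname(glrlm_features(disc)),
                 unname(acc / nrow(dirs)), tolerance = 1e-9)

    # GLSZM via igraph components
    zones <- oracle_glszm_zones(lv)
    P <- matrix(0, ng, max(zones$size))
    for (r in seq_len(nrow(zones)))
      P[zones$level[r], zones$size[r]] <- P[zones$level[r], zones$size[r]] + 1
    expect_equal(unname(glszm_features(disc)),
                 unname(oracle_rlm_style_features(P, np, "zone")),
                 tolerance = 1e-9)

    # GLDM: matrix from the per-voxel neighbour loop, features loop-style
    MD <- oracle_gldm(lv, ng, 0)
    expect_equal(unname(fetrad:::cpp_gldm(as.integer(lv), dim(lv), ng, 0)),
                 unname(MD))
    nd <- sum(MD)
    sde <- lde <- gln <- dnn <- lgl <- hgl <- sdl <- sdh <- ldl <- ldh <- 0
    mug <- mud <- gv <- dv <- ent <- 0
    for (i in 1:ng) for (j in 1:27) {
      p <- MD[i, j] / nd
      mug <- mug + i * p; mud <- mud + j * p
    }
    for (i in 1:ng) for (j in 1:27) {
      p <- MD[i, j] / nd
      sde <- sde + p / j^2; lde <- lde + p * j^2
      lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
      sdl <- sdl + p / (i^2 * j^2); sdh <- sdh + p * i^2 / j^2
      ldl <- ldl + p * j^2 / i^2; ldh <- ldh + p * i^2 * j^2
      gv <- gv + p * (i - mug)^2; dv <- dv + p * (j - mud)^2
      if (p > 0) ent <- ent - p * log2(p)
    }
    for (i in 1:ng) gln <- gln + sum(MD[i, ])^2 / nd
    for (j in 1:27) dnn <- dnn + sum(MD[, j])^2 / nd
    expect_equal(unname(gldm_features(disc)),
                 c(sde, lde, gln, dnn, dnn / nd, gv, dv, ent, lgl, hgl,
                   sdl, sdh, ldl, ldh), tolerance = 1e-9)

    # NGTDM: table from the per-voxel loop, features from the definitions
    MN <- oracle_ngtdm(lv, ng)
    expect_equal(unname(fetrad:::cpp_ngtdm(as.integer(lv), dim(lv), ng)),
                 unname(MN), tolerance = 1e-12)
    nvp <- sum(MN[, 1])
    pv <- MN[, 1] / nvp; sv <- MN[, 2]
    pres <- which(MN[, 1] > 0)
    cb <- cbusy <- cstr <- ccompl <- 0
    for (i in pres) for (j in pres) {
      cb <- cb + pv[i] * pv[j] * (i - j)^2
      cbusy <- cbusy + abs(i * pv[i] - j * pv[j])
      cstr <- cstr + (pv[i] + pv[j]) * (i - j)^2
      ccompl <- ccompl + abs(i - j) * (pv[i] * sv[i] + pv[j] * sv[j]) /
        (pv[i] + pv[j])
    }
    o_ngtdm <- c(
      Busyness = if (cbusy > 0) sum(pv * sv) / cbusy else 0,
      Coarseness = if (sum(pv * sv) > 0) 1 / sum(pv * sv) else 1e6,
      Complexity = ccompl / nvp,
      Contrast = if (length(pres) > 1)
        cb / (length(pres) * (length(pres) - 1)) * sum(sv) / nvp else 0,
      Strength = if (sum(sv) > 0) cstr / sum(sv) else 0)
    expect_equal(unname(ngtdm_features(disc)), unname(o_ngtdm),
                 tolerance = 1e-9)
  }
})

test_that("texture extraction is bit-deterministic", {
  lv <- random_disc_array(c(5, 5, 5), ng = 3, seed = 8)
  disc <- as_disc(lv)
  expect_identical(glcm_features(disc), glcm_features(disc))
  expect_identical(glszm_features(disc), glszm_features(disc))
})
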