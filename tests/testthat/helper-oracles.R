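# Independent brute-force oracles. These deliberately use different
# mechanisms from the package implementation (adaptive quadrature, rle() on
# extracted lattice lines, igraph components, explicit voxel loops) so that
# agreement is evidence, not tautology.

# frame-averaged gamma-variate by adaptive quadrature
oracle_frame_means <- function(phenotype, schedule) {
  f <- function(t) tac_value(phenotype, t)
  vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$start[i]; b <- schedule$end[i]
    stats::integrate(f, a, b, rel.tol = 1e-10,
                     subdivisions = 400L)$value / (b - a)
  }, numeric(1))
}

# all 26 neighbour offsets
offsets26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# symmetric GLCM for one direction by explicit voxel loop
oracle_glcm <- function(lv, off, ng) {
  d <- dim(lv)
  M <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v1 <- lv[i, j, k]
    if (is.na(v1)) next
    for (s in c(1, -1)) {
      p <- c(i, j, k) + s * off
      if (any(p < 1) || any(p > d)) next
      v2 <- lv[p[1], p[2], p[3]]
      if (is.na(v2)) next
      M[v1, v2] <- M[v1, v2] + 1
    }
  }
  M
}

# run-length counts for one direction using rle() on extracted lattice lines
oracle_glrlm <- function(lv, dir, ng, lmax) {
  d <- dim(lv)
  M <- matrix(0, ng, lmax)
  starts <- which(array(TRUE, d), arr.ind = TRUE)
  prev <- sweep(starts, 2, dir)
  is_start <- prev[, 1] < 1 | prev[, 1] > d[1] |
    prev[, 2] < 1 | prev[, 2] > d[2] | prev[, 3] < 1 | prev[, 3] > d[3]
  for (r in which(is_start)) {
    p <- starts[r, ]
    line <- integer(0)
    while (all(p >= 1) && all(p <= d)) {
      line <- c(line, lv[p[1], p[2], p[3]])
      p <- p + dir
    }
    rl <- rle(line)
    for (q in seq_along(rl$lengths)) {
      v <- rl$values[q]
      if (!is.na(v)) M[v, rl$lengths[q]] <- M[v, rl$lengths[q]] + 1
    }
  }
  M
}

# zones via igraph connected components over equal-level 26-neighbours
oracle_glszm_zones <- function(lv) {
  d <- dim(lv)
  vox <- which(!is.na(lv))
  if (!length(vox)) return(data.frame(level = integer(0), size = integer(0)))
  pos <- arrayInd(vox, d)
  key <- setNames(seq_along(vox), vox)
  offs <- offsets26()
  edges <- integer(0)
  for (r in seq_along(vox)) {
    for (m in seq_len(nrow(offs))) {
      p <- pos[r, ] + offs[m, ]
      if (any(p < 1) || any(p > d)) next
      lin <- (p[3] - 1) * d[1] * d[2] + (p[2] - 1) * d[1] + p[1]
      rr <- key[as.character(lin)]
      if (is.na(rr) || rr <= r) next
      if (lv[vox[rr]] == lv[vox[r]]) edges <- c(edges, r, rr)
    }
  }
  g <- igraph::make_graph(edges, n = length(vox), directed = FALSE)
  comp <- igraph::components(g)
  data.frame(level = vapply(seq_len(comp$no), function(cc)
    lv[vox[comp$membership == cc][1]], numeric(1)),
    size = as.integer(comp$csize))
}

oracle_gldm <- function(lv, ng, alpha = 0) {
  d <- dim(lv)
  offs <- offsets26()
  M <- matrix(0, ng, 27)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- lv[i, j, k]
    if (is.na(v)) next
    dep <- 0
    for (m in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[m, ]
      if (any(p < 1) || any(p > d)) next
      v2 <- lv[p[1], p[2], p[3]]
      if (!is.na(v2) && abs(v - v2) <= alpha) dep <- dep + 1
    }
    M[v, dep + 1] <- M[v, dep + 1] + 1
  }
  M
}

oracle_ngtdm <- function(lv, ng) {
  d <- dim(lv)
  offs <- offsets26()
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- lv[i, j, k]
    if (is.na(v)) next
    nb <- c()
    for (m in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[m, ]
      if (any(p < 1) || any(p > d)) next
      v2 <- lv[p[1], p[2], p[3]]
      if (!is.na(v2)) nb <- c(nb, v2)
    }
    if (!length(nb)) next
    n_i[v] <- n_i[v] + 1
    s_i[v] <- s_i[v] + abs(v - mean(nb))
  }
  cbind(n_i, s_i)
}

# single-TAC classification written from the rule statement, loop style
oracle_classify <- function(tac, schedule, exclude_before = 2.7) {
  mid <- (schedule$start + schedule$end) / 2
  late <- which(mid >= 15 & mid <= 40)
  if (length(late) >= 2) {
    fit <- stats::lm(y ~ x, data = data.frame(x = mid[late], y = tac[late]))
    if (unname(stats::coef(fit)[2]) > 0) return(6L)
  }
  ok <- which(mid >= exclude_before)
  best <- ok[which(tac[ok] == max(tac[ok]))[1]]
  m <- mid[best]
  breaks <- c(0, 5, 10, 15, 20, 30, 40)
  for (g in 1:6) if (m >= breaks[g] && m < breaks[g + 1] ||
                     (g == 6 && m == 40)) return(g)
  stop("unclassified")
}

# small random discretized ROI (levels with NA shell outside an ellipsoid-ish
# random mask)
random_disc_array <- function(dims, ng, seed, p_mask = 0.8) {
  set.seed(seed)
  arr <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  m <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(m)) m[1] <- TRUE
  arr[!m] <- NA_integer_
  arr
}

# wrap a level array as a fet_disc without resampling
as_disc <- function(lv, spacing = 1, bin_width = 1) {
  structure(list(levels = lv, n_levels = max(lv, na.rm = TRUE),
                 bin_width = bin_width,
                 values = as.numeric(lv[!is.na(lv)]),
                 spacing = spacing, mask = !is.na(lv)),
            class = "fet_disc")
}

# loop-style second implementations of the texture feature formulas,
# computed from oracle-built matrices
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + P[i, j]
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * px[i]
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  acc <- autoc <- cp <- cs <- ct <- con <- id <- idm <- idmn <- idn <- 0
  iv <- je <- 0; H <- 0; mp <- 0; ss <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    autoc <- autoc + i * j * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    con <- con + (i - j)^2 * p
    id <- id + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / ng)^2)
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + p / (i - j)^2
    je <- je + p^2
    if (p > 0) H <- H - p * log2(p)
    if (p > mp) mp <- p
    ss <- ss + (i - mu)^2 * p
  }
  da <- 0
  for (k in seq_along(pd)) da <- da + (k - 1) * pd[k]
  de <- 0; dv <- 0
  for (k in seq_along(pd)) {
    if (pd[k] > 0) de <- de - pd[k] * log2(pd[k])
    dv <- dv + (k - 1 - da)^2 * pd[k]
  }
  sa <- 0; se <- 0
  for (k in seq_along(ps)) {
    sa <- sa + (k + 1) * ps[k]
    if (ps[k] > 0) se <- se - ps[k] * log2(ps[k])
  }
  HX <- 0
  for (i in 1:ng) if (px[i] > 0) HX <- HX - px[i] * log2(px[i])
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * px[j]
    if (P[i, j] > 0) HXY1 <- HXY1 - P[i, j] * log2(q)
    if (q > 0) HXY2 <- HXY2 - q * log2(q)
  }
  pres <- which(px > 0)
  mcc <- 1
  if (length(pres) >= 2) {
    np <- length(pres)
    Q <- matrix(0, np, np)
    for (a in seq_len(np)) for (b in seq_len(np)) {
      s <- 0
      for (cc in seq_len(np)) {
        s <- s + P[pres[a], pres[cc]] * P[pres[b], pres[cc]] /
          (px[pres[a]] * px[pres[cc]])
      }
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    mcc <- sqrt(max(ev[2], 0))
  }
  c(Autocorrelation = autoc, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = con,
    Correlation = if (sig2 > 0) (autoc - mu^2) / sig2 else 1,
    DifferenceAverage = da, DifferenceEntropy = de, DifferenceVariance = dv,
    Id = id, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = if (HX > 0) (H - HXY1) / HX else 0,
    Imc2 = sqrt(max(1 - exp(-2 * (HXY2 - H)), 0)),
    InverseVariance = iv, JointAverage = mu, JointEnergy = je,
    JointEntropy = H, MCC = mcc, MaximumProbability = mp,
    SumAverage = sa, SumEntropy = se, SumSquares = ss)
}

oracle_rlm_style_features <- function(P, np, kind = c("run", "zone")) {
  kind <- match.arg(kind)
  ng <- nrow(P); L <- ncol(P)
  nr <- sum(P)
  sre <- lre <- gln <- rln <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- 0
  for (i in 1:ng) for (l in 1:L) {
    p <- P[i, l] / nr
    sre <- sre + p / l^2; lre <- lre + p * l^2
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    srl <- srl + p / (i^2 * l^2); srh <- srh + p * i^2 / l^2
    lrl <- lrl + p * l^2 / i^2; lrh <- lrh + p * i^2 * l^2
  }
  for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  for (l in 1:L) rln <- rln + sum(P[, l])^2
  mug <- 0; mul <- 0
  for (i in 1:ng) for (l in 1:L) {
    mug <- mug + i * P[i, l] / nr; mul <- mul + l * P[i, l] / nr
  }
  gv <- rv <- ent <- 0
  for (i in 1:ng) for (l in 1:L) {
    p <- P[i, l] / nr
    gv <- gv + p * (i - mug)^2; rv <- rv + p * (l - mul)^2
    if (p > 0) ent <- ent - p * log2(p)
  }
  base <- c(sre, lre, gln / nr, gln / nr^2, rln / nr, rln / nr^2, nr / np,
            gv, rv, ent, lgl, hgl, srl, srh, lrl, lrh)
  names(base) <- if (kind == "run") {
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  } else {
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  }
  base
}

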