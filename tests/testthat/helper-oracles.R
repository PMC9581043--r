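# Brute-force texture oracles: explicit enumeration of pixel pairs, runs,
# zones and dependence counts in plain R with scalar loops, independent of
# the package's vectorized/C++ implementations.

inside3 <- function(v, d) all(v >= 1) && all(v <= d)

# wrap an integer level array (0 = outside mask) as a discretized_volume
make_dvol <- function(lev, ng, spacing = c(1, 1, 1), values = NULL) {
  lev <- array(as.integer(lev), dim = dim(lev))
  if (is.null(values)) values <- as.numeric(lev[lev > 0L])
  structure(list(levels = lev, ng = as.integer(ng), values = values,
                 n_voxels = sum(lev > 0L), dims = dim(lev),
                 spacing = spacing),
            class = "discretized_volume")
}

oracle_glcm_matrix <- function(lev, ng, off) {
  d <- dim(lev)
  P <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    q <- c(x, y, z) + off
    if (!inside3(q, d)) next
    b <- lev[q[1], q[2], q[3]]
    if (b == 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  p <- P / sum(P)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:ng) { sx2 <- sx2 + (i - mux)^2 * px[i]; sy2 <- sy2 + (i - muy)^2 * py[i] }
  pd <- numeric(ng)            # |i-j| = k marginal, k = 0..ng-1
  ps <- numeric(2 * ng)        # i+j = k marginal, k = 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j] <- ps[i + j] + p[i, j]
  }
  ent <- function(q) { s <- 0; for (v in q) if (v > 0) s <- s - v * log2(v); s }
  hxy <- ent(as.vector(p)); hx <- ent(px); hy <- ent(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (px[i] * py[j] > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  acc <- function(f) { s <- 0; for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j) * p[i, j]; s }
  out <- c(
    Autocorrelation = acc(function(i, j) i * j),
    JointAverage = acc(function(i, j) i),
    ClusterProminence = acc(function(i, j) (i + j - mux - muy)^4),
    ClusterShade = acc(function(i, j) (i + j - mux - muy)^3),
    ClusterTendency = acc(function(i, j) (i + j - mux - muy)^2),
    Contrast = acc(function(i, j) (i - j)^2),
    Correlation = if (sx2 > 0 && sy2 > 0)
      (acc(function(i, j) i * j) - mux * muy) / sqrt(sx2 * sy2) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = { s <- 0; for (k in 0:(ng - 1)) s <- s + (k - da)^2 * pd[k + 1]; s },
    JointEnergy = { s <- 0; for (i in 1:ng) for (j in 1:ng) s <- s + p[i, j]^2; s },
    JointEntropy = hxy,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    Idm = acc(function(i, j) 1 / (1 + (i - j)^2)),
    Idmn = acc(function(i, j) 1 / (1 + ((i - j) / ng)^2)),
    Id = acc(function(i, j) 1 / (1 + abs(i - j))),
    Idn = acc(function(i, j) 1 / (1 + abs(i - j) / ng)),
    InverseVariance = acc(function(i, j) if (i != j) 1 / (i - j)^2 else 0),
    MaximumProbability = max(p),
    SumEntropy = ent(ps),
    SumSquares = acc(function(i, j) (i - mux)^2)
  )
  out
}

oracle_glrlm_matrix <- function(lev, ng, dir, maxlen) {
  d <- dim(lev)
  P <- matrix(0, ng, maxlen)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    prev <- c(x, y, z) - dir
    if (inside3(prev, d) && lev[prev[1], prev[2], prev[3]] == a) next
    len <- 1
    cur <- c(x, y, z) + dir
    while (inside3(cur, d) && lev[cur[1], cur[2], cur[3]] == a) {
      len <- len + 1
      cur <- cur + dir
    }
    P[a, len] <- P[a, len] + 1
  }
  P
}

oracle_glrlm_features <- function(P, np) {
  ng <- nrow(P); ml <- ncol(P)
  nr <- sum(P)
  acc <- function(f) { s <- 0; for (i in 1:ng) for (j in 1:ml) s <- s + f(i, j) * P[i, j]; s }
  rsum <- rowSums(P); csum <- colSums(P)
  mui <- acc(function(i, j) i) / nr
  muj <- acc(function(i, j) j) / nr
  rent <- 0
  for (i in 1:ng) for (j in 1:ml) if (P[i, j] > 0) {
    q <- P[i, j] / nr; rent <- rent - q * log2(q)
  }
  c(ShortRunEmphasis = acc(function(i, j) 1 / j^2) / nr,
    LongRunEmphasis = acc(function(i, j) j^2) / nr,
    GrayLevelNonUniformity = sum(rsum^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rsum^2) / nr^2,
    RunLengthNonUniformity = sum(csum^2) / nr,
    RunLengthNonUniformityNormalized = sum(csum^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = acc(function(i, j) (i - mui)^2) / nr,
    RunVariance = acc(function(i, j) (j - muj)^2) / nr,
    RunEntropy = rent,
    LowGrayLevelRunEmphasis = acc(function(i, j) 1 / i^2) / nr,
    HighGrayLevelRunEmphasis = acc(function(i, j) i^2) / nr,
    ShortRunLowGrayLevelEmphasis = acc(function(i, j) 1 / (i^2 * j^2)) / nr,
    ShortRunHighGrayLevelEmphasis = acc(function(i, j) i^2 / j^2) / nr,
    LongRunLowGrayLevelEmphasis = acc(function(i, j) j^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = acc(function(i, j) i^2 * j^2) / nr)
}

# zones by breadth-first flood fill over the 26-neighbourhood
oracle_glszm_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, dim = d)
  zones <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0 || seen[x, y, z]) next
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (inside3(w, d) && !seen[w[1], w[2], w[3]] &&
            lev[w[1], w[2], w[3]] == a) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    zones <- rbind(zones, c(a, size))
  }
  zones
}

oracle_glszm_features <- function(zones, np) {
  nz <- nrow(zones)
  i <- zones[, 1]; s <- zones[, 2]
  acc <- function(f) { v <- 0; for (r in 1:nz) v <- v + f(i[r], s[r]); v }
  gl_counts <- table(i); sz_counts <- table(s)
  mui <- acc(function(a, b) a) / nz
  mus <- acc(function(a, b) b) / nz
  cell <- table(paste(i, s))
  zent <- 0
  for (v in as.vector(cell)) { q <- v / nz; zent <- zent - q * log2(q) }
  c(SmallAreaEmphasis = acc(function(a, b) 1 / b^2) / nz,
    LargeAreaEmphasis = acc(function(a, b) b^2) / nz,
    GrayLevelNonUniformity = sum(as.vector(gl_counts)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(as.vector(gl_counts)^2) / nz^2,
    SizeZoneNonUniformity = sum(as.vector(sz_counts)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(as.vector(sz_counts)^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = acc(function(a, b) (a - mui)^2) / nz,
    ZoneVariance = acc(function(a, b) (b - mus)^2) / nz,
    ZoneEntropy = zent,
    LowGrayLevelZoneEmphasis = acc(function(a, b) 1 / a^2) / nz,
    HighGrayLevelZoneEmphasis = acc(function(a, b) a^2) / nz,
    SmallAreaLowGrayLevelEmphasis = acc(function(a, b) 1 / (a^2 * b^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = acc(function(a, b) a^2 / b^2) / nz,
    LargeAreaLowGrayLevelEmphasis = acc(function(a, b) b^2 / a^2) / nz,
    LargeAreaHighGrayLevelEmphasis = acc(function(a, b) a^2 * b^2) / nz)
}

# per-voxel dependence counts over the 26-neighbourhood
oracle_gldm_deps <- function(lev, alpha = 0) {
  d <- dim(lev)
  deps <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    cnt <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- c(x + dx, y + dy, z + dz)
      if (!inside3(w, d)) next
      b <- lev[w[1], w[2], w[3]]
      if (b > 0 && abs(b - a) <= alpha) cnt <- cnt + 1
    }
    deps <- rbind(deps, c(a, cnt))
  }
  deps
}

oracle_gldm_features <- function(deps) {
  nz <- nrow(deps)
  i <- deps[, 1]; j <- deps[, 2] + 1
  acc <- function(f) { v <- 0; for (r in 1:nz) v <- v + f(i[r], j[r]); v }
  mui <- acc(function(a, b) a) / nz
  muj <- acc(function(a, b) b) / nz
  cell <- table(paste(i, j))
  dent <- 0
  for (v in as.vector(cell)) { q <- v / nz; dent <- dent - q * log2(q) }
  c(SmallDependenceEmphasis = acc(function(a, b) 1 / b^2) / nz,
    LargeDependenceEmphasis = acc(function(a, b) b^2) / nz,
    GrayLevelNonUniformity = sum(as.vector(table(i))^2) / nz,
    DependenceNonUniformity = sum(as.vector(table(j))^2) / nz,
    DependenceNonUniformityNormalized = sum(as.vector(table(j))^2) / nz^2,
    GrayLevelVariance = acc(function(a, b) (a - mui)^2) / nz,
    DependenceVariance = acc(function(a, b) (b - muj)^2) / nz,
    DependenceEntropy = dent,
    LowGrayLevelEmphasis = acc(function(a, b) 1 / a^2) / nz,
    HighGrayLevelEmphasis = acc(function(a, b) a^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = acc(function(a, b) 1 / (a^2 * b^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = acc(function(a, b) a^2 / b^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = acc(function(a, b) b^2 / a^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = acc(function(a, b) a^2 * b^2) / nz)
}

# full-oracle feature sets for one level array, mirroring the package's
# direction handling (directions without pairs are excluded from the mean)
oracle_texture_all <- function(lev, ng) {
  dirs <- radpath::directions_3d()
  np <- sum(lev > 0)
  glcm_list <- list(); glrlm_list <- list()
  for (r in seq_len(nrow(dirs))) {
    P <- oracle_glcm_matrix(lev, ng, dirs[r, ])
    if (sum(P) > 0) glcm_list[[length(glcm_list) + 1]] <- oracle_glcm_features(P)
    R <- oracle_glrlm_matrix(lev, ng, dirs[r, ], max(dim(lev)))
    if (sum(R) > 0) glrlm_list[[length(glrlm_list) + 1]] <- oracle_glrlm_features(R, np)
  }
  list(
    glcm = if (length(glcm_list)) colMeans(do.call(rbind, glcm_list)) else NULL,
    glrlm = if (length(glrlm_list)) colMeans(do.call(rbind, glrlm_list)) else NULL,
    glszm = oracle_glszm_features(oracle_glszm_zones(lev), np),
    gldm = oracle_gldm_features(oracle_gldm_deps(lev))
  )
}

# random masked level array for property tests
random_levels <- function(dims, ng, p_mask = 0.8) {
  lev <- array(0L, dim = dims)
  n <- prod(dims)
  inmask <- runif(n) < p_mask
  if (!any(inmask)) inmask[1] <- TRUE
  lev[inmask] <- sample.int(ng, sum(inmask), replace = TRUE)
  lev
}
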