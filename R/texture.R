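# Texture feature classes: GLCM, GLRLM, GLSZM, GLDM (and optional NGTDM).
# Matrices are accumulated in C++ over the 13 unique 3D direction offsets at
# distance 1 (or a caller-supplied direction set); features are averaged over
# directions that contain at least one pair/run.

#' The 13 unique 3D direction offsets at distance 1
#'
#' One representative of each +/- pair of the 26-neighbourhood.
#' @return integer matrix, 13 x 3.
#' @export
directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] == 1 | (g[, 3] == 0 & g[, 2] == 1) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] == 1)
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

# features of one symmetric co-occurrence count matrix
glcm_features_from_matrix <- function(P) {
  tot <- sum(P)
  if (tot == 0) return(setNames(rep(NA_real_, length(GLCM_NAMES)), GLCM_NAMES))
  ng <- nrow(P)
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px)); sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # difference |i-j| and sum i+j marginals
  k_d <- 0:(ng - 1)
  pd <- vapply(k_d, function(k) sum(p[abs(i - j) == k]), 0)
  k_s <- 2:(2 * ng)
  ps <- vapply(k_s, function(k) sum(p[(i + j) == k]), 0)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  pxy <- outer(px, py)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent(pxy)
  hx <- ent(px); hy <- ent(py)
  da <- sum(k_d * pd)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 1
  c(Autocorrelation = sum(i * j * p),
    JointAverage = sum(i * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = sum((k_d - da)^2 * pd),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    MaximumProbability = max(p),
    SumEntropy = ent(ps),
    SumSquares = sum((i - mux)^2 * p))
}

average_directions <- function(mat_feats) {
  ok <- !vapply(mat_feats, function(f) all(is.na(f)), logical(1))
  if (!any(ok)) return(mat_feats[[1]])
  colMeans(do.call(rbind, mat_feats[ok]))
}

#' Gray-level co-occurrence features
#'
#' Symmetric, per-direction-normalized GLCMs at distance 1; 22 features
#' averaged over the direction set. Directions with no voxel pair (and a mask
#' with a single voxel) yield missing values.
#'
#' @param d a [discretize()] result.
#' @param directions integer matrix of direction offsets (rows), default the
#'   13 unique 3D offsets.
#' @return named numeric vector of 22 features (`glcm__*`).
#' @export
glcm_features <- function(d, directions = directions_3d()) {
  arr <- cpp_glcm(as.integer(d$levels), d$dims, d$ng, directions)
  feats <- lapply(seq_len(dim(arr)[3]), function(k) {
    glcm_features_from_matrix(matrix(arr[, , k], d$ng, d$ng))
  })
  out <- average_directions(feats)
  names(out) <- paste0("glcm__", GLCM_NAMES)
  out
}

# P: Ng x maxlen run-count matrix for one direction; np: in-mask voxel count
glrlm_features_from_matrix <- function(P, np) {
  nr <- sum(P)
  if (nr == 0) return(setNames(rep(NA_real_, length(GLRLM_NAMES)), GLRLM_NAMES))
  i <- row(P); j <- col(P)
  p <- P / nr
  mui <- sum(i * p); muj <- sum(j * p)
  pnz <- p[p > 0]
  c(ShortRunEmphasis = sum(P / col(P)^2) / nr,
    LongRunEmphasis = sum(P * col(P)^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum((i - mui)^2 * p),
    RunVariance = sum((j - muj)^2 * p),
    RunEntropy = -sum(pnz * log2(pnz)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr)
}

#' Gray-level run-length features
#'
#' Run-length matrices \eqn{P(i,j|\theta)} per direction with run count
#' \eqn{N_r(\theta)}; 16 features averaged over the direction set, including
#' LongRunLowGrayLevelEmphasis
#' \eqn{F_L = \frac{1}{N_r(\theta)} \sum_i \sum_j P(i,j|\theta)\, j^2 / i^2}.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features (`glrlm__*`).
#' @export
glrlm_features <- function(d, directions = directions_3d()) {
  maxlen <- max(d$dims)
  arr <- cpp_glrlm(as.integer(d$levels), d$dims, d$ng, directions, maxlen)
  feats <- lapply(seq_len(dim(arr)[3]), function(k) {
    glrlm_features_from_matrix(matrix(arr[, , k], d$ng, maxlen), d$n_voxels)
  })
  out <- average_directions(feats)
  names(out) <- paste0("glrlm__", GLRLM_NAMES)
  out
}

glszm_features_from_zones <- function(zones, ng, np) {
  nz <- nrow(zones)
  if (nz == 0) return(setNames(rep(NA_real_, length(GLSZM_NAMES)), GLSZM_NAMES))
  i <- zones[, 1]; s <- zones[, 2]     # per-zone level and size
  p <- rep(1 / nz, nz)
  mui <- sum(i * p); mus <- sum(s * p)
  # entropy over the (level, size) cells of the implied matrix
  key <- paste(i, s)
  cellp <- as.vector(table(key)) / nz
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = sum(as.vector(table(i))^2) / nz,
    GrayLevelNonUniformityNormalized = sum(as.vector(table(i))^2) / nz^2,
    SizeZoneNonUniformity = sum(as.vector(table(s))^2) / nz,
    SizeZoneNonUniformityNormalized = sum(as.vector(table(s))^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum((i - mui)^2 * p),
    ZoneVariance = sum((s - mus)^2 * p),
    ZoneEntropy = -sum(cellp * log2(cellp)),
    LowGrayLevelZoneEmphasis = mean(1 / i^2),
    HighGrayLevelZoneEmphasis = mean(i^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (i^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(i^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = mean(i^2 * s^2))
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level; 16 features of the
#' size-zone matrix \eqn{P(i,j)} with zone count \eqn{N_z}, including
#' SmallAreaLowGrayLevelEmphasis
#' \eqn{F_{SALGLE} = \frac{1}{N_z} \sum_i \sum_j P(i,j) / (i^2 j^2)}.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features (`glszm__*`).
#' @export
glszm_features <- function(d) {
  zones <- cpp_glszm_zones(as.integer(d$levels), d$dims)
  out <- glszm_features_from_zones(zones, d$ng, d$n_voxels)
  names(out) <- paste0("glszm__", GLSZM_NAMES)
  out
}

gldm_features_from_deps <- function(deps) {
  nz <- nrow(deps)
  if (nz == 0) return(setNames(rep(NA_real_, length(GLDM_NAMES)), GLDM_NAMES))
  i <- deps[, 1]; j <- deps[, 2] + 1   # dependence size = dependent count + 1
  p <- rep(1 / nz, nz)
  mui <- sum(i * p); muj <- sum(j * p)
  key <- paste(i, j)
  cellp <- as.vector(table(key)) / nz
  c(SmallDependenceEmphasis = mean(1 / j^2),
    LargeDependenceEmphasis = mean(j^2),
    GrayLevelNonUniformity = sum(as.vector(table(i))^2) / nz,
    DependenceNonUniformity = sum(as.vector(table(j))^2) / nz,
    DependenceNonUniformityNormalized = sum(as.vector(table(j))^2) / nz^2,
    GrayLevelVariance = sum((i - mui)^2 * p),
    DependenceVariance = sum((j - muj)^2 * p),
    DependenceEntropy = -sum(cellp * log2(cellp)),
    LowGrayLevelEmphasis = mean(1 / i^2),
    HighGrayLevelEmphasis = mean(i^2),
    SmallDependenceLowGrayLevelEmphasis = mean(1 / (i^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = mean(i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = mean(j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = mean(i^2 * j^2))
}

#' Gray-level dependence features
#'
#' A voxel's dependence size is one plus the number of 26-neighbours within
#' the mask whose level differs by at most `alpha` (default 0, exact
#' equality); 14 standard features of the dependence matrix.
#'
#' @inheritParams glcm_features
#' @param alpha gray-level similarity tolerance (integer >= 0).
#' @return named numeric vector of 14 features (`gldm__*`).
#' @export
gldm_features <- function(d, alpha = 0L) {
  deps <- cpp_gldm_deps(as.integer(d$levels), d$dims, as.integer(alpha))
  out <- gldm_features_from_deps(deps)
  names(out) <- paste0("gldm__", GLDM_NAMES)
  out
}

#' Neighbouring gray-tone difference features
#'
#' Optional texture class (off in the default bank): per level \eqn{i}, the
#' accumulated absolute difference \eqn{s_i} between the level and the mean of
#' its in-mask 26-neighbours, with occupancy probabilities \eqn{p_i}.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features (`ngtdm__*`).
#' @export
ngtdm_features <- function(d) {
  m <- cpp_ngtdm(as.integer(d$levels), d$dims, d$ng)
  n_i <- m[, 1]; s_i <- m[, 2]
  nvp <- sum(n_i)
  out <- setNames(rep(NA_real_, 5), NGTDM_NAMES)
  if (nvp > 0) {
    p_i <- n_i / nvp
    act <- which(p_i > 0)
    ngp <- length(act)
    lev <- seq_len(d$ng)
    coars <- 1 / max(sum(p_i * s_i), 1e-6)
    contr <- if (ngp > 1) {
      s1 <- 0
      for (a in act) for (b in act) s1 <- s1 + p_i[a] * p_i[b] * (a - b)^2
      (s1 / (ngp * (ngp - 1))) * (sum(s_i) / nvp)
    } else 0
    busy_den <- 0
    for (a in act) for (b in act) busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
    busy <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
    compl <- 0
    for (a in act) for (b in act) {
      compl <- compl + abs(a - b) / (nvp * (p_i[a] + p_i[b])) *
        (p_i[a] * s_i[a] + p_i[b] * s_i[b])
    }
    stren <- 0
    for (a in act) for (b in act) stren <- stren + (p_i[a] + p_i[b]) * (a - b)^2
    stren <- if (sum(s_i) > 0) stren / sum(s_i) else 0
    out[] <- c(coars, contr, busy, compl, stren)
  }
  names(out) <- paste0("ngtdm__", NGTDM_NAMES)
  out
}
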