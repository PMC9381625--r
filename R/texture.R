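# Forced-2D texture features. Matrices are built per axial slice (and per
# in-plane direction for GLCM/GLRLM) at distance 1, so each interior voxel
# has 8 texture neighbors; feature values are averaged uniformly over the
# separate matrices, and slices contributing no valid matrix are skipped.
#
# Degenerate conventions (stated once, used consistently): GLCM correlation
# of a zero-variance matrix is 1, MCC of a single-level matrix is 1, and
# NGTDM coarseness is capped at 1e6 when its denominator vanishes.

# The four in-plane symmetric directions (0, 45, 90, 135 degrees).
glcm_directions <- function() {
  rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
}

# Level matrices of slices that contain VOI voxels.
voi_slices <- function(disc) {
  d <- dim(disc$level_array)
  ks <- which(apply(!is.na(disc$level_array), 3, any))
  lapply(ks, function(k)
    matrix(disc$level_array[, , k], d[1], d[2]))
}

average_matrix_features <- function(rows, family) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    stop(sprintf("undefined features: no valid %s matrix in any slice", family))
  colMeans(do.call(rbind, rows))
}

# ---- GLCM ------------------------------------------------------------------

glcm_from_counts <- function(P) {
  s <- sum(P)
  if (s == 0) return(NULL)
  p <- P / s
  keep <- rowSums(p) > 0
  p <- p[keep, keep, drop = FALSE]
  iv <- which(keep)                      # gray-level values of kept rows
  Ng <- length(iv)
  px <- rowSums(p)
  py <- colSums(p)
  I <- matrix(iv, Ng, Ng)
  J <- t(I)
  mux <- sum(iv * px)
  muy <- sum(iv * py)
  sigx <- sqrt(sum((iv - mux)^2 * px))
  sigy <- sqrt(sum((iv - muy)^2 * py))
  # distributions of i+j and |i-j|
  sums <- tapply(as.vector(p), as.vector(I + J), sum)
  sum_k <- as.vector(sums)
  sum_v <- as.numeric(names(sums))
  difs <- tapply(as.vector(p), as.vector(abs(I - J)), sum)
  dif_k <- as.vector(difs)
  dif_v <- as.numeric(names(difs))
  da <- sum(dif_v * dif_k)
  pe <- p[p > 0]
  hxy <- -sum(pe * log2(pe))
  pp <- outer(px, py)
  hxy1 <- -sum(p[pp > 0 & p > 0] * log2(pp[pp > 0 & p > 0]))
  hxy2 <- -sum(pp[pp > 0] * log2(pp[pp > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  mcc <- if (Ng == 1) 1 else {
    Q <- (p / px) %*% t(sweep(p, 2, py, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(Autocorrelation = sum(p * I * J),
    JointAverage = mux,
    ClusterProminence = sum(p * (I + J - mux - muy)^4),
    ClusterShade = sum(p * (I + J - mux - muy)^3),
    ClusterTendency = sum(p * (I + J - mux - muy)^2),
    Contrast = sum(p * (I - J)^2),
    Correlation = if (sigx * sigy < 1e-12) 1 else
      (sum(p * I * J) - mux * muy) / (sigx * sigy),
    DifferenceAverage = da,
    DifferenceEntropy = -sum(dif_k[dif_k > 0] * log2(dif_k[dif_k > 0])),
    DifferenceVariance = sum(dif_k * (dif_v - da)^2),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = if (max(hx, hy) < 1e-12) 0 else (hxy - hxy1) / max(hx, hy),
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    Idm = sum(p / (1 + (I - J)^2)),
    Idmn = sum(p / (1 + (I - J)^2 / Ng^2)),
    Id = sum(p / (1 + abs(I - J))),
    Idn = sum(p / (1 + abs(I - J) / Ng)),
    InverseVariance = sum((p / pmax(1, (I - J)^2))[I != J]),
    MaximumProbability = max(p),
    SumAverage = sum(sum_v * sum_k),
    SumEntropy = -sum(sum_k[sum_k > 0] * log2(sum_k[sum_k > 0])),
    SumSquares = sum(p * (I - mux)^2),
    MCC = mcc)
}

#' Gray-level co-occurrence features (forced 2D)
#'
#' Builds the symmetric distance-1 GLCM of every axial slice in each of the
#' four in-plane directions over VOI voxels only, computes the 24 standard
#' co-occurrence features per matrix, and averages them uniformly over all
#' existing (slice, direction) matrices.
#'
#' @param disc a `discretized_voi` from [discretize_voi()].
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(disc) {
  dirs <- glcm_directions()
  rows <- list()
  for (m in voi_slices(disc))
    for (d in seq_len(nrow(dirs)))
      rows[[length(rows) + 1L]] <-
        glcm_from_counts(cpp_glcm_slice(m, dirs[d, 1], dirs[d, 2], disc$n_bins))
  average_matrix_features(rows, "GLCM")
}

# ---- GLRLM -----------------------------------------------------------------

glrlm_from_counts <- function(P) {
  Nr <- sum(P)
  if (Nr == 0) return(NULL)
  iv <- seq_len(nrow(P))
  lv <- seq_len(ncol(P))
  I <- matrix(iv, nrow(P), ncol(P))
  L <- matrix(lv, nrow(P), ncol(P), byrow = TRUE)
  Np <- sum(P * L)
  pr <- P / Nr
  mu_i <- sum(pr * I)
  mu_l <- sum(pr * L)
  pe <- pr[pr > 0]
  c(GrayLevelNonUniformity = sum(rowSums(P)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / Nr^2,
    GrayLevelVariance = sum(pr * (I - mu_i)^2),
    HighGrayLevelRunEmphasis = sum(P * I^2) / Nr,
    LongRunEmphasis = sum(P * L^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * I^2 * L^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * L^2 / I^2) / Nr,
    LowGrayLevelRunEmphasis = sum(P / I^2) / Nr,
    RunEntropy = -sum(pe * log2(pe)),
    RunLengthNonUniformity = sum(colSums(P)^2) / Nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / Nr^2,
    RunPercentage = Nr / Np,
    RunVariance = sum(pr * (L - mu_l)^2),
    ShortRunEmphasis = sum(P / L^2) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * I^2 / L^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (I^2 * L^2)) / Nr)
}

#' Gray-level run-length features (forced 2D)
#'
#' Distance-1 run-length matrices per axial slice and in-plane direction;
#' 16 features per matrix, averaged uniformly.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(disc) {
  dirs <- glcm_directions()
  rows <- list()
  for (m in voi_slices(disc))
    for (d in seq_len(nrow(dirs)))
      rows[[length(rows) + 1L]] <-
        glrlm_from_counts(cpp_glrlm_slice(m, dirs[d, 1], dirs[d, 2], disc$n_bins))
  average_matrix_features(rows, "GLRLM")
}

# ---- GLSZM -----------------------------------------------------------------

glszm_from_zones <- function(zones) {
  if (nrow(zones) == 0) return(NULL)
  iz <- zones[, 1]
  sz <- zones[, 2]
  Nz <- length(iz)
  Np <- sum(sz)
  lev_counts <- tapply(rep(1, Nz), iz, sum)
  size_counts <- tapply(rep(1, Nz), sz, sum)
  cell <- table(paste(iz, sz))
  pc <- as.numeric(cell) / Nz
  c(GrayLevelNonUniformity = sum(lev_counts^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(lev_counts^2) / Nz^2,
    GrayLevelVariance = mean((iz - mean(iz))^2),
    HighGrayLevelZoneEmphasis = mean(iz^2),
    LargeAreaEmphasis = mean(sz^2),
    LargeAreaHighGrayLevelEmphasis = mean(sz^2 * iz^2),
    LargeAreaLowGrayLevelEmphasis = mean(sz^2 / iz^2),
    LowGrayLevelZoneEmphasis = mean(1 / iz^2),
    SizeZoneNonUniformity = sum(size_counts^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(size_counts^2) / Nz^2,
    SmallAreaEmphasis = mean(1 / sz^2),
    SmallAreaHighGrayLevelEmphasis = mean(iz^2 / sz^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (iz^2 * sz^2)),
    ZoneEntropy = -sum(pc * log2(pc)),
    ZonePercentage = Nz / Np,
    ZoneVariance = mean((sz - mean(sz))^2))
}

#' Gray-level size-zone features (forced 2D)
#'
#' 8-connected equal-level zones per axial slice; 16 features per slice
#' matrix, averaged uniformly.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(disc) {
  rows <- lapply(voi_slices(disc), function(m)
    glszm_from_zones(cpp_glszm_slice(m)))
  average_matrix_features(rows, "GLSZM")
}

# ---- GLDM ------------------------------------------------------------------

gldm_from_counts <- function(P) {
  Nz <- sum(P)
  if (Nz == 0) return(NULL)
  iv <- seq_len(nrow(P))
  jv <- seq_len(ncol(P))                  # dependence = 1 + dependent neighbors
  I <- matrix(iv, nrow(P), ncol(P))
  J <- matrix(jv, nrow(P), ncol(P), byrow = TRUE)
  pd <- P / Nz
  mu_i <- sum(pd * I)
  mu_j <- sum(pd * J)
  pe <- pd[pd > 0]
  c(DependenceEntropy = -sum(pe * log2(pe)),
    DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    DependenceVariance = sum(pd * (J - mu_j)^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    GrayLevelVariance = sum(pd * (I - mu_i)^2),
    HighGrayLevelEmphasis = sum(P * I^2) / Nz,
    LargeDependenceEmphasis = sum(P * J^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * I^2 * J^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * J^2 / I^2) / Nz,
    LowGrayLevelEmphasis = sum(P / I^2) / Nz,
    SmallDependenceEmphasis = sum(P / J^2) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * I^2 / J^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (I^2 * J^2)) / Nz)
}

#' Gray-level dependence features (forced 2D)
#'
#' For each VOI voxel the dependence is 1 plus the number of its in-plane
#' 8-neighbors with an identical gray level (alpha = 0); 14 features per
#' slice matrix, averaged uniformly.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(disc) {
  rows <- lapply(voi_slices(disc), function(m)
    gldm_from_counts(cpp_gldm_slice(m, disc$n_bins, 0L)))
  average_matrix_features(rows, "GLDM")
}

# ---- NGTDM -----------------------------------------------------------------

ngtdm_from_counts <- function(M) {
  n_i <- M[, 1]
  s_i <- M[, 2]
  Nvp <- sum(n_i)
  if (Nvp == 0) return(NULL)
  p_i <- n_i / Nvp
  act <- which(p_i > 0)
  iv <- act
  Ngp <- length(act)
  pia <- p_i[act]
  sia <- s_i[act]
  ps <- sum(pia * sia)
  busy_den <- sum(abs(outer(iv * pia, iv * pia, "-")))
  pij_sum <- outer(pia, pia, "+")
  dij2 <- outer(iv, iv, "-")^2
  c(Busyness = if (busy_den < 1e-12) 0 else ps / busy_den,
    Coarseness = if (ps < 1e-12) 1e6 else 1 / ps,
    Complexity = sum(abs(outer(iv, iv, "-")) *
                       (outer(pia * sia, pia * sia, "+")) / pij_sum) / Nvp,
    Contrast = if (Ngp <= 1) 0 else
      sum(outer(pia, pia) * dij2) / (Ngp * (Ngp - 1)) * sum(sia) / Nvp,
    Strength = if (sum(sia) < 1e-12) 0 else sum(pij_sum * dij2) / sum(sia))
}

#' Neighboring gray-tone difference features (forced 2D)
#'
#' Per-slice NGTDM with the in-plane 8-neighborhood (voxels without any
#' valid neighbor are excluded); 5 features per slice matrix, averaged
#' uniformly.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(disc) {
  rows <- lapply(voi_slices(disc), function(m)
    ngtdm_from_counts(cpp_ngtdm_slice(m, disc$n_bins)))
  average_matrix_features(rows, "NGTDM")
}
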