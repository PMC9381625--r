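# Independent brute-force reference implementations used as oracles.
# Everything here is written as plain nested loops / exhaustive enumeration,
# deliberately sharing no code with the package internals.

# ---- geometry --------------------------------------------------------------

# Exhaustive sphere membership: loop over every voxel.
oracle_sphere_voxels <- function(dims, spacing, center0, diameter_mm) {
  r2 <- (diameter_mm / 2)^2
  out <- array(FALSE, dim = dims)
  for (i in 0:(dims[1] - 1))
    for (j in 0:(dims[2] - 1))
      for (k in 0:(dims[3] - 1)) {
        d2 <- ((i - center0[1]) * spacing[1])^2 +
          ((j - center0[2]) * spacing[2])^2 +
          ((k - center0[3]) * spacing[3])^2
        if (d2 <= r2) out[i + 1, j + 1, k + 1] <- TRUE
      }
  out
}

# Exhaustive cross-mean scoring of all candidates of the seed search.
oracle_seed_voxel <- function(adc_arr, spacing, click0, mask = NULL,
                              offsets = NULL) {
  if (is.null(offsets)) {
    offsets <- matrix(0L, 0, 3)
    for (di in -2:2) for (dj in -2:2) for (dk in -2:2) {
      n2 <- di^2 + dj^2 + dk^2
      if (n2 > 0 && n2 <= 5) offsets <- rbind(offsets, c(di, dj, dk))
    }
  }
  dims <- dim(adc_arr)
  inb <- function(v) all(v >= 0) && all(v <= dims - 1)
  inm <- function(v) is.null(mask) || mask[v[1] + 1, v[2] + 1, v[3] + 1]
  cand <- rbind(c(0L, 0L, 0L), offsets)
  best <- NULL
  for (r in seq_len(nrow(cand))) {
    v <- click0 + cand[r, ]
    if (!inb(v) || !inm(v)) next
    tot <- 0; cnt <- 0
    for (f in list(c(0,0,0), c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
      w <- v + f
      if (!inb(w) || !inm(w)) next
      tot <- tot + adc_arr[w[1] + 1, w[2] + 1, w[3] + 1]
      cnt <- cnt + 1
    }
    score <- tot / cnt
    d2 <- sum(((v - click0) * spacing)^2)
    key <- c(score, d2, v[3], v[2], v[1])
    if (is.null(best) ||
        isTRUE(order_lex(key, best$key) < 0)) best <- list(v = v, key = key)
  }
  best$v
}

order_lex <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(-1)
    if (a[i] > b[i] + 1e-12) return(1)
  }
  0
}

# ---- ROC / AP --------------------------------------------------------------

# AUC by exhaustive concordant-pair counting (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  tot <- 0
  for (p in pos)
    for (q in neg) {
      if (scores[p] > scores[q]) tot <- tot + 1
      else if (scores[p] == scores[q]) tot <- tot + 0.5
    }
  tot / (length(pos) * length(neg))
}

# ---- information theory ----------------------------------------------------

oracle_entropy <- function(v) {
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log2(p))
}

oracle_mi <- function(a, b) {
  oracle_entropy(a) + oracle_entropy(b) -
    oracle_entropy(paste(a, b, sep = "|"))
}

oracle_joint_mi <- function(f, s, y) {
  oracle_mi(paste(f, s, sep = "|"), y)
}

# Criterion value of candidate f given the already-selected set.
oracle_jmim_score <- function(D, y, f, selected) {
  if (length(selected) == 0) return(oracle_mi(D[, f], y))
  min(vapply(selected, function(s) oracle_joint_mi(D[, f], D[, s], y), 0))
}

# Checks a selection path is greedy-optimal: at every step the chosen
# feature's criterion must reach the best over all remaining candidates
# (within floating-point tolerance, so exact ties may resolve either way).
oracle_jmim_path_optimal <- function(D, y, path, tol = 1e-9) {
  selected <- integer(0)
  for (pick in path) {
    scores <- vapply(setdiff(seq_len(ncol(D)), selected), function(f)
      oracle_jmim_score(D, y, f, selected), 0)
    if (oracle_jmim_score(D, y, pick, selected) < max(scores) - tol)
      return(FALSE)
    selected <- c(selected, pick)
  }
  TRUE
}

# Greedy JMIM path, re-evaluating every candidate at every step.
oracle_jmim_path <- function(D, y, k) {
  selected <- integer(0)
  for (step in seq_len(k)) {
    best <- NULL
    for (f in seq_len(ncol(D))) {
      if (f %in% selected) next
      score <- if (length(selected) == 0) oracle_mi(D[, f], y) else
        min(vapply(selected, function(s)
          oracle_joint_mi(D[, f], D[, s], y), 0))
      if (is.null(best) || score > best$score + 1e-12)
        best <- list(f = f, score = score)
    }
    selected <- c(selected, best$f)
  }
  selected
}

# ---- radiomics features ----------------------------------------------------

oracle_znorm <- function(a, scale = 100) {
  (a - mean(a)) / sqrt(mean((a - mean(a))^2)) * scale
}

oracle_first_order <- function(x, lev, vv) {
  n <- length(x)
  p <- as.numeric(table(lev)) / n
  q <- stats::quantile(x, c(.1, .25, .5, .75, .9), names = FALSE, type = 7)
  mu <- sum(x) / n
  cm <- function(k) sum((x - mu)^k) / n
  sub <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2), TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)), Minimum = min(x),
    Percentile10 = q[1], Percentile90 = q[5], Maximum = max(x),
    Mean = mu, Median = q[3], InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x), MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(sub - mean(sub))) / length(sub),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (cm(2) > 1e-24) cm(3) / cm(2)^1.5 else 0,
    Kurtosis = if (cm(2) > 1e-24) cm(4) / cm(2)^2 else 0,
    Variance = cm(2), Uniformity = sum(p^2))
}

o_valid <- function(sl, i, j) {
  i >= 1 && j >= 1 && i <= nrow(sl) && j <= ncol(sl) && !is.na(sl[i, j])
}

oracle_glcm_mat <- function(sl, di, dj, ng) {
  P <- matrix(0, ng, ng)
  for (i in seq_len(nrow(sl)))
    for (j in seq_len(ncol(sl))) {
      if (!o_valid(sl, i, j) || !o_valid(sl, i + di, j + dj)) next
      a <- sl[i, j]; b <- sl[i + di, j + dj]
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  P
}

oracle_glcm_feats <- function(P) {
  if (sum(P) == 0) return(NULL)
  keep <- which(rowSums(P) > 0)
  p <- P[keep, keep, drop = FALSE] / sum(P)
  iv <- keep
  ng <- length(iv)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sigx <- sqrt(sum((iv - mux)^2 * px)); sigy <- sqrt(sum((iv - muy)^2 * py))
  out <- c(Autocorrelation = 0, JointAverage = mux, ClusterProminence = 0,
           ClusterShade = 0, ClusterTendency = 0, Contrast = 0,
           Correlation = 0, DifferenceAverage = 0, DifferenceEntropy = 0,
           DifferenceVariance = 0, JointEnergy = 0, JointEntropy = 0,
           Imc1 = 0, Imc2 = 0, Idm = 0, Idmn = 0, Id = 0, Idn = 0,
           InverseVariance = 0, MaximumProbability = max(p), SumAverage = 0,
           SumEntropy = 0, SumSquares = 0, MCC = 0)
  pxy_sum <- list(); pxy_dif <- list()
  hxy <- 0; hxy1 <- 0; hxy2 <- 0
  for (a in 1:ng) for (b in 1:ng) {
    v <- p[a, b]; i <- iv[a]; j <- iv[b]
    out["Autocorrelation"] <- out["Autocorrelation"] + v * i * j
    out["ClusterProminence"] <- out["ClusterProminence"] + v * (i + j - mux - muy)^4
    out["ClusterShade"] <- out["ClusterShade"] + v * (i + j - mux - muy)^3
    out["ClusterTendency"] <- out["ClusterTendency"] + v * (i + j - mux - muy)^2
    out["Contrast"] <- out["Contrast"] + v * (i - j)^2
    out["JointEnergy"] <- out["JointEnergy"] + v^2
    out["Idm"] <- out["Idm"] + v / (1 + (i - j)^2)
    out["Idmn"] <- out["Idmn"] + v / (1 + (i - j)^2 / ng^2)
    out["Id"] <- out["Id"] + v / (1 + abs(i - j))
    out["Idn"] <- out["Idn"] + v / (1 + abs(i - j) / ng)
    if (i != j) out["InverseVariance"] <- out["InverseVariance"] + v / (i - j)^2
    out["SumSquares"] <- out["SumSquares"] + v * (i - mux)^2
    ks <- as.character(i + j); kd <- as.character(abs(i - j))
    pxy_sum[[ks]] <- (if (is.null(pxy_sum[[ks]])) 0 else pxy_sum[[ks]]) + v
    pxy_dif[[kd]] <- (if (is.null(pxy_dif[[kd]])) 0 else pxy_dif[[kd]]) + v
    if (v > 0) {
      hxy <- hxy - v * log2(v)
      if (px[a] * py[b] > 0) hxy1 <- hxy1 - v * log2(px[a] * py[b])
    }
    if (px[a] * py[b] > 0)
      hxy2 <- hxy2 - px[a] * py[b] * log2(px[a] * py[b])
  }
  out["JointEntropy"] <- hxy
  da <- 0
  for (kd in names(pxy_dif)) da <- da + as.numeric(kd) * pxy_dif[[kd]]
  out["DifferenceAverage"] <- da
  for (kd in names(pxy_dif)) {
    v <- pxy_dif[[kd]]
    if (v > 0) out["DifferenceEntropy"] <- out["DifferenceEntropy"] - v * log2(v)
    out["DifferenceVariance"] <- out["DifferenceVariance"] +
      v * (as.numeric(kd) - da)^2
  }
  for (ks in names(pxy_sum)) {
    v <- pxy_sum[[ks]]
    out["SumAverage"] <- out["SumAverage"] + as.numeric(ks) * v
    if (v > 0) out["SumEntropy"] <- out["SumEntropy"] - v * log2(v)
  }
  out["Correlation"] <- if (sigx * sigy < 1e-12) 1 else
    (out[["Autocorrelation"]] - mux * muy) / (sigx * sigy)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  out["Imc1"] <- if (max(hx, hy) < 1e-12) 0 else (hxy - hxy1) / max(hx, hy)
  out["Imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  out["MCC"] <- if (ng == 1) 1 else {
    Q <- matrix(0, ng, ng)
    for (a in 1:ng) for (b in 1:ng) for (kk in 1:ng)
      Q[a, b] <- Q[a, b] + p[a, kk] * p[b, kk] / (px[a] * py[kk])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  out
}

oracle_glrlm_mat <- function(sl, di, dj, ng) {
  maxlen <- max(nrow(sl), ncol(sl))
  P <- matrix(0, ng, maxlen)
  for (i in seq_len(nrow(sl)))
    for (j in seq_len(ncol(sl))) {
      if (!o_valid(sl, i, j)) next
      lev <- sl[i, j]
      if (o_valid(sl, i - di, j - dj) && sl[i - di, j - dj] == lev) next
      len <- 1; ci <- i + di; cj <- j + dj
      while (o_valid(sl, ci, cj) && sl[ci, cj] == lev) {
        len <- len + 1; ci <- ci + di; cj <- cj + dj
      }
      P[lev, len] <- P[lev, len] + 1
    }
  P
}

oracle_glrlm_feats <- function(P) {
  Nr <- sum(P)
  if (Nr == 0) return(NULL)
  out <- numeric(0)
  Np <- 0; mu_i <- 0; mu_l <- 0
  for (i in seq_len(nrow(P))) for (l in seq_len(ncol(P))) {
    Np <- Np + P[i, l] * l
    mu_i <- mu_i + P[i, l] / Nr * i
    mu_l <- mu_l + P[i, l] / Nr * l
  }
  acc <- function(f) {
    s <- 0
    for (i in seq_len(nrow(P))) for (l in seq_len(ncol(P)))
      s <- s + f(P[i, l], i, l)
    s
  }
  pe <- P[P > 0] / Nr
  c(GrayLevelNonUniformity = sum(rowSums(P)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / Nr^2,
    GrayLevelVariance = acc(function(v, i, l) v / Nr * (i - mu_i)^2),
    HighGrayLevelRunEmphasis = acc(function(v, i, l) v * i^2) / Nr,
    LongRunEmphasis = acc(function(v, i, l) v * l^2) / Nr,
    LongRunHighGrayLevelEmphasis = acc(function(v, i, l) v * i^2 * l^2) / Nr,
    LongRunLowGrayLevelEmphasis = acc(function(v, i, l) v * l^2 / i^2) / Nr,
    LowGrayLevelRunEmphasis = acc(function(v, i, l) v / i^2) / Nr,
    RunEntropy = -sum(pe * log2(pe)),
    RunLengthNonUniformity = sum(colSums(P)^2) / Nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / Nr^2,
    RunPercentage = Nr / Np,
    RunVariance = acc(function(v, i, l) v / Nr * (l - mu_l)^2),
    ShortRunEmphasis = acc(function(v, i, l) v / l^2) / Nr,
    ShortRunHighGrayLevelEmphasis = acc(function(v, i, l) v * i^2 / l^2) / Nr,
    ShortRunLowGrayLevelEmphasis = acc(function(v, i, l) v / (i^2 * l^2)) / Nr)
}

# Naive 8-connected zone search by repeated region growth.
oracle_glszm_zones <- function(sl) {
  seen <- matrix(FALSE, nrow(sl), ncol(sl))
  zones <- NULL
  for (i in seq_len(nrow(sl)))
    for (j in seq_len(ncol(sl))) {
      if (!o_valid(sl, i, j) || seen[i, j]) next
      lev <- sl[i, j]
      members <- matrix(c(i, j), 1)
      seen[i, j] <- TRUE
      grew <- TRUE
      while (grew) {
        grew <- FALSE
        for (m in seq_len(nrow(members)))
          for (di in -1:1) for (dj in -1:1) {
            ci <- members[m, 1] + di; cj <- members[m, 2] + dj
            if ((di == 0 && dj == 0) || !o_valid(sl, ci, cj)) next
            if (sl[ci, cj] == lev && !seen[ci, cj]) {
              members <- rbind(members, c(ci, cj))
              seen[ci, cj] <- TRUE
              grew <- TRUE
            }
          }
      }
      zones <- rbind(zones, c(lev, nrow(members)))
    }
  zones
}

oracle_glszm_feats <- function(zones) {
  if (is.null(zones) || nrow(zones) == 0) return(NULL)
  iz <- zones[, 1]; sz <- zones[, 2]
  Nz <- nrow(zones); Np <- sum(sz)
  pc <- as.numeric(table(paste(iz, sz))) / Nz
  c(GrayLevelNonUniformity = sum(as.numeric(table(iz))^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(as.numeric(table(iz))^2) / Nz^2,
    GrayLevelVariance = sum((iz - mean(iz))^2) / Nz,
    HighGrayLevelZoneEmphasis = sum(iz^2) / Nz,
    LargeAreaEmphasis = sum(sz^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(sz^2 * iz^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(sz^2 / iz^2) / Nz,
    LowGrayLevelZoneEmphasis = sum(1 / iz^2) / Nz,
    SizeZoneNonUniformity = sum(as.numeric(table(sz))^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(as.numeric(table(sz))^2) / Nz^2,
    SmallAreaEmphasis = sum(1 / sz^2) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(iz^2 / sz^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (iz^2 * sz^2)) / Nz,
    ZoneEntropy = -sum(pc * log2(pc)),
    ZonePercentage = Nz / Np,
    ZoneVariance = sum((sz - mean(sz))^2) / Nz)
}

oracle_gldm_mat <- function(sl, ng) {
  P <- matrix(0, ng, 9)
  for (i in seq_len(nrow(sl)))
    for (j in seq_len(ncol(sl))) {
      if (!o_valid(sl, i, j)) next
      dep <- 1
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        if (o_valid(sl, i + di, j + dj) && sl[i + di, j + dj] == sl[i, j])
          dep <- dep + 1
      }
      P[sl[i, j], dep] <- P[sl[i, j], dep] + 1
    }
  P
}

oracle_gldm_feats <- function(P) {
  Nz <- sum(P)
  if (Nz == 0) return(NULL)
  acc <- function(f) {
    s <- 0
    for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
      s <- s + f(P[i, j], i, j)
    s
  }
  mu_i <- acc(function(v, i, j) v / Nz * i)
  mu_j <- acc(function(v, i, j) v / Nz * j)
  pe <- P[P > 0] / Nz
  c(DependenceEntropy = -sum(pe * log2(pe)),
    DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    DependenceVariance = acc(function(v, i, j) v / Nz * (j - mu_j)^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    GrayLevelVariance = acc(function(v, i, j) v / Nz * (i - mu_i)^2),
    HighGrayLevelEmphasis = acc(function(v, i, j) v * i^2) / Nz,
    LargeDependenceEmphasis = acc(function(v, i, j) v * j^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = acc(function(v, i, j) v * i^2 * j^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = acc(function(v, i, j) v * j^2 / i^2) / Nz,
    LowGrayLevelEmphasis = acc(function(v, i, j) v / i^2) / Nz,
    SmallDependenceEmphasis = acc(function(v, i, j) v / j^2) / Nz,
    SmallDependenceHighGrayLevelEmphasis = acc(function(v, i, j) v * i^2 / j^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = acc(function(v, i, j) v / (i^2 * j^2)) / Nz)
}

oracle_ngtdm_feats <- function(sl, ng) {
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (i in seq_len(nrow(sl)))
    for (j in seq_len(ncol(sl))) {
      if (!o_valid(sl, i, j)) next
      nb <- c()
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        if (o_valid(sl, i + di, j + dj)) nb <- c(nb, sl[i + di, j + dj])
      }
      if (length(nb) == 0) next
      lev <- sl[i, j]
      n_i[lev] <- n_i[lev] + 1
      s_i[lev] <- s_i[lev] + abs(lev - mean(nb))
    }
  Nvp <- sum(n_i)
  if (Nvp == 0) return(NULL)
  p_i <- n_i / Nvp
  act <- which(p_i > 0)
  ps <- sum(p_i[act] * s_i[act])
  busy <- 0; comp <- 0; contr <- 0; stre <- 0
  for (a in act) for (b in act) {
    busy <- busy + abs(a * p_i[a] - b * p_i[b])
    comp <- comp + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
      (p_i[a] + p_i[b])
    contr <- contr + p_i[a] * p_i[b] * (a - b)^2
    stre <- stre + (p_i[a] + p_i[b]) * (a - b)^2
  }
  ngp <- length(act)
  c(Busyness = if (busy < 1e-12) 0 else ps / busy,
    Coarseness = if (ps < 1e-12) 1e6 else 1 / ps,
    Complexity = comp / Nvp,
    Contrast = if (ngp <= 1) 0 else
      contr / (ngp * (ngp - 1)) * sum(s_i[act]) / Nvp,
    Strength = if (sum(s_i[act]) < 1e-12) 0 else stre / sum(s_i[act]))
}

# Full 93-feature reference extraction for one sequence volume + VOI mask.
oracle_voi_features <- function(vals, mask, spacing, W = 30, scale = 100) {
  z <- oracle_znorm(vals, scale)
  x <- z[mask]
  lev <- floor((x - min(x)) / W) + 1
  ng <- floor((max(x) - min(x)) / W) + 1
  arr <- array(NA_integer_, dim = dim(vals))
  arr[mask] <- as.integer(lev)
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  avg <- function(rows) {
    rows <- rows[!vapply(rows, is.null, logical(1))]
    colMeans(do.call(rbind, rows))
  }
  glcm <- list(); glrlm <- list(); glszm <- list(); gldm <- list(); ngtdm <- list()
  for (k in seq_len(dim(vals)[3])) {
    sl <- arr[, , k]
    if (all(is.na(sl))) next
    for (d in dirs) {
      glcm[[length(glcm) + 1]] <- oracle_glcm_feats(oracle_glcm_mat(sl, d[1], d[2], ng))
      glrlm[[length(glrlm) + 1]] <- oracle_glrlm_feats(oracle_glrlm_mat(sl, d[1], d[2], ng))
    }
    glszm[[length(glszm) + 1]] <- oracle_glszm_feats(oracle_glszm_zones(sl))
    gldm[[length(gldm) + 1]] <- oracle_gldm_feats(oracle_gldm_mat(sl, ng))
    ngtdm[[length(ngtdm) + 1]] <- oracle_ngtdm_feats(sl, ng)
  }
  fo <- oracle_first_order(x, lev, prod(spacing))
  c(stats::setNames(fo, paste0("firstorder_", names(fo))),
    stats::setNames(avg(glcm), paste0("glcm_", names(avg(glcm)))),
    stats::setNames(avg(glrlm), paste0("glrlm_", names(avg(glrlm)))),
    stats::setNames(avg(glszm), paste0("glszm_", names(avg(glszm)))),
    stats::setNames(avg(gldm), paste0("gldm_", names(avg(gldm)))),
    stats::setNames(avg(ngtdm), paste0("ngtdm_", names(avg(ngtdm)))))
}
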