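#' Radiomics extraction parameters
#'
#' Settings of the feature extractor: whole-image z-normalization with a
#' scale factor, fixed-bin-width discretization inside the VOI, and
#' forced-2D texture computation at neighbor distance 1 (in-plane
#' connectivity of eight). The defaults (bin width 30 after normalization
#' to sd 100) give discretized images in the tens-to-low-hundreds of gray
#' bins.
#'
#' @param bin_width fixed discretization bin width `W` (> 0).
#' @param normalize apply whole-image z-normalization before extraction.
#' @param scale post-normalization standard deviation.
#' @param distance texture distance-to-neighbor; must be 1.
#' @param sequences sequence names to extract, in output column order.
#' @return An `extraction_params` list.
#' @export
extraction_params <- function(bin_width = 30, normalize = TRUE, scale = 100,
                              distance = 1L, sequences = c("T2", "ADC", "DWI")) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (distance != 1L) stop("distance-to-neighbor is fixed at 1")
  structure(list(bin_width = bin_width, normalize = normalize, scale = scale,
                 distance = 1L, sequences = sequences),
            class = "extraction_params")
}

#' Whole-image z-normalization
#'
#' Centers the volume to mean 0 and unit (population) standard deviation,
#' then multiplies by `scale`.
#'
#' @param vol an [image_volume].
#' @param scale multiplier applied after standardization (default 100).
#' @return The normalized [image_volume].
#' @export
znormalize <- function(vol, scale = 100) {
  stopifnot(inherits(vol, "image_volume"))
  x <- vol$values
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev < 1e-12)
    stop("degenerate input: constant image cannot be z-normalized")
  vol$values <- (x - mu) / sdev * scale
  vol
}

#' Fixed-bin-width discretization inside a VOI
#'
#' Gray level of a VOI voxel with intensity `x` is
#' `floor((x - min_VOI) / W) + 1`; the number of bins is
#' `floor((max_VOI - min_VOI) / W) + 1`.
#'
#' @param vol an [image_volume].
#' @param voi a `voi_mask` on the same grid.
#' @param W bin width.
#' @return A `discretized_voi`: raw VOI `values`, integer `levels`, `n_bins`,
#'   a 3D `level_array` with `NA` outside the VOI, and the voxel spacing.
#' @export
discretize_voi <- function(vol, voi, W = 30) {
  stopifnot(inherits(vol, "image_volume"), inherits(voi, "voi_mask"))
  sel <- which(voi$mask)
  if (length(sel) == 0) stop("empty VOI")
  vals <- vol$values[sel]
  lev <- as.integer(floor((vals - min(vals)) / W)) + 1L
  arr <- array(NA_integer_, dim = dim(vol$values))
  arr[sel] <- lev
  structure(list(values = vals, levels = lev,
                 n_bins = as.integer(floor((max(vals) - min(vals)) / W)) + 1L,
                 level_array = arr, spacing = vol$spacing),
            class = "discretized_voi")
}

#' First-order (intensity-distribution) features
#'
#' The 18 standard first-order features, computed over the full 3D VOI
#' voxel set: energy, total energy, histogram entropy, minimum, 10th/90th
#' percentiles, maximum, mean, median, interquartile range, range, mean
#' absolute deviation, robust MAD (on the 10-90 percentile subset), root
#' mean squared, skewness, kurtosis (non-excess), variance (population),
#' and uniformity. Entropy and uniformity use the discretized histogram.
#' Skewness and kurtosis of a constant input are defined as 0.
#'
#' @param values numeric intensities of the VOI voxels.
#' @param levels integer discretized levels of the same voxels.
#' @param voxel_volume voxel volume in mm^3 (for total energy).
#' @return Named numeric vector of length 18.
#' @export
first_order_features <- function(values, levels, voxel_volume = 1) {
  n <- length(values)
  stopifnot(n >= 1, length(levels) == n)
  p <- tabulate(levels)
  p <- p[p > 0] / n
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  sub <- values[values >= q[1] & values <= q[5]]
  c(Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(values),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 1e-24) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 1e-24) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

# All 93 features of one sequence volume over one VOI, names prefixed by
# feature group.
voi_features <- function(vol, voi, params) {
  v <- if (params$normalize) znormalize(vol, params$scale) else vol
  disc <- discretize_voi(v, voi, params$bin_width)
  fams <- list(
    firstorder = first_order_features(disc$values, disc$levels, prod(v$spacing)),
    glcm = glcm_features(disc),
    glrlm = glrlm_features(disc),
    glszm = glszm_features(disc),
    gldm = gldm_features(disc),
    ngtdm = ngtdm_features(disc))
  do.call(c, lapply(names(fams), function(g)
    stats::setNames(fams[[g]], paste(g, names(fams[[g]]), sep = "_"))))
}

#' Extract the full radiomics feature vector for one lesion
#'
#' Per sequence: whole-image z-normalization, fixed-bin-width
#' discretization inside the VOI, 18 first-order features on the 3D voxel
#' set, and the five texture families in forced 2D (per-slice matrices,
#' distance 1, features averaged uniformly over the separate matrices).
#' With the default three sequences the vector has 279 entries named
#' `sequence_group_feature`.
#'
#' @param case a `synthetic_case` (or any list with `volumes`).
#' @param voi a `voi_mask` valid on all sequence grids.
#' @param params an [extraction_params()].
#' @return Named numeric feature vector (93 per sequence).
#' @export
extract_case <- function(case, voi, params = extraction_params()) {
  out <- lapply(params$sequences, function(sq) {
    vol <- case$volumes[[sq]]
    if (is.null(vol)) stop(sprintf("sequence %s missing", sq))
    f <- voi_features(vol, voi, params)
    stats::setNames(f, paste(sq, names(f), sep = "_"))
  })
  do.call(c, out)
}

#' Extract the lesion-by-feature table of a cohort
#'
#' Builds the DLM auto-fixed VOI of every lesion from its manifest click at
#' one sphere diameter and extracts the full feature vector.
#'
#' @param cohort a `synthetic_cohort` (or list with `cases` + `manifest`).
#' @param diameter_mm initial sphere diameter in mm.
#' @param params an [extraction_params()].
#' @return A data frame: `case_id`, `lesion_id`, `center_id`, `label`
#'   (1 = clinically significant), then one column per feature.
#' @export
extract_cohort <- function(cohort, diameter_mm, params = extraction_params()) {
  man <- cohort$manifest
  case_idx <- match(man$case_id, vapply(cohort$cases, `[[`, "", "case_id"))
  rows <- lapply(seq_len(nrow(man)), function(r) {
    case <- cohort$cases[[case_idx[r]]]
    click <- c(man$click_i[r], man$click_j[r], man$click_k[r])
    voi <- build_dlm_voi(case, click, diameter_mm)
    extract_case(case, voi, params)
  })
  feats <- do.call(rbind, rows)
  out <- data.frame(case_id = man$case_id, lesion_id = man$lesion_id,
                    center_id = man$center_id,
                    label = as.integer(man$is_cs),
                    feats, check.names = FALSE)
  rownames(out) <- NULL
  out
}

# Names of the non-feature metadata columns of a feature table.
feature_table_meta <- c("case_id", "lesion_id", "center_id", "label")

# Feature-column names of a feature table.
feature_columns <- function(table) {
  setdiff(colnames(table), feature_table_meta)
}
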