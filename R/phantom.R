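#' Configuration of the synthetic bpMRI phantom
#'
#' Parameters of the seeded multi-center phantom generator. The defaults
#' define the study conditions every downstream stage is exercised under:
#' a 96x96x20 grid at 0.5x0.5x3 mm (fine in-plane, thick slices), an
#' ellipsoidal gland of half-axes 25x20x15 mm with per-case jitter, ADC
#' levels ordered clinically (CS core < non-CS core < gland), lesion-wise
#' multiplicative texture fields that are rougher for CS lesions, and
#' per-center intensity scale and noise.
#'
#' @param n_cases number of cases (patients).
#' @param lesions_min,lesions_max per-case lesion count is uniform on
#'   `lesions_min:lesions_max`.
#' @param cs_fraction probability that a lesion is clinically significant
#'   (ISUP grade >= 2 analogue).
#' @param n_centers number of simulated centers.
#' @param grid_shape voxel grid `(nx, ny, nz)`.
#' @param spacing voxel spacing in mm.
#' @param gland_axes_mm gland ellipsoid half-axes in mm.
#' @param gland_jitter_frac relative per-case jitter of the half-axes.
#' @param adc_levels named vector: `background`, `gland`, `noncs_core`,
#'   `cs_core` mean ADC-like levels (arbitrary units); must satisfy
#'   `cs_core < noncs_core < gland`.
#' @param texture_heterogeneity list with `cs` and `noncs` entries, each
#'   `c(amplitude, corr_mm)`: relative amplitude and correlation length of
#'   the lesion texture field.
#' @param center_scale_range per-center multiplicative intensity scale is
#'   uniform on this range.
#' @param center_noise_sd_range per-center Gaussian noise sd (ADC units) is
#'   uniform on this range.
#' @param edge_lesion_fraction probability a lesion center is placed within
#'   5 mm of the gland boundary (so a naive 18-mm sphere leaks outside).
#' @param lesion_radius_range_mm lesion radius is uniform on this range.
#' @param click_jitter_voxels Chebyshev radius of simulated click jitter.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   config.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_cases = 120,
                           lesions_min = 1, lesions_max = 2,
                           cs_fraction = 0.4,
                           n_centers = 9,
                           grid_shape = c(96L, 96L, 20L),
                           spacing = c(0.5, 0.5, 3),
                           gland_axes_mm = c(20, 17, 13),
                           gland_jitter_frac = 0.12,
                           adc_levels = c(background = 400, gland = 1400,
                                          noncs_core = 950, cs_core = 600),
                           texture_heterogeneity = list(
                             cs = c(amplitude = 0.35, corr_mm = 2),
                             noncs = c(amplitude = 0.12, corr_mm = 5)),
                           center_scale_range = c(0.8, 1.25),
                           center_noise_sd_range = c(15, 60),
                           edge_lesion_fraction = 0.35,
                           lesion_radius_range_mm = c(4, 8),
                           click_jitter_voxels = 1,
                           seed = 7) {
  cfg <- list(n_cases = as.integer(n_cases),
              lesions_min = as.integer(lesions_min),
              lesions_max = as.integer(lesions_max),
              cs_fraction = cs_fraction,
              n_centers = as.integer(n_centers),
              grid_shape = as.integer(grid_shape),
              spacing = as.numeric(spacing),
              gland_axes_mm = as.numeric(gland_axes_mm),
              gland_jitter_frac = gland_jitter_frac,
              adc_levels = adc_levels,
              texture_heterogeneity = texture_heterogeneity,
              center_scale_range = as.numeric(center_scale_range),
              center_noise_sd_range = as.numeric(center_noise_sd_range),
              edge_lesion_fraction = edge_lesion_fraction,
              lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
              click_jitter_voxels = as.integer(click_jitter_voxels),
              seed = as.integer(seed))
  if (cfg$cs_fraction < 0 || cfg$cs_fraction > 1)
    stop("cs_fraction must be in [0, 1]")
  if (any(cfg$spacing <= 0)) stop("spacing must be positive")
  lv <- cfg$adc_levels
  if (!(lv[["cs_core"]] < lv[["noncs_core"]] && lv[["noncs_core"]] < lv[["gland"]]))
    stop("adc_levels must satisfy cs_core < noncs_core < gland")
  half_extent <- (cfg$grid_shape - 1) * cfg$spacing / 2
  if (any(cfg$gland_axes_mm * (1 + cfg$gland_jitter_frac) >= half_extent))
    stop("configuration error: grid too small to contain the gland")
  structure(cfg, class = "phantom_config")
}

# Base intensity levels for the non-ADC sequences: (background, gland,
# non-CS core, CS core). T2 shows lesions mildly dark, high-b DWI shows
# them bright; class contrast lives mainly in ADC and texture.
phantom_seq_levels <- function(adc_levels) {
  list(T2 = c(150, 480, 380, 340),
       ADC = c(adc_levels[["background"]], adc_levels[["gland"]],
               adc_levels[["noncs_core"]], adc_levels[["cs_core"]]),
       DWI = c(60, 140, 260, 380))
}

# Smoothed standard Gaussian random field on a small grid: white noise
# blurred with a separable Gaussian of physical sd `corr_mm`, rescaled to
# unit variance.
gaussian_field <- function(dims, spacing, corr_mm) {
  g <- array(stats::rnorm(prod(dims)), dim = dims)
  for (ax in 1:3) {
    sig <- corr_mm / spacing[ax]
    if (sig < 1e-6) next
    n <- dims[ax]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * sig^2))
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    gp <- aperm(g, perm)
    gp <- array(K %*% matrix(gp, nrow = n), dim = dims[perm])
    g <- aperm(gp, order(perm))
  }
  s <- stats::sd(g)
  if (s < 1e-12) g else (g - mean(g)) / s
}

# Sample one lesion center (0-based voxel) honoring the edge/interior rule.
sample_lesion_center <- function(axes, center_phys, spacing, dims, gland,
                                 edge) {
  for (try in 1:200) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    r_u <- 1 / sqrt(sum((u / axes)^2))  # gland radius along u, mm
    if (edge) {
      b <- stats::runif(1, 0.5, 5)
      if (b >= r_u) next
      p <- center_phys + u * (r_u - b)
    } else {
      t_max <- 1 - 6 / r_u
      if (t_max <= 0.05) next
      t <- t_max * stats::runif(1)^(1 / 3)
      p <- center_phys + u * t * r_u
    }
    v0 <- as.integer(round(p / spacing))
    if (any(v0 < 0L) || any(v0 > dims - 1L)) next
    if (gland[v0[1] + 1L, v0[2] + 1L, v0[3] + 1L]) return(v0)
  }
  as.integer(round(center_phys / spacing))
}

#' Generate a synthetic multi-center bpMRI cohort
#'
#' Deterministically (given `config$seed`) simulates cases with T2/ADC/DWI
#' volumes, a gland-shaped prostate mask, lesions with depressed-ADC cores
#' whose contrast and texture heterogeneity differ by class, per-center
#' intensity scale and noise, and simulated clicks.
#'
#' @param config a [phantom_config()].
#' @return A `synthetic_cohort`: list with `cases` (each a `synthetic_case`
#'   holding `volumes`, `prostate_mask`, `lesions`), a per-lesion `manifest`
#'   data frame (case/lesion ids, center, click voxel, label, radius), and
#'   the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    dims <- config$grid_shape
    sp <- config$spacing
    center_phys <- (dims - 1) * sp / 2
    seq_levels <- phantom_seq_levels(config$adc_levels)
    adc_gland <- config$adc_levels[["gland"]]

    center_scale <- stats::runif(config$n_centers, config$center_scale_range[1],
                                 config$center_scale_range[2])
    center_noise <- stats::runif(config$n_centers, config$center_noise_sd_range[1],
                                 config$center_noise_sd_range[2])
    case_center <- sample.int(config$n_centers, config$n_cases, replace = TRUE)

    cases <- vector("list", config$n_cases)
    man <- list()
    for (ci in seq_len(config$n_cases)) {
      axes <- config$gland_axes_mm *
        stats::runif(3, 1 - config$gland_jitter_frac, 1 + config$gland_jitter_frac)
      # gland ellipsoid mask
      xs <- ((seq_len(dims[1]) - 1) * sp[1] - center_phys[1]) / axes[1]
      ys <- ((seq_len(dims[2]) - 1) * sp[2] - center_phys[2]) / axes[2]
      zs <- ((seq_len(dims[3]) - 1) * sp[3] - center_phys[3]) / axes[3]
      gland <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= 1

      n_les <- sample(config$lesions_min:config$lesions_max, 1)
      lesions <- list()
      vols <- lapply(seq_levels, function(lv) {
        a <- array(lv[1], dim = dims)
        a[gland] <- lv[2]
        a
      })
      placed <- matrix(numeric(0), ncol = 4)  # physical center + radius
      for (li in seq_len(n_les)) {
        is_cs <- stats::runif(1) < config$cs_fraction
        radius <- stats::runif(1, config$lesion_radius_range_mm[1],
                               config$lesion_radius_range_mm[2])
        edge <- stats::runif(1) < config$edge_lesion_fraction
        v0 <- NULL
        for (att in 1:30) {
          v0 <- sample_lesion_center(axes, center_phys, sp, dims, gland, edge)
          p <- v0 * sp
          if (nrow(placed) == 0) break
          if (all(sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - p)^2)) >=
                  placed[, 4] + radius)) break
        }
        p <- v0 * sp
        placed <- rbind(placed, c(p, radius))

        # bounding box of the lesion sphere
        lo <- pmax(0L, as.integer(floor((p - radius) / sp)))
        hi <- pmin(dims - 1L, as.integer(ceiling((p + radius) / sp)))
        bi <- (lo[1]:hi[1]) + 1L; bj <- (lo[2]:hi[2]) + 1L; bk <- (lo[3]:hi[3]) + 1L
        dx2 <- (((bi - 1) * sp[1]) - p[1])^2
        dy2 <- (((bj - 1) * sp[2]) - p[2])^2
        dz2 <- (((bk - 1) * sp[3]) - p[3])^2
        rho <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
        w <- array(pmin(1, pmax(0, (radius - rho) / (0.3 * radius))),
                   dim = dim(rho))  # 1 in core, 0 at rim
        tex_par <- config$texture_heterogeneity[[if (is_cs) "cs" else "noncs"]]
        G <- gaussian_field(dim(w), sp, tex_par[["corr_mm"]])
        for (sq in names(vols)) {
          lv <- seq_levels[[sq]]
          core <- if (is_cs) lv[4] else lv[3]
          blk <- vols[[sq]][bi, bj, bk]
          blk <- blk + (core - blk) * w
          blk <- blk * (1 + tex_par[["amplitude"]] * G * w)
          vols[[sq]][bi, bj, bk] <- blk
        }
        lesions[[li]] <- structure(
          list(lesion_id = sprintf("case%03d_les%d", ci, li),
               center_voxel = v0, radius_mm = radius, is_cs = is_cs),
          class = "lesion_truth")
      }

      # per-center effects: global scale plus sequence-proportional noise
      cs_id <- case_center[ci]
      for (sq in names(vols)) {
        fac <- seq_levels[[sq]][2] / adc_gland
        vols[[sq]] <- center_scale[cs_id] * vols[[sq]] +
          array(stats::rnorm(prod(dims), 0, center_noise[cs_id] * fac), dim = dims)
      }
      vols <- lapply(vols, image_volume, spacing = sp)

      cases[[ci]] <- structure(
        list(case_id = sprintf("case%03d", ci),
             center_id = cs_id,
             volumes = vols,
             prostate_mask = gland,
             spacing = sp,
             lesions = lesions),
        class = "synthetic_case")
    }

    for (ci in seq_len(config$n_cases)) {
      for (li in seq_along(cases[[ci]]$lesions)) {
        les <- cases[[ci]]$lesions[[li]]
        click_seed <- (config$seed * 7919L + ci * 131L + li) %% 2147483647L
        click <- simulate_click(cases[[ci]], les,
                                jitter_voxels = config$click_jitter_voxels,
                                seed = click_seed)
        man[[length(man) + 1L]] <- data.frame(
          case_id = cases[[ci]]$case_id, center_id = cases[[ci]]$center_id,
          lesion_id = les$lesion_id,
          click_i = click[1], click_j = click[2], click_k = click[3],
          radius_mm = les$radius_mm, is_cs = les$is_cs)
      }
    }
    structure(list(cases = cases,
                   manifest = do.call(rbind, man),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d cases, %d lesions (%d CS), %d centers>\n",
              length(x$cases), nrow(x$manifest), sum(x$manifest$is_cs),
              x$config$n_centers))
  invisible(x)
}

# In-lesion voxels (1-based linear indices) of a lesion sphere clipped to
# the prostate mask.
lesion_voxels <- function(case, lesion) {
  dims <- dim(case$prostate_mask)
  sp <- case$spacing
  p <- lesion$center_voxel * sp
  r <- lesion$radius_mm
  dx2 <- (((seq_len(dims[1]) - 1) * sp[1]) - p[1])^2
  dy2 <- (((seq_len(dims[2]) - 1) * sp[2]) - p[2])^2
  dz2 <- (((seq_len(dims[3]) - 1) * sp[3]) - p[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
  which(inside & case$prostate_mask)
}

#' Simulate a radiologist's click on a lesion
#'
#' Emulates the single mouse click on the visually lowest-ADC part of a
#' lesion: the true in-lesion ADC-minimum voxel, jittered by at most
#' `jitter_voxels` in Chebyshev distance, constrained to the prostate mask.
#'
#' @param case a `synthetic_case`.
#' @param lesion one of `case$lesions`.
#' @param jitter_voxels Chebyshev jitter radius (0 = exact minimum).
#' @param seed integer seed.
#' @return 0-based click voxel `(i, j, k)`.
#' @export
simulate_click <- function(case, lesion, jitter_voxels = 1, seed = 1) {
  vox <- lesion_voxels(case, lesion)
  if (length(vox) == 0) stop("lesion has no in-mask voxels")
  adc <- case$volumes$ADC$values
  amin <- vox[which.min(adc[vox])]
  v0 <- as.integer(arrayInd(amin, dim(adc))) - 1L
  if (jitter_voxels == 0) return(v0)
  dims <- dim(adc)
  with_seed(seed, {
    for (try in 1:50) {
      off <- sample((-jitter_voxels):jitter_voxels, 3, replace = TRUE)
      cand <- v0 + off
      if (!in_bounds0(cand, dims)) next
      if (case$prostate_mask[cand[1] + 1L, cand[2] + 1L, cand[3] + 1L])
        return(as.integer(cand))
    }
    v0
  })
}
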