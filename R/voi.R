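#' Default 56-voxel search neighborhood
#'
#' The local search region used to reposition a mouse click onto the true
#' lowest-ADC voxel. It is the Euclidean lattice ball of squared radius 5
#' around the origin, excluding the origin itself: all integer offsets
#' `(di, dj, dk) != 0` with `di^2 + dj^2 + dk^2 <= 5`. This is the unique
#' small lattice ball containing exactly 56 offsets (shells of squared norm
#' 1, 2, 3, 4, 5 contribute 6 + 12 + 8 + 6 + 24), i.e. "56-connectivity".
#'
#' @param max_sq_norm squared lattice radius of the ball (default 5).
#' @return Integer matrix with one offset per row, columns `di, dj, dk`;
#'   closed under negation.
#' @export
default_search_neighborhood <- function(max_sq_norm = 5) {
  r <- floor(sqrt(max_sq_norm))
  g <- as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
  n2 <- rowSums(g^2)
  out <- g[n2 > 0 & n2 <= max_sq_norm, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

# Outlier-robust score of one candidate voxel: mean ADC over the voxel and
# its in-bounds, in-mask face neighbors (up to 7 voxels). A single-voxel
# outlier cannot dominate this mean.
cross_mean_score <- function(adc_arr, mask_arr, v1) {
  offs <- rbind(c(0L, 0L, 0L),
                c(1L, 0L, 0L), c(-1L, 0L, 0L),
                c(0L, 1L, 0L), c(0L, -1L, 0L),
                c(0L, 0L, 1L), c(0L, 0L, -1L))
  dims <- dim(adc_arr)
  tot <- 0
  cnt <- 0L
  for (r in seq_len(nrow(offs))) {
    w <- v1 + offs[r, ]
    if (any(w < 1L) || any(w > dims)) next
    if (!is.null(mask_arr) && !mask_arr[w[1], w[2], w[3]]) next
    tot <- tot + adc_arr[w[1], w[2], w[3]]
    cnt <- cnt + 1L
  }
  tot / cnt
}

#' Reposition a click to the robust lowest-ADC voxel
#'
#' Candidates are the click plus its search neighborhood, restricted to the
#' grid and (when given) the prostate mask. Each candidate is scored by the
#' mean ADC over itself and its available face neighbors (a cross-shaped
#' mean robust to single-voxel outliers); the candidate with the smallest
#' score wins. Ties break to the candidate closest to the click in physical
#' distance, then lexicographically by `(k, j, i)`.
#'
#' @param adc ADC map as an [image_volume].
#' @param click 0-based voxel index `(i, j, k)` of the mouse click.
#' @param prostate_mask optional logical array on the same grid.
#' @param spec offset matrix from [default_search_neighborhood()].
#' @return 0-based integer voxel index of the selected seed.
#' @export
find_seed_voxel <- function(adc, click, prostate_mask = NULL,
                            spec = default_search_neighborhood()) {
  stopifnot(inherits(adc, "image_volume"))
  dims <- dim(adc$values)
  click <- as.integer(click)
  if (!in_bounds0(click, dims))
    stop("click outside grid bounds")
  cand <- rbind(c(0L, 0L, 0L), spec)
  cand <- sweep(cand, 2, click, "+")
  keep <- cand[, 1] >= 0L & cand[, 2] >= 0L & cand[, 3] >= 0L &
    cand[, 1] < dims[1] & cand[, 2] < dims[2] & cand[, 3] < dims[3]
  cand <- cand[keep, , drop = FALSE]
  if (!is.null(prostate_mask)) {
    inm <- prostate_mask[cand + 1L]
    cand <- cand[inm, , drop = FALSE]
  }
  if (nrow(cand) == 0L)
    stop("invalid click: no candidate voxel inside the prostate mask")
  scores <- vapply(seq_len(nrow(cand)), function(r)
    cross_mean_score(adc$values, prostate_mask, cand[r, ] + 1L), numeric(1))
  d2 <- colSums((t(cand) - click)^2 * adc$spacing^2)
  ord <- order(scores, d2, cand[, 3], cand[, 2], cand[, 1])
  as.integer(cand[ord[1], ])
}

#' Rasterize a physical-space sphere on an anisotropic grid
#'
#' A voxel belongs to the sphere iff the physical (mm) distance between its
#' center and the seed voxel's center is at most `diameter_mm / 2`; the
#' sphere is clipped at the grid bounds. Membership uses non-strict `<=`.
#'
#' @param dims grid dimensions `(nx, ny, nz)`.
#' @param spacing voxel spacing in mm.
#' @param center 0-based seed voxel index.
#' @param diameter_mm sphere diameter in mm (> 0).
#' @return A `voi_mask`: list with logical `mask`, `seed_voxel` (0-based) and
#'   `diameter_mm`.
#' @export
rasterize_sphere <- function(dims, spacing, center, diameter_mm) {
  if (diameter_mm <= 0) stop("diameter_mm must be > 0")
  center <- as.integer(center)
  if (!in_bounds0(center, dims)) stop("center outside grid bounds")
  r <- diameter_mm / 2
  dx2 <- ((seq_len(dims[1]) - 1L - center[1]) * spacing[1])^2
  dy2 <- ((seq_len(dims[2]) - 1L - center[2]) * spacing[2])^2
  dz2 <- ((seq_len(dims[3]) - 1L - center[3]) * spacing[3])^2
  m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
  structure(list(mask = m, seed_voxel = center, diameter_mm = diameter_mm),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask d=%g mm, seed=(%s), %d voxels>\n", x$diameter_mm,
              paste(x$seed_voxel, collapse = ","), sum(x$mask)))
  invisible(x)
}

#' Intersect a spherical VOI with the whole-prostate mask
#'
#' Removes all sphere voxels outside the prostate. A quality check requires
#' the index (seed) voxel to survive the masking: the seed sits inside the
#' lesion and therefore inside the prostate, so losing it signals a
#' defective prostate segmentation and raises an error of class
#' `dlmvoi_qc_error`.
#'
#' @param voi a `voi_mask`.
#' @param prostate_mask logical array on the same grid.
#' @return The masked `voi_mask`.
#' @export
apply_prostate_mask <- function(voi, prostate_mask) {
  stopifnot(inherits(voi, "voi_mask"))
  if (!all(dim(voi$mask) == dim(prostate_mask)))
    stop("grids not aligned")
  s1 <- voi$seed_voxel + 1L
  if (!isTRUE(prostate_mask[s1[1], s1[2], s1[3]] != 0))
    stop(structure(
      class = c("dlmvoi_qc_error", "error", "condition"),
      list(message = "quality-control violation: prostate mask removes the index voxel",
           call = sys.call(-1))))
  voi$mask <- voi$mask & (prostate_mask != 0)
  voi
}

#' Build a DLM auto-fixed VOI from a single click
#'
#' The full semi-automatic segmentation: reposition the click to the robust
#' lowest-ADC voxel, rasterize a sphere of the requested diameter around it,
#' and intersect with the whole-prostate mask. Every voxel of the result
#' lies inside the prostate.
#'
#' @param case a `synthetic_case` (uses its ADC volume and prostate mask),
#'   or an [image_volume] ADC map (then `prostate_mask` is required).
#' @param click 0-based voxel index of the mouse click.
#' @param diameter_mm initial sphere diameter in mm.
#' @param prostate_mask logical array; ignored when `case` is a
#'   `synthetic_case`.
#' @param spec search neighborhood for the repositioning step.
#' @return A masked `voi_mask`.
#' @export
build_dlm_voi <- function(case, click, diameter_mm, prostate_mask = NULL,
                          spec = default_search_neighborhood()) {
  if (inherits(case, "synthetic_case")) {
    adc <- case$volumes$ADC
    prostate_mask <- case$prostate_mask
  } else {
    adc <- case
    if (is.null(prostate_mask)) stop("prostate_mask required")
  }
  seed <- find_seed_voxel(adc, click, prostate_mask, spec)
  voi <- rasterize_sphere(dim(adc$values), adc$spacing, seed, diameter_mm)
  apply_prostate_mask(voi, prostate_mask)
}

#' Diameter sweep grid
#'
#' The 13 initial sphere diameters explored when optimizing the auto-fixed
#' VOI size: 6 to 30 mm in 2-mm steps.
#'
#' @return Integer vector of 13 diameters in mm.
#' @export
sweep_diameters <- function() {
  seq(6L, 30L, by = 2L)
}
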