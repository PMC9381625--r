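make_voi <- function(mask) {
  seedv <- which(mask, arr.ind = TRUE)[1, ] - 1L
  structure(list(mask = mask, seed_voxel = as.integer(seedv),
                 diameter_mm = NA_real_), class = "voi_mask")
}

# single-slice volume + VOI from a 2D matrix of intensities (NA = outside)
slice_voi <- function(m, W = 10) {
  vals <- array(0, dim = c(nrow(m), ncol(m), 1))
  vals[, , 1] <- ifelse(is.na(m), 0, m)
  mask <- array(!is.na(m), dim = dim(vals))
  vol <- image_volume(vals, c(1, 1, 1))
  discretize_voi(vol, make_voi(mask), W)
}

test_that("z-normalization centers, scales, and is idempotent", {
  set.seed(3)
  v <- image_volume(array(stats::rnorm(6 * 6 * 4, 50, 9), dim = c(6, 6, 4)),
                    c(0.5, 0.5, 3))
  z <- znormalize(v, scale = 100)
  expect_lt(abs(mean(z$values)), 1e-6 * 100)
  expect_lt(abs(sqrt(mean((z$values - mean(z$values))^2)) - 100) / 100, 1e-6)
  z1 <- znormalize(v, scale = 1)
  z2 <- znormalize(z1, scale = 1)
  expect_lt(max(abs(z1$values - z2$values)), 1e-12)
  # {0, 10} equally frequent -> {-100, +100}
  tw <- image_volume(array(c(0, 10), dim = c(2, 1, 1)), c(1, 1, 1))
  expect_equal(sort(unique(as.numeric(znormalize(tw, 100)$values))),
               c(-100, 100))
  const <- image_volume(array(5, dim = c(3, 3, 1)), c(1, 1, 1))
  expect_error(znormalize(const), "degenerate")
})

test_that("fixed-bin-width discretization follows the floor formula", {
  vals <- array(0, dim = c(4, 1, 1))
  vals[, 1, 1] <- c(0, 29.9, 30, 95)
  vol <- image_volume(vals, c(1, 1, 1))
  voi <- make_voi(array(TRUE, dim = dim(vals)))
  d <- discretize_voi(vol, voi, W = 30)
  expect_identical(d$levels, c(1L, 1L, 2L, 4L))
  expect_identical(d$n_bins, 4L)
  # constant VOI
  cv <- image_volume(array(7, dim = c(2, 2, 1)), c(1, 1, 1))
  dc <- discretize_voi(cv, make_voi(array(TRUE, dim = c(2, 2, 1))), 30)
  expect_true(all(dc$levels == 1L))
  expect_identical(dc$n_bins, 1L)
  # shift by W leaves levels unchanged
  d2 <- discretize_voi(image_volume(vals + 30, c(1, 1, 1)), voi, 30)
  expect_identical(d2$levels, d$levels)
})

test_that("first-order features match hand calculations", {
  f <- first_order_features(c(1, 2, 3, 4), c(1L, 2L, 3L, 4L), voxel_volume = 2)
  expect_equal(f[["Entropy"]], 2)          # 4 voxels in 4 distinct bins
  expect_equal(f[["Uniformity"]], 0.25)
  expect_equal(f[["Mean"]], 2.5)
  expect_equal(f[["Variance"]], 1.25)      # population variance
  expect_equal(f[["Range"]], 3)
  expect_equal(f[["Energy"]], 30)
  expect_equal(f[["TotalEnergy"]], 60)
  fc <- first_order_features(rep(5, 6), rep(1L, 6))
  expect_equal(fc[["Entropy"]], 0)
  expect_equal(fc[["Variance"]], 0)
  expect_equal(fc[["Skewness"]], 0)
  expect_length(f, 18L)
})

test_that("GLCM features match brute-force pair counting", {
  # levels [[1,1],[2,2]] on one slice (rows = i)
  d <- slice_voi(matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE) * 10)
  expect_identical(sort(unique(d$levels)), c(1L, 2L))
  got <- glcm_features(d)
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  sl <- d$level_array[, , 1]
  rows <- lapply(dirs, function(dd)
    oracle_glcm_feats(oracle_glcm_mat(sl, dd[1], dd[2], d$n_bins)))
  want <- colMeans(do.call(rbind, rows[!vapply(rows, is.null, NA)]))
  expect_equal(got, want, tolerance = 1e-12)
  # hand check for direction (1,0): both columns pair 1-2 -> contrast 1
  P10 <- oracle_glcm_mat(sl, 1, 0, d$n_bins)
  expect_equal(sum(P10), 4)                # 2 ordered pairs, symmetric
  expect_equal(P10[1, 2], 2)

  # checkerboard: 0/90-degree contrast maximal, no diagonal mass
  cb <- matrix(rep(c(1, 2), 8), 4, 4)
  cb[, c(2, 4)] <- 3 - cb[, c(2, 4)]
  dcb <- slice_voi(cb * 10)
  slcb <- dcb$level_array[, , 1]
  P0 <- oracle_glcm_mat(slcb, 0, 1, dcb$n_bins)
  expect_equal(P0[1, 1] + P0[2, 2], 0)     # joint maximum off-diagonal only
  f0 <- dlmvoi:::glcm_from_counts(P0)
  expect_equal(f0[["Contrast"]], 1)
})

test_that("degenerate single-level slices use the documented conventions", {
  d <- slice_voi(matrix(5, 3, 3))          # constant -> one level
  g <- glcm_features(d)
  expect_equal(g[["Contrast"]], 0)
  expect_equal(g[["Correlation"]], 1)
  n <- ngtdm_features(d)
  expect_equal(n[["Coarseness"]], 1e6)
  gd <- gldm_features(d)
  # center voxel of 3x3 has dependence 9 = itself + 8 equal neighbors
  P <- dlmvoi:::cpp_gldm_slice(d$level_array[, , 1], d$n_bins, 0L)
  expect_equal(P[1, 9], 1)
  expect_equal(sum(P), 9)
})

test_that("GLRLM and GLSZM match hand counts on tiny patterns", {
  # 1x4 run of a single level
  d <- slice_voi(matrix(7, 1, 4))
  P <- dlmvoi:::cpp_glrlm_slice(matrix(d$level_array[, , 1], 1, 4), 0L, 1L,
                                d$n_bins)
  expect_equal(P[1, 4], 1)                 # one run of length 4
  expect_equal(sum(P), 1)
  g <- glrlm_features(d)
  expect_equal(g[["RunLengthNonUniformity"]],
               mean(c(1, 4, 4, 4)))        # dir 0: 1 run; others: 4 runs of 1

  # two 8-connected zones, sizes 3 and 1
  m <- matrix(NA, 3, 4)
  m[1, 1] <- 10; m[2, 2] <- 10; m[1, 2] <- 10   # L-shaped zone, size 3
  m[3, 4] <- 10                                  # isolated voxel
  dz <- slice_voi(m)
  zones <- dlmvoi:::cpp_glszm_slice(dz$level_array[, , 1])
  expect_equal(sort(zones[, 2]), c(1, 3))
  expect_identical(zones[, 1], c(1L, 1L))
})

test_that("extraction yields 279 deterministic, shift-invariant features", {
  co <- tiny_cohort()
  case <- co$cases[[1]]
  click <- as.integer(co$manifest[1, c("click_i", "click_j", "click_k")])
  voi <- build_dlm_voi(case, click, 14)
  f1 <- extract_case(case, voi)
  f2 <- extract_case(case, voi)
  expect_length(f1, 279L)
  expect_identical(f1, f2)
  expect_false(any(is.na(f1)))
  expect_identical(names(f1)[1], "T2_firstorder_Energy")
  # shifting one sequence's intensities leaves its features unchanged
  shifted <- case
  shifted$volumes$ADC$values <- case$volumes$ADC$values + 500
  f3 <- extract_case(shifted, voi)
  adc_cols <- grep("^ADC_", names(f1))
  expect_equal(f3[adc_cols], f1[adc_cols], tolerance = 1e-9)
})

test_that("in-plane rotation permutes directions but preserves averaged features", {
  set.seed(11)
  m <- matrix(stats::rnorm(36, 100, 30), 6, 6)
  d <- slice_voi(m, W = 20)
  dr <- slice_voi(t(m)[ncol(m):1, ], W = 20)   # 90-degree rotation
  fams <- list(glcm_features, glrlm_features, glszm_features,
               gldm_features, ngtdm_features)
  for (f in fams)
    expect_equal(f(dr), f(d), tolerance = 1e-10)
})

test_that("implementation agrees with the naive reference on random VOIs", {
  for (s in 1:5) {
    rv <- random_small_voi(s)
    got <- dlmvoi:::voi_features(rv$vol, rv$voi, extraction_params())
    want <- oracle_voi_features(rv$vol$values, rv$voi$mask, rv$vol$spacing)
    expect_equal(got, want, tolerance = 1e-9, label = sprintf("seed %d", s))
  }
})
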