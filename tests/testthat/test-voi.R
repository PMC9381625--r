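test_that("search neighborhood is the 56-offset lattice ball", {
  nb <- default_search_neighborhood()
  expect_equal(nrow(nb), 56L)
  # brute-force lattice enumeration
  expected <- NULL
  for (di in -3:3) for (dj in -3:3) for (dk in -3:3) {
    n2 <- di^2 + dj^2 + dk^2
    if (n2 > 0 && n2 <= 5) expected <- rbind(expected, c(di, dj, dk))
  }
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(nb), key(expected))
  expect_true(any(apply(nb, 1, identical, y = c(di = 1L, dj = 0L, dk = 0L))))
  has <- function(v) any(nb[, 1] == v[1] & nb[, 2] == v[2] & nb[, 3] == v[3])
  expect_true(has(c(2L, 1L, 0L)))
  expect_false(has(c(2L, 2L, 0L)))  # squared norm 8
  # closed under negation
  expect_identical(key(nb), key(-nb))
})

test_that("seed repositioning is outlier-robust and matches exhaustive scoring", {
  sp <- c(0.5, 0.5, 3)
  # uniform volume: click wins all ties
  u <- image_volume(array(1000, dim = c(9, 9, 5)), sp)
  expect_identical(find_seed_voxel(u, c(4, 4, 2)), c(4L, 4L, 2L))

  # single 100-outlier vs a 2x2x2 block at 600
  a <- array(1000, dim = c(9, 9, 5))
  click <- c(4L, 4L, 2L)
  a[4 + 2 + 1, 4 + 1 + 1, 2 + 1] <- 100          # offset (2,1,0)
  a[(4 - 2 + 1):(4 - 1 + 1), (4 + 1):(4 + 2), (2 + 1):(2 + 2)] <- 600
  vol <- image_volume(a, sp)
  seed <- find_seed_voxel(vol, click)
  expect_equal(a[seed[1] + 1, seed[2] + 1, seed[3] + 1], 600)
  expect_identical(seed, oracle_seed_voxel(a, sp, click))

  # random volumes agree with the exhaustive oracle
  for (s in 1:5) {
    set.seed(s)
    arr <- array(stats::runif(9 * 9 * 5, 500, 1500), dim = c(9, 9, 5))
    v <- image_volume(arr, sp)
    expect_identical(find_seed_voxel(v, click),
                     oracle_seed_voxel(arr, sp, click))
  }
})

test_that("seed stays inside the prostate mask", {
  sp <- c(0.5, 0.5, 3)
  set.seed(1)
  arr <- array(stats::runif(9 * 9 * 5, 800, 1200), dim = c(9, 9, 5))
  mask <- array(FALSE, dim = c(9, 9, 5))
  mask[1:5, , ] <- TRUE                  # half-space mask, i0 <= 4
  arr[6:9, , ] <- 0                      # tempting low values outside
  v <- image_volume(arr, sp)
  click <- c(4L, 4L, 2L)
  seed <- find_seed_voxel(v, click, mask)
  expect_true(mask[seed[1] + 1, seed[2] + 1, seed[3] + 1])
  expect_identical(seed, oracle_seed_voxel(arr, sp, click, mask))
  # click with no in-mask candidate errors
  mask0 <- array(FALSE, dim = c(9, 9, 5))
  expect_error(find_seed_voxel(v, click, mask0), "invalid click")
})

test_that("seed search is translation-equivariant", {
  sp <- c(0.5, 0.5, 3)
  set.seed(7)
  core <- array(stats::runif(9 * 9 * 5, 500, 1500), dim = c(9, 9, 5))
  big <- array(1e6, dim = c(14, 14, 7))
  shift <- c(3L, 2L, 1L)
  big[3 + (1:9), 2 + (1:9), 1 + (1:5)] <- core
  big_mask <- array(FALSE, dim = dim(big))
  big_mask[3 + (1:9), 2 + (1:9), 1 + (1:5)] <- TRUE
  s1 <- find_seed_voxel(image_volume(core, sp), c(4, 4, 2),
                        array(TRUE, dim = dim(core)))
  s2 <- find_seed_voxel(image_volume(big, sp), c(4, 4, 2) + shift, big_mask)
  expect_identical(s2, s1 + shift)
})

test_that("sphere rasterization matches exhaustive enumeration", {
  dims <- c(61, 61, 21)
  sp <- c(0.5, 0.5, 3)
  ctr <- c(30L, 30L, 10L)
  s <- rasterize_sphere(dims, sp, ctr, 18)
  expect_identical(s$mask, oracle_sphere_voxels(dims, sp, ctr, 18))
  # sub-voxel diameter keeps only the center voxel
  s0 <- rasterize_sphere(dims, sp, ctr, 0.4)
  expect_equal(sum(s0$mask), 1L)
  expect_true(s0$mask[31, 31, 11])
  # flip symmetry about the center on a symmetric grid
  m <- s$mask
  expect_identical(m, m[rev(seq_len(61)), , ])
  expect_identical(m, m[, rev(seq_len(61)), ])
  expect_identical(m, m[, , rev(seq_len(21))])
})

test_that("sphere voxel count is monotone in diameter and converges to (pi/6)d^3", {
  dims <- c(61, 61, 21)
  sp <- c(0.5, 0.5, 3)
  ctr <- c(30L, 30L, 10L)
  counts <- vapply(sweep_diameters(), function(d)
    sum(rasterize_sphere(dims, sp, ctr, d)$mask), 0L)
  expect_true(all(diff(counts) >= 0))
  # refinement: 0.25 mm isotropic, d = 18 mm
  fine <- rasterize_sphere(c(81, 81, 81), c(0.25, 0.25, 0.25),
                           c(40L, 40L, 40L), 18)
  vol <- sum(fine$mask) * 0.25^3
  expect_lt(abs(vol - pi / 6 * 18^3) / (pi / 6 * 18^3), 0.02)
})

test_that("prostate masking intersects, preserves the seed, and errors when it cannot", {
  dims <- c(41, 41, 15)
  sp <- c(0.5, 0.5, 3)
  ctr <- c(20L, 20L, 7L)
  s <- rasterize_sphere(dims, sp, ctr, 14)
  all_true <- array(TRUE, dim = dims)
  expect_identical(apply_prostate_mask(s, all_true)$mask, s$mask)
  # analytic half-space mask: i0 <= 22
  half <- array(FALSE, dim = dims)
  half[1:23, , ] <- TRUE
  masked <- apply_prostate_mask(s, half)
  expect_equal(sum(masked$mask), sum(s$mask & half))
  expect_true(all(masked$mask[24:41, , ] == FALSE))
  expect_true(masked$mask[21, 21, 8])
  # mask false at seed: quality-control error
  bad <- half
  bad[21, 21, 8] <- FALSE
  expect_error(apply_prostate_mask(s, bad), class = "dlmvoi_qc_error")
})

test_that("the composed DLM VOI never leaves the prostate", {
  co <- tiny_cohort()
  man <- co$manifest
  found_leak <- FALSE
  for (r in seq_len(nrow(man))) {
    case <- co$cases[[match(man$case_id[r],
                            vapply(co$cases, `[[`, "", "case_id"))]]
    click <- as.integer(man[r, c("click_i", "click_j", "click_k")])
    voi <- build_dlm_voi(case, click, 18)
    expect_true(all(case$prostate_mask[voi$mask]))
    expect_true(voi$mask[voi$seed_voxel[1] + 1, voi$seed_voxel[2] + 1,
                         voi$seed_voxel[3] + 1])
    naive <- rasterize_sphere(dim(case$prostate_mask), case$spacing,
                              voi$seed_voxel, 18)
    if (any(naive$mask & !case$prostate_mask)) {
      found_leak <- TRUE
      expect_lt(sum(voi$mask), sum(naive$mask))
    } else {
      expect_identical(voi$mask, naive$mask)
    }
  }
  expect_true(found_leak)  # edge lesions exercise the masking step
})

test_that("diameter sweep grid is 6 to 30 mm in 2-mm steps", {
  d <- sweep_diameters()
  expect_length(d, 13L)
  expect_equal(d[1], 6L)
  expect_equal(d[13], 30L)
  expect_true(all(diff(d) == 2L))
})
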