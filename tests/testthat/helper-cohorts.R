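# Shared fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small cohort for structural / pipeline tests.
tiny_cohort <- function() {
  memo("tiny", generate_cohort(phantom_config(n_cases = 10, seed = 5,
                                              cs_fraction = 0.5)))
}

# The default study cohort and its 18-mm feature table (used by the
# class-signal and parameter-recovery checks).
default_cohort <- function() {
  memo("default", generate_cohort(phantom_config()))
}

default_tab18 <- function() {
  memo("tab18", extract_cohort(default_cohort(), 18))
}

# A random small VOI on an anisotropic grid; every used slice keeps at
# least 4 voxels so all texture families are defined.
random_small_voi <- function(seed) {
  set.seed(seed)
  dims <- c(sample(5:8, 1), sample(5:8, 1), sample(2:3, 1))
  vals <- array(stats::rnorm(prod(dims), 1000, 250), dim = dims)
  mask <- array(stats::runif(prod(dims)) < 0.7, dim = dims)
  for (k in seq_len(dims[3]))
    if (sum(mask[, , k]) < 4) mask[, , k] <- FALSE
  if (!any(mask)) mask[2:4, 2:4, 1] <- TRUE
  seedv <- which(mask, arr.ind = TRUE)[1, ] - 1L
  list(vol = image_volume(vals, c(0.5, 0.5, 3)),
       voi = structure(list(mask = mask, seed_voxel = as.integer(seedv),
                            diameter_mm = NA_real_),
                       class = "voi_mask"))
}

# Feature table with planted signal for selection / modeling tests.
synthetic_feature_table <- function(n = 120, p_noise = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rnorm(n * p_noise), n,
              dimnames = list(NULL, paste0("noise", seq_len(p_noise))))
  tab <- data.frame(signal1 = y + stats::rnorm(n, 0, 0.3),
                    signal2 = y + stats::rnorm(n, 0, 0.6), X)
  list(table = tab, labels = y)
}
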