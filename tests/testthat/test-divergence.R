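test_that("Cohen's d matches hand calculations and edge cases", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)

  res <- cohens_d(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$s_p, 1)
  expect_equal(res$d, 3)
  expect_true(res$reportable)

  # means exactly 2 pooled sd apart sit on the overlap threshold
  x <- c(-1, 0, 1); y <- x + 2 * sd(x)
  expect_equal(cohens_d(x, y)$d, 2)

  # zero pooled sd: 0 for equal means, Inf for unequal
  expect_equal(cohens_d(c(2, 2, 2), c(2, 2, 2))$d, 0)
  expect_equal(cohens_d(c(2, 2, 2), c(3, 3, 3))$d, Inf)

  # n = 2 computes but is not reportable (qualitative only)
  expect_false(cohens_d(c(1, 2), c(5, 6))$reportable)
  expect_error(cohens_d(1, c(1, 2)), ">= 2 values")
})

test_that("Cohen's d is symmetric, shift-invariant and scales with pooled sd", {
  set.seed(3)
  x <- rnorm(8); y <- rnorm(10, 1)
  expect_equal(cohens_d(x, y)$d, cohens_d(y, x)$d)
  expect_equal(cohens_d(x + 7, y + 7)$d, cohens_d(x, y)$d)
  expect_equal(cohens_d(3 * x, 3 * y)$d, cohens_d(x, y)$d)  # common scaling cancels
})

test_that("overlap classification is strict at the threshold", {
  rep_tab <- data.frame(species_i = "a", species_j = "b", n_i = 5, n_j = 5,
                        d_PC1 = 1.5, d_PC2 = 1.9, insufficient = FALSE)
  expect_true(classify_overlap(rep_tab)$overlap)

  rep_tab$d_PC2 <- 2.0
  expect_false(classify_overlap(rep_tab)$overlap)  # d = 2 is NOT overlap

  # single-axis case at d = 1.98 (the near-threshold frequency comparison)
  rep_tab <- data.frame(species_i = "a", species_j = "b", n_i = 5, n_j = 5,
                        d_freq = 1.98, insufficient = FALSE)
  expect_true(classify_overlap(rep_tab)$overlap)

  # insufficient samples stay qualitative: NA, never a numeric verdict
  rep_tab$insufficient <- TRUE
  expect_true(is.na(classify_overlap(rep_tab)$overlap))
})

test_that("overlap report computes d per axis from scores", {
  set.seed(4)
  sc <- data.frame(
    species = rep(c("a", "b", "c"), each = 5),
    PC1 = c(rnorm(5, 0), rnorm(5, 10), rnorm(5, 0)),
    PC2 = c(rnorm(5, 0), rnorm(5, 0), rnorm(5, 0.2)))
  out <- classify_overlap(overlap_report(sc))
  ab <- out[out$species_i == "a" & out$species_j == "b", ]
  ac <- out[out$species_i == "a" & out$species_j == "c", ]
  expect_false(ab$overlap)   # far apart on PC1
  expect_true(ac$overlap)    # close on both axes
  expect_equal(ab$d_PC1, cohens_d(sc$PC1[1:5], sc$PC1[6:10])$d)
})

test_that("dispersion Z agrees with exhaustive enumeration on a 5-species pool", {
  set.seed(6)
  pool <- list(a = rnorm(6, 0, 0.1), b = rnorm(6, 0.2, 0.1),
               c = rnorm(6, 0.4, 0.1), d = rnorm(6, 10, 0.1),
               e = rnorm(6, 10.2, 0.1))
  oracle <- exact_dispersion_z(pool, c("a", "d"))  # one species per cluster
  expect_gt(oracle$z, 0)

  dz <- dispersion_z(pool, c("a", "d"), n_draws = 4000, n_replicates = 8,
                     seed = 7)
  expect_equal(dz$observed, oracle$obs, tolerance = 1e-12)
  expect_lt(abs(dz$mean_z - oracle$z), 0.1)
  expect_gt(dz$mean_z, 0)
})

test_that("mean Z over all possible communities is near zero", {
  set.seed(8)
  pool <- lapply(setNames(nm = paste0("s", 1:5)),
                 function(s) rnorm(5, runif(1, -1, 1)))
  combos <- combn(names(pool), 2)
  zs <- vapply(seq_len(ncol(combos)), function(k) {
    dispersion_z(pool, combos[, k], n_draws = 1500, n_replicates = 4,
                 seed = 20 + k)$mean_z
  }, 0)
  expect_lt(abs(mean(zs)), 0.12)
})

test_that("Z is invariant to affine transformation of the trait axis", {
  set.seed(9)
  pool <- lapply(setNames(nm = paste0("s", 1:8)), function(s) rnorm(5, runif(1)))
  z1 <- dispersion_z(pool, c("s1", "s4", "s7"), n_draws = 400,
                     n_replicates = 3, seed = 10)
  pool2 <- lapply(pool, function(v) -2.5 * v + 7)
  z2 <- dispersion_z(pool2, c("s1", "s4", "s7"), n_draws = 400,
                     n_replicates = 3, seed = 10)
  expect_equal(z1$z, z2$z)
  expect_equal(z1$p, z2$p)
})

test_that("members below the sample-size floor are excluded with a warning", {
  pool <- list(a = rnorm(5), b = rnorm(5), c = rnorm(2), d = rnorm(5),
               e = rnorm(5), f = rnorm(6))
  expect_warning(
    dz <- dispersion_z(pool, c("a", "b", "c"), n_draws = 200,
                       n_replicates = 2, seed = 1),
    "n < 3")
  expect_equal(dz$n_members, 2)
  expect_equal(dz$n_pool, 5)
  expect_error(dispersion_z(pool, c("a", "z"), n_draws = 10,
                            n_replicates = 1), "not in pool")
})

test_that("the individual-value null mode runs and centres near zero too", {
  set.seed(12)
  pool <- lapply(setNames(nm = paste0("s", 1:6)), function(s) rnorm(6))
  dz <- dispersion_z(pool, c("s1", "s2", "s3"), n_draws = 300,
                     n_replicates = 3, unit = "values", seed = 2)
  expect_true(is.finite(dz$mean_z))
  expect_lt(abs(dz$mean_z), 3)
})
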