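test_that("Yule trees are ultrametric, reproducible, and a cherry at n = 2", {
  tr <- simulate_yule_tree(2, seed = 50)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(tr$edge.length[1], tr$edge.length[2])  # equal tip depths

  tr1 <- simulate_yule_tree(12, seed = 51)
  tr2 <- simulate_yule_tree(12, seed = 51)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  expect_true(ape::is.ultrametric(tr1, tol = 1e-8))
  expect_true(ape::is.binary.phylo(tr1))
  expect_silent(validate_phylogeny(tr1))
})

test_that("the pure-birth clock grows at rate exp(birth * t)", {
  set.seed(52)
  counts <- vapply(1:500, function(i) yule_lineage_count(2, birth = 1), 0L)
  # E = e^2 ~ 7.39, Var = e^2(e^2 - 1), se ~ 0.31 at 500 draws
  expect_lt(abs(mean(counts) - exp(2)), 1)
})

test_that("Brownian traits follow the variance law and its degenerate limits", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(simulate_bm_traits(tr, sigma2 = 0, seed = 53)), c(0, 0))

  set.seed(54)
  diffs <- vapply(1:2000, function(i) {
    x <- simulate_bm_traits(tr, sigma2 = 1)
    x[1] - x[2]
  }, 0)
  expect_lt(abs(var(diffs) - 2), 0.2)  # Var(x_A - x_B) = 2 sigma^2 t

  # seeded reproducibility
  expect_identical(simulate_bm_traits(tr, seed = 55),
                   simulate_bm_traits(tr, seed = 55))
})

test_that("lambda = 0 and white-noise traits have matching K distributions", {
  set.seed(56)
  tr <- simulate_yule_tree(12, seed = 56)
  k_lambda <- vapply(1:60, function(i)
    blomberg_k(tr, simulate_bm_traits(tr, transform = "lambda", delta = 0)), 0)
  k_white <- vapply(1:60, function(i)
    blomberg_k(tr, simulate_bm_traits(tr, transform = "white")), 0)
  expect_gt(suppressWarnings(stats::ks.test(k_lambda, k_white)$p.value), 0.01)
})

test_that("specimen generator controls within-species spread and separation", {
  vals <- c(sp1 = 0, sp2 = 10)
  tt0 <- simulate_specimens(vals, counts = 4, within_sd = 0, trait_sd = 0,
                            seed = 57)
  sp1 <- tt0[tt0$species == "sp1", trait_measurement_names()]
  expect_true(all(vapply(sp1, function(v) diff(range(v)) == 0, TRUE)))

  tt <- simulate_specimens(vals, counts = 10, within_sd = 1, trait_sd = 0.02,
                           seed = 58)
  p <- pca_svd(log_transform(tt))
  d <- cohens_d(p$scores$PC1[p$scores$species == "sp1"],
                p$scores$PC1[p$scores$species == "sp2"])$d
  expect_gt(d, 2)  # species 10 within-sd apart are far beyond overlap

  # PC1 dominance grows as trait-specific noise vanishes
  spread <- setNames(rnorm(6, 0, 1), paste0("s", 1:6))
  pv <- vapply(c(0.5, 0.1, 0.01), function(ts) {
    tt <- simulate_specimens(spread, counts = 6, within_sd = 0.1,
                             trait_sd = ts, seed = 59)
    pca_svd(log_transform(tt))$percent_var[1]
  }, 0)
  expect_true(all(diff(pv) > 0))
  expect_gt(pv[3], 99)
})

test_that("assembly modes order trait spacing as designed", {
  set.seed(60)
  vals <- setNames(rnorm(15), paste0("s", 1:15))
  min_gap <- function(members) min(dist(vals[members]))
  for (i in 1:10) {
    over <- assemble_communities(vals, "overdispersed", size = 5,
                                 seed = 60 + i)$communities[[1]]
    rand <- assemble_communities(vals, "random", size = 5,
                                 seed = 60 + i)$communities[[1]]
    expect_gte(min_gap(over), min_gap(rand))
  }
  clus <- assemble_communities(vals, "clustered", size = 5,
                               seed = 61)$communities[[1]]
  expect_lte(min_gap(clus), min_gap(over))
})

test_that("full-detection single-cell communities give the (1-P)/P co-occurrence pattern", {
  set.seed(62)
  vals <- setNames(rnorm(12), paste0("s", 1:12))
  asm <- assemble_communities(vals, "random", size = 3, n_communities = 4,
                              detection_prob = 1, cells_per_community = 1,
                              seed = 63)
  m <- grid_occurrences(asm$occurrences, cell_size_deg = asm$cell_size)
  expect_equal(nrow(m), 4)  # one site per community
  res <- do_index(m)
  # a pair sharing all its cells: P_ij = P_i = P_j = P -> DO = (1 - P)/P
  members <- asm$communities[[1]]
  p_shared <- res[res$species_i == sort(members[1:2])[1] &
                  res$species_j == sort(members[1:2])[2], ]
  if (p_shared$p_i == p_shared$p_ij && p_shared$p_j == p_shared$p_ij) {
    expect_equal(p_shared$do, (1 - p_shared$p_i) / p_shared$p_i)
  }
})

test_that("chorus synthesis round-trips peak frequencies and supports edge cases", {
  spec <- data.frame(species = c("a", "b", "c"), peak_hz = c(800, 1600, 2400),
                     period_s = 1, element_s = 0.2)
  ch <- simulate_chorus(spec, duration = 9, seed = 64)
  expect_gt(nrow(ch$annotations), 0)
  sp <- extract_peak_frequencies(ch$waveform, ch$sample_rate, ch$annotations,
                                 fmin = 0)
  expect_lt(max(abs(sp$peak_hz - ch$annotations$freq_hz)), 2)

  # two far species: Mann-Whitney p < 0.01
  spec2 <- spec[c(1, 3), ]
  ch2 <- simulate_chorus(spec2, duration = 14, freq_jitter = 10, seed = 65)
  sp2 <- extract_peak_frequencies(ch2$waveform, ch2$sample_rate,
                                  ch2$annotations, fmin = 0)
  expect_lt(compare_chorus(sp2)$p, 0.01)

  # zero-duration request
  ch0 <- simulate_chorus(spec, duration = 0, seed = 66)
  expect_equal(length(ch0$waveform), 0)
  expect_equal(nrow(ch0$annotations), 0)

  # Nyquist guard and bit-reproducibility
  expect_error(simulate_chorus(data.frame(species = "a", peak_hz = 20000,
                                          period_s = 1, element_s = 0.1),
                               sample_rate = 22050), "Nyquist")
  chA <- simulate_chorus(spec, duration = 3, freq_jitter = 5, seed = 67)
  chB <- simulate_chorus(spec, duration = 3, freq_jitter = 5, seed = 67)
  expect_identical(chA$waveform, chB$waveform)
  expect_identical(chA$annotations, chB$annotations)
})
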