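test_that("contrasts match closed forms on tiny trees", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  pc <- pic_contrasts(tr, c(A = 0, B = 2))
  expect_equal(nrow(pc), 1)
  expect_equal(abs(pc$contrast), 2 / sqrt(2))
  expect_equal(pc$expected_var, 2)

  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  pc4 <- pic_contrasts(tr4, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(pc4$contrast, rep(0, 3))  # constant trait: all contrasts 0
})

test_that("sum of squared contrasts equals the GLS quadratic form", {
  set.seed(31)
  for (i in 1:6) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    x <- rnorm(n)
    names(x) <- tr$tip.label
    pc <- pic_contrasts(tr, x)
    expect_equal(nrow(pc), n - 1)
    V <- ape::vcv(tr)
    Vi <- solve(V)
    a <- sum(Vi %*% x[rownames(V)]) / sum(Vi)
    dev <- x[rownames(V)] - a
    mse <- drop(t(dev) %*% Vi %*% dev) / (n - 1)
    expect_equal(sum(pc$contrast^2), (n - 1) * mse, tolerance = 1e-8)
    # and the contrasts agree with ape's implementation up to sign
    expect_equal(sort(abs(pc$contrast)),
                 sort(abs(as.numeric(ape::pic(x, tr)))), tolerance = 1e-10)
  }
})

test_that("K is exactly 1 on a star phylogeny", {
  for (len in c(0.5, 1, 3)) {
    tr <- star_tree(8, len)
    x <- setNames(rnorm(8), tr$tip.label)
    expect_equal(blomberg_k(tr, x), 1, tolerance = 1e-12)
  }
})

test_that("K matches an independent implementation and its invariances", {
  set.seed(33)
  tr <- simulate_yule_tree(15, seed = 33)
  x <- simulate_bm_traits(tr, seed = 34)
  k <- blomberg_k(tr, x)
  expect_equal(k, picante::Kcalc(x[tr$tip.label], tr), tolerance = 1e-10,
               ignore_attr = TRUE)

  # affine transform of the trait and rescaling of all branch lengths
  expect_equal(blomberg_k(tr, 3 * x - 10), k, tolerance = 1e-10)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.5
  expect_equal(blomberg_k(tr2, x), k, tolerance = 1e-10)
})

test_that("K averages near 1 under Brownian motion and falls for white noise", {
  set.seed(35)
  ks <- vapply(1:40, function(i) {
    tr <- simulate_yule_tree(20)
    blomberg_k(tr, simulate_bm_traits(tr))
  }, 0)
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 1), 3 * se + 0.05)

  tr <- balanced_tree(5, depth = 1)  # 32 tips, deep structure
  kw <- vapply(1:40, function(i) {
    blomberg_k(tr, simulate_bm_traits(tr, transform = "white"))
  }, 0)
  expect_lt(median(kw), 0.5)
})

test_that("tip-shuffle p matches the exhaustive 24-permutation distribution", {
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 1, B = 2, C = 10, D = 11)  # clade-ordered: strong signal
  eng_stat <- function(vals) var(pic_contrasts(tr4, setNames(vals, names(x)))$contrast)
  obs <- eng_stat(x)
  allp <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  allp <- allp[apply(allp, 1, function(r) length(unique(r)) == 4), ]
  null <- apply(allp, 1, function(ix) eng_stat(unname(x)[as.integer(ix)]))
  p_exact <- mean(null <= obs)

  res <- tip_shuffle_p(tr4, x, n_shuffles = 600, seed = 36)
  # estimate within binomial error of the exhaustive value
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / 600) + 2 / 600
  expect_lt(abs(res$p - p_exact), tol + 0.02)
  expect_equal(res$n_taxa, 4)
})

test_that("strong clade structure reaches the add-one p floor", {
  set.seed(37)
  tr <- balanced_tree(4, depth = 3)      # 16 tips
  # trait tracks clade membership tightly
  x <- setNames(rep(c(-10, -5, 5, 10), each = 4) + rnorm(16, 0, 0.1),
                tr$tip.label)
  res <- tip_shuffle_p(tr, x, n_shuffles = 500, seed = 38)
  expect_equal(res$p, 1 / 501)
})

test_that("null-trait p values are roughly uniform", {
  set.seed(39)
  tr <- simulate_yule_tree(10, seed = 39)
  ps <- vapply(1:60, function(i) {
    x <- setNames(rnorm(10), tr$tip.label)   # no signal at all
    tip_shuffle_p(tr, x, n_shuffles = 99)$p
  }, 0)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(min(ps), 0)
})

test_that("degenerate and malformed traits are flagged", {
  tr <- simulate_yule_tree(6, seed = 40)
  res <- tip_shuffle_p(tr, setNames(rep(2, 6), tr$tip.label),
                       n_shuffles = 50, seed = 41)
  expect_true(res$degenerate)
  expect_equal(res$p, 1)

  expect_error(pic_contrasts(tr, c(t1 = 1)), "missing for tips")
  expect_error(blomberg_k(tr, setNames(c(1, 2, NA, 4, 5, 6), tr$tip.label)),
               "NA")
})

test_that("polytomies are resolved with a warning and K uses the exact covariance", {
  tr <- ape::read.tree(text = "(A:2,B:2,C:2,D:1);")
  x <- c(A = 1, B = 2, C = 4, D = 0)
  expect_warning(pc <- pic_contrasts(tr, x), "polytomies")
  expect_equal(nrow(pc), 3)
  # K needs no resolution: V is the same before and after
  k_poly <- blomberg_k(tr, x)
  k_res <- blomberg_k(ape::multi2di(tr, random = FALSE), x)
  expect_equal(k_poly, k_res, tolerance = 1e-12)
})
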