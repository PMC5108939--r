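# Precompile a postorder pruning engine for a (resolved) bifurcating tree.
# Returns list(tree, fn) where fn(x) takes tip values ordered as
# tree$tip.label and returns data.frame(contrast, expected_var).
.pic_engine <- function(tree) {
  validate_phylogeny(tree)
  if (!ape::is.binary.phylo(tree)) {
    warning("tree has polytomies; resolved arbitrarily with zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  elen <- tree$edge.length
  nt <- length(tree$tip.label)
  ntot <- nt + tree$Nnode
  fn <- function(x) {
    val <- c(x, rep(NA_real_, tree$Nnode))
    v_extra <- numeric(ntot)
    first_child_row <- integer(ntot)
    contrast <- evar <- numeric(tree$Nnode)
    ci <- 0L
    for (r in seq_len(nrow(edge))) {
      p <- edge[r, 1L]
      if (first_child_row[p] == 0L) {
        first_child_row[p] <- r
      } else {
        r1 <- first_child_row[p]
        c1 <- edge[r1, 2L]; c2 <- edge[r, 2L]
        v1 <- elen[r1] + v_extra[c1]
        v2 <- elen[r] + v_extra[c2]
        if (v1 + v2 <= 0) {
          stop("zero branch-length sum at an internal node; ",
               "contrast cannot be standardized")
        }
        ci <- ci + 1L
        contrast[ci] <- (val[c1] - val[c2]) / sqrt(v1 + v2)
        evar[ci] <- v1 + v2
        val[p] <- (val[c1] / v1 + val[c2] / v2) / (1 / v1 + 1 / v2)
        v_extra[p] <- v1 * v2 / (v1 + v2)
      }
    }
    data.frame(contrast = contrast[seq_len(ci)],
               expected_var = evar[seq_len(ci)])
  }
  list(tree = tree, fn = fn)
}

# Match a named trait vector to the tree's tips, erroring on gaps.
.match_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label)) {
      stop("unnamed trait vector must have one value per tip")
    }
    names(trait) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) {
    stop("trait values missing for tips: ", paste(missing, collapse = ", "))
  }
  if (anyNA(trait)) stop("trait contains NA values")
  trait[tree$tip.label]
}

#' Phylogenetically independent contrasts (Felsenstein pruning)
#'
#' At each internal node the contrast is `(x_left - x_right) /
#' sqrt(v_left + v_right)` where the `v` are child branch lengths, each
#' lengthened by the pruning correction `v1 v2 / (v1 + v2)` accumulated below;
#' the ancestral value is the `1/v`-weighted average of the children. A
#' bifurcating n-tip tree yields exactly n - 1 contrasts; polytomies are
#' resolved arbitrarily with zero-length branches (with a warning).
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param trait Named numeric vector of species values covering every tip.
#' @return data.frame with one row per internal node: `contrast`
#'   (standardized) and `expected_var` (the branch-length sum it was divided
#'   by).
#' @export
pic_contrasts <- function(tree, trait) {
  eng <- .pic_engine(tree)
  x <- .match_trait(eng$tree, trait)
  eng$fn(as.numeric(x))
}

#' Blomberg's K phylogenetic-signal statistic
#'
#' `K` is the ratio of mean squared errors `MSE0/MSE` — trait deviations from
#' the phylogenetically (GLS-)corrected mean, over deviations standardized by
#' the phylogenetic covariance matrix `V` — divided by its expectation under
#' Brownian motion, `(tr(V) - n / sum(V^-1)) / (n - 1)`. `K = 1` is the
#' Brownian expectation (exactly 1 on a star phylogeny for any non-constant
#' trait); `K < 1` means relatives are more divergent than Brownian motion
#' predicts, `K > 1` more similar.
#'
#' @inheritParams pic_contrasts
#' @return Scalar `K`.
#' @export
blomberg_k <- function(tree, trait) {
  validate_phylogeny(tree)
  x <- as.numeric(.match_trait(tree, trait))
  n <- length(x)
  if (n < 3) warning("Blomberg's K with fewer than 3 taxa is uninformative")
  V <- ape::vcv(tree)
  Vinv <- tryCatch(solve(V), error = function(e) {
    stop("phylogenetic covariance matrix is singular ",
         "(duplicate zero-length tips?)")
  })
  one <- rep(1, n)
  sum_vinv <- sum(Vinv)
  a_hat <- sum(Vinv %*% x) / sum_vinv
  dev <- x - a_hat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- drop(t(dev) %*% Vinv %*% dev) / (n - 1)
  expected <- (sum(diag(V)) - n / sum_vinv) / (n - 1)
  (mse0 / mse) / expected
}

#' Tip-shuffle significance of phylogenetic signal
#'
#' The observed statistic is the variance of the standardized independent
#' contrasts (optionally their mean square). Each shuffle permutes the
#' assignment of trait values to tips — destroying any association between
#' trait and phylogenetic position — and recomputes the statistic. Signal
#' means contrasts are *smaller* than on a shuffled tree, so
#' `p = (1 + #\{null <= observed\}) / (1 + n_shuffles)` (one-tailed; the
#' add-one correction keeps p > 0, making 1/(1+n) the attainable floor).
#'
#' @inheritParams pic_contrasts
#' @param n_shuffles Number of tip shuffles (default 1000).
#' @param stat `"variance"` (default) or `"meansq"` of the contrasts.
#' @param seed Optional integer seed.
#' @return Object of class `signal_result`: `n_taxa`, `K`, `observed`
#'   (contrast variance), `null` (vector of shuffled statistics), `p`,
#'   `stat`, `degenerate` (constant trait).
#' @export
tip_shuffle_p <- function(tree, trait, n_shuffles = 1000,
                          stat = c("variance", "meansq"), seed = NULL) {
  stat <- match.arg(stat)
  if (!is.null(seed)) set.seed(seed)
  eng <- .pic_engine(tree)
  x <- as.numeric(.match_trait(eng$tree, trait))
  statfun <- if (stat == "variance") {
    function(cs) var(cs)
  } else {
    function(cs) mean(cs^2)
  }
  obs <- statfun(eng$fn(x)$contrast)
  null <- vapply(seq_len(n_shuffles),
                 function(i) statfun(eng$fn(sample(x))$contrast), 0)
  degenerate <- var(x) == 0
  p <- if (degenerate) 1 else (1 + sum(null <= obs)) / (1 + n_shuffles)
  structure(list(
    n_taxa = length(x),
    K = blomberg_k(eng$tree, setNames(x, eng$tree$tip.label)),
    observed = obs, null = null, p = p, stat = stat,
    n_shuffles = n_shuffles, degenerate = degenerate
  ), class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat("Phylogenetic signal (", x$n_taxa, " taxa)\n", sep = "")
  cat(sprintf("  Blomberg's K: %.4f\n", x$K))
  cat(sprintf("  contrast %s: %.5g; tip-shuffle p (%d shuffles): %s%.4g\n",
              x$stat, x$observed, x$n_shuffles,
              if (x$p <= 1 / (1 + x$n_shuffles)) "<= " else "", x$p))
  if (x$degenerate) cat("  note: constant trait, p degenerate\n")
  invisible(x)
}
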