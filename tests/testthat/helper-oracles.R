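# Independent oracles, deliberately naive, used to check the package's
# implementations on small inputs.

# DO index by direct counting over sites.
brute_do <- function(m, i, j) {
  n <- nrow(m)
  pi <- sum(m[, i]) / n
  pj <- sum(m[, j]) / n
  pij <- sum(m[, i] == 1 & m[, j] == 1) / n
  if (pi * pj == 0) return(NA_real_)
  (pij - pi * pj) / (pi * pj)
}

# Tip-to-tip path length by explicit path enumeration through the root.
brute_cophenetic <- function(tree) {
  nt <- length(tree$tip.label)
  parent <- integer(nt + tree$Nnode)
  plen <- numeric(nt + tree$Nnode)
  for (r in seq_len(nrow(tree$edge))) {
    parent[tree$edge[r, 2]] <- tree$edge[r, 1]
    plen[tree$edge[r, 2]] <- tree$edge.length[r]
  }
  path_to_root <- function(node) {
    nodes <- node
    while (parent[node] != 0) {
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(nt - 1)) {
    pa <- path_to_root(a)
    for (b in (a + 1):nt) {
      pb <- path_to_root(b)
      mrca <- intersect(pa, pb)[1]
      up <- pa[seq_len(which(pa == mrca) - 1)]
      down <- pb[seq_len(which(pb == mrca) - 1)]
      d[a, b] <- d[b, a] <- sum(plen[up]) + sum(plen[down])
    }
  }
  d
}

# Exact two-tailed Mann-Whitney p by exhaustive enumeration of all
# assignments of the pooled values to the two groups (tie-free data).
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, `>`))
  u_obs <- u_of(x, y)
  mu <- nx * length(y) / 2
  combos <- combn(length(pooled), nx)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Exact dispersion Z on a small pool: enumerate every possible
# pseudo-community, population mean/sd of the statistic.
exact_dispersion_z <- function(pool, members) {
  stat <- function(sps) {
    pairs <- combn(sps, 2)
    mean(vapply(seq_len(ncol(pairs)), function(k)
      cohens_d(pool[[pairs[1, k]]], pool[[pairs[2, k]]])$d, 0))
  }
  obs <- stat(members)
  combos <- combn(names(pool), length(members))
  stats <- apply(combos, 2, stat)
  mu <- mean(stats)
  sdev <- sqrt(mean((stats - mu)^2))  # population sd: full enumeration
  list(z = (obs - mu) / sdev, obs = obs, null_mean = mu, null_sd = sdev,
       stats = stats)
}

# A balanced bifurcating ultrametric tree of depth `depth` with 2^levels tips.
balanced_tree <- function(levels, depth = 1) {
  nwk <- "t"
  for (i in seq_len(levels)) {
    nwk <- sprintf("(%s:%g,%s:%g)", nwk, depth / levels, nwk, depth / levels)
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  tree$tip.label <- paste0("t", seq_along(tree$tip.label))
  tree
}

# Star phylogeny with n tips, all branch lengths `len`.
star_tree <- function(n, len = 1) {
  nwk <- paste0("(", paste0("t", 1:n, ":", len, collapse = ","), ");")
  ape::read.tree(text = nwk)
}
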