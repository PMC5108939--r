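#' Cophenetic (patristic) distances between tips
#'
#' Sum of branch lengths on the tip-to-tip path, for all pairs among the
#' requested taxa. When `taxa` is a subset of the tips, the tree is pruned to
#' that subset first (pruning does not change tip-to-tip path lengths; it
#' mirrors pruning a regional phylogeny to the community's species).
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param taxa Optional character vector of tip labels; default all tips.
#' @return Symmetric numeric matrix with zero diagonal, rows/columns ordered
#'   as `taxa`.
#' @export
cophenetic_distances <- function(tree, taxa = NULL) {
  validate_phylogeny(tree)
  if (is.null(taxa)) taxa <- tree$tip.label
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in the phylogeny: ", paste(missing, collapse = ", "))
  }
  if (length(taxa) < 2) stop("need >= 2 taxa for pairwise distances")
  if (length(taxa) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, taxa)
  }
  d <- ape::cophenetic.phylo(tree)
  d[taxa, taxa, drop = FALSE]
}

#' Correlate co-occurrence with phylogenetic distance
#'
#' Pearson correlation between `DO_ij` and cophenetic distance over all
#' species pairs with a defined index. A negative correlation means close
#' relatives co-occur more than distant ones (phylogenetic clustering); a
#' positive one means co-occurring species are more distantly related than
#' expected (overdispersion).
#'
#' @param do_stats data.frame from [do_index()].
#' @param dists Cophenetic distance matrix covering all species in
#'   `do_stats`.
#' @return List: `r`, `n_pairs` used, `n_excluded` (undefined DO), `defined`
#'   (FALSE when fewer than 3 usable pairs or either vector has zero
#'   variance).
#' @export
phylo_cooccurrence_correlation <- function(do_stats, dists) {
  missing <- setdiff(unique(c(do_stats$species_i, do_stats$species_j)),
                     rownames(dists))
  if (length(missing)) {
    stop("species missing from distance matrix: ",
         paste(missing, collapse = ", "))
  }
  use <- do_stats[do_stats$defined, , drop = FALSE]
  n_excluded <- sum(!do_stats$defined)
  d <- dists[cbind(use$species_i, use$species_j)]
  if (nrow(use) < 3 || sd(use$do) == 0 || sd(d) == 0) {
    return(list(r = NA_real_, n_pairs = nrow(use), n_excluded = n_excluded,
                defined = FALSE))
  }
  list(r = cor(use$do, d), n_pairs = nrow(use), n_excluded = n_excluded,
       defined = TRUE)
}

#' Independent-swap randomization of a presence-absence matrix
#'
#' Performs `n_swaps` successful 2x2 checkerboard swaps (a `[[1,0],[0,1]]` or
#' `[[0,1],[1,0]]` submatrix replaced by its complement). Every swap conserves
#' both row sums (site richness) and column sums (species occurrence
#' frequency), the defining property of the independent-swap null model. If
#' the matrix contains no checkerboard it is returned unchanged with
#' attribute `no_checkerboard = TRUE` and a warning.
#'
#' @param m Binary site x species matrix.
#' @param n_swaps Number of successful swaps; default `10 * sum(m)`.
#' @param seed Optional integer seed.
#' @return The randomized matrix with attributes `swaps_done` and
#'   `no_checkerboard`.
#' @export
independent_swap <- function(m, n_swaps = NULL, seed = NULL) {
  m <- validate_community_matrix(m)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_swaps)) n_swaps <- 10L * sum(m)
  res <- .swap_kernel(m, as.integer(n_swaps))
  out <- res$matrix
  dimnames(out) <- dimnames(m)
  attr(out, "swaps_done") <- res$done
  attr(out, "no_checkerboard") <- res$no_checkerboard
  if (res$no_checkerboard) {
    warning("matrix contains no 2x2 checkerboard; returned unchanged")
  }
  out
}

#' Phylogenetic structure of co-occurrence against an independent-swap null
#'
#' Computes the observed correlation between the DO co-occurrence index and
#' cophenetic distance (the tree is pruned to the species in the matrix),
#' then rebuilds the correlation on `n_reps` independent-swap randomizations
#' of the observed matrix. Reported significance:
#'
#' * `p_parametric`: two-tailed t-distribution p of the observed r;
#' * `p_lower`: fraction of null correlations <= observed (small when the
#'   observed correlation is unusually negative, i.e. phylogenetic
#'   clustering; equals 1 when the observed r exceeds every null r);
#' * `p_upper`: fraction of null correlations >= observed (overdispersion
#'   tail);
#' * `p_two_tailed`: `min(1, 2 * min(p_lower, p_upper))`.
#'
#' No add-one correction is applied, so 0 and 1 are attainable.
#'
#' @param m Binary site x species matrix (column names = species).
#' @param tree Phylogeny containing at least those species.
#' @param n_reps Number of null replicates (default 999).
#' @param n_swaps Successful swaps per replicate; default `10 * sum(m)`.
#' @param seed Optional integer seed.
#' @return Object of class `phylostructure_result`: list with `r`,
#'   `p_parametric`, `null_r`, `p_lower`, `p_upper`, `p_two_tailed`,
#'   `n_pairs`, `n_null_dropped` (replicates with undefined r), `n_reps`,
#'   `n_swaps`.
#' @export
randomization_test <- function(m, tree, n_reps = 999, n_swaps = NULL,
                               seed = NULL) {
  m <- validate_community_matrix(m)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_swaps)) n_swaps <- 10L * sum(m)
  species <- colnames(m)
  dists <- cophenetic_distances(tree, species)
  obs <- phylo_cooccurrence_correlation(do_index(m), dists)
  if (!obs$defined) {
    stop("observed correlation undefined (fewer than 3 usable pairs ",
         "or zero variance)")
  }

  null_r <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    res <- .swap_kernel(m, as.integer(n_swaps))
    rm_ <- res$matrix
    dimnames(rm_) <- dimnames(m)
    nr <- phylo_cooccurrence_correlation(do_index(rm_), dists)
    if (nr$defined) null_r[i] <- nr$r
  }
  dropped <- sum(is.na(null_r))
  null_r <- null_r[!is.na(null_r)]
  if (!length(null_r)) stop("all null replicates had undefined correlations")

  np <- obs$n_pairs
  tstat <- obs$r * sqrt((np - 2) / max(1 - obs$r^2, .Machine$double.eps))
  p_par <- 2 * pt(-abs(tstat), df = np - 2)
  p_lower <- mean(null_r <= obs$r)
  p_upper <- mean(null_r >= obs$r)
  structure(list(
    r = obs$r, p_parametric = p_par, null_r = null_r,
    p_lower = p_lower, p_upper = p_upper,
    p_two_tailed = min(1, 2 * min(p_lower, p_upper)),
    n_pairs = np, n_null_dropped = dropped,
    n_reps = n_reps, n_swaps = n_swaps
  ), class = "phylostructure_result")
}

#' @export
print.phylostructure_result <- function(x, ...) {
  cat("Phylogenetic structure of co-occurrence (independent-swap null)\n")
  cat(sprintf("  observed r (DO vs cophenetic distance): %.4f over %d pairs\n",
              x$r, x$n_pairs))
  cat(sprintf("  parametric p: %.4f\n", x$p_parametric))
  cat(sprintf("  randomization p (lower / upper / two-tailed): %.4f / %.4f / %.4f\n",
              x$p_lower, x$p_upper, x$p_two_tailed))
  cat(sprintf("  null replicates: %d (%d dropped), %d swaps each\n",
              length(x$null_r), x$n_null_dropped, x$n_swaps))
  invisible(x)
}
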