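#' Log-transform specimen measurements
#'
#' Elementwise logarithm of the seven measurement columns. Logging linearizes
#' allometric scaling between linear size measurements and brings them toward
#' multivariate normality. Changing the base rescales every column by the
#' same factor, so PCA percent-variance is base-invariant.
#'
#' @param traits Trait table (see [read_traits()]).
#' @param base Logarithm base; default natural log.
#' @return The table with measurement columns replaced by their logs.
#' @export
log_transform <- function(traits, base = exp(1)) {
  for (tr in trait_measurement_names()) {
    v <- traits[[tr]]
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop("log undefined: non-positive ", tr, " for specimen(s) ",
           paste(traits$specimen_id[bad], collapse = ", "))
    }
    traits[[tr]] <- log(v, base = base)
  }
  traits
}

#' Covariance PCA of log measurements via singular value decomposition
#'
#' Columns are mean-centred (no scaling to unit variance — the measurements
#' are already on a common log scale) and the centred matrix is decomposed by
#' SVD. Eigenvalue k is `s_k^2 / (n - 1)`, i.e. the variance of the k-th
#' score. Each loading vector is oriented so its largest-magnitude element is
#' positive. Rank-deficient input yields trailing zero eigenvalues, not an
#' error.
#'
#' @param traits Log-transformed trait table.
#' @param vars Measurement columns to ordinate (default the seven linear
#'   measurements).
#' @return Object of class `pca_result`: `loadings` (traits x PCs, orthonormal
#'   columns), `eigenvalues`, `percent_var`, `cumulative_var`, and `scores`
#'   (data.frame: `specimen_id`, `species`, `PC1..PC7`).
#' @export
pca_svd <- function(traits, vars = trait_measurement_names()) {
  x <- as.matrix(traits[vars])
  n <- nrow(x)
  if (n < 2) stop("need >= 2 specimens for PCA")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  loadings <- sweep(sv$v, 2, flip, `*`)
  eig <- sv$d^2 / (n - 1)
  scores <- xc %*% loadings
  pcs <- paste0("PC", seq_along(eig))
  dimnames(loadings) <- list(vars, pcs)
  names(eig) <- pcs
  pct <- 100 * eig / sum(eig)
  sc <- data.frame(specimen_id = traits$specimen_id,
                   species = traits$species, scores,
                   stringsAsFactors = FALSE, row.names = NULL)
  names(sc) <- c("specimen_id", "species", pcs)
  structure(list(loadings = loadings, eigenvalues = eig,
                 percent_var = pct, cumulative_var = cumsum(pct),
                 scores = sc),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Covariance PCA (SVD) of", nrow(x$scores), "specimens\n")
  tab <- rbind(eigenvalue = x$eigenvalues,
               `% variance` = x$percent_var,
               `cumulative %` = x$cumulative_var)
  print(round(tab, 4))
  invisible(x)
}

#' Assign species to morphospace size classes along PC1
#'
#' Clusters species mean PC1 scores into `k` groups by one-dimensional
#' k-means (best of `nstart` restarts) and labels the groups `I < II < III
#' (< ...)` by ascending mean PC1 — an algorithmic stand-in for sorting a
#' PC1/PC2 scatter into small, medium and large size classes by eye.
#'
#' @param scores PCA score data.frame (needs `species` and `PC1`).
#' @param k Number of classes (default 3).
#' @param nstart k-means restarts (default 50).
#' @param seed Optional integer seed (k-means initialization is stochastic).
#' @return data.frame: `species`, `mean_pc1`, `class` (ordered factor);
#'   attribute `boundaries` gives midpoints between adjacent class extremes.
#' @export
assign_morphospace_classes <- function(scores, k = 3, nstart = 50,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  means <- tapply(scores$PC1, scores$species, mean)
  if (length(means) < k) {
    stop("fewer species (", length(means), ") than classes (", k, ")")
  }
  if (length(unique(means)) < k) {
    stop("degenerate clustering: fewer than ", k, " distinct species means")
  }
  km <- kmeans(as.numeric(means), centers = k, nstart = nstart)
  ord <- order(km$centers)
  lab <- as.roman(seq_len(k))
  class_of <- setNames(as.character(lab), as.character(ord))
  cls <- factor(class_of[as.character(km$cluster)],
                levels = as.character(lab), ordered = TRUE)
  out <- data.frame(species = names(means), mean_pc1 = as.numeric(means),
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$mean_pc1), ]
  rownames(out) <- NULL
  # boundary between classes: midpoint of adjacent class extremes
  hi <- tapply(out$mean_pc1, out$class, max)
  lo <- tapply(out$mean_pc1, out$class, min)
  attr(out, "boundaries") <- (hi[-k] + lo[-1]) / 2
  out
}
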