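#' Cohen's d between two samples
#'
#' `d = |mean_x - mean_y| / s_p` with the pooled standard deviation
#' `s_p = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`
#' (sample variances, denominator n - 1). The absolute value is reported.
#' With a zero pooled sd, equal means give `d = 0` and unequal means `Inf`.
#' Pairs where either sample has fewer than 3 values are computable but
#' flagged unreportable (`reportable = FALSE`): their trait comparison is
#' treated as qualitative only.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List: `d`, `s_p`, `n_i`, `n_j`, `reportable`.
#' @export
cohens_d <- function(x, y) {
  ni <- length(x); nj <- length(y)
  if (ni < 2 || nj < 2) stop("need >= 2 values per sample for Cohen's d")
  sp <- sqrt(((ni - 1) * var(x) + (nj - 1) * var(y)) / (ni + nj - 2))
  dm <- abs(mean(x) - mean(y))
  d <- if (sp > 0) dm / sp else if (dm == 0) 0 else Inf
  list(d = d, s_p = sp, n_i = ni, n_j = nj, reportable = ni >= 3 && nj >= 3)
}

#' Pairwise trait-overlap report
#'
#' Computes Cohen's d for every unordered species pair on each requested axis
#' (e.g. PC1 and PC2 scores, or peak frequency).
#'
#' @param scores data.frame with a `species` column and the axis columns.
#' @param axes Character vector of axis column names (default
#'   `c("PC1", "PC2")`).
#' @return data.frame with one row per pair: `species_i`, `species_j`,
#'   `n_i`, `n_j`, one `d_<axis>` column per axis, and `insufficient`
#'   (TRUE when either sample has n < 3; such pairs are qualitative only).
#' @export
overlap_report <- function(scores, axes = c("PC1", "PC2")) {
  stopifnot(all(c("species", axes) %in% names(scores)))
  sp <- sort(unique(scores$species))
  if (length(sp) < 2) stop("need >= 2 species for an overlap report")
  pairs <- combn(sp, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    xi <- scores[scores$species == i, , drop = FALSE]
    xj <- scores[scores$species == j, , drop = FALSE]
    ds <- lapply(axes, function(ax) {
      if (nrow(xi) >= 2 && nrow(xj) >= 2) cohens_d(xi[[ax]], xj[[ax]])$d
      else NA_real_
    })
    names(ds) <- paste0("d_", axes)
    c(list(species_i = i, species_j = j, n_i = nrow(xi), n_j = nrow(xj)),
      ds)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  out$insufficient <- out$n_i < 3 | out$n_j < 3
  out
}

#' Flag overlapping species pairs
#'
#' Two species overlap in trait space when Cohen's d is strictly below the
#' threshold on every supplied axis (so `d = 1.98` overlaps at the default
#' conservative threshold of 2, `d = 2.0` does not). Pairs with insufficient
#' samples (n < 3) get `overlap = NA` — qualitative only, never a numeric
#' verdict.
#'
#' @param report data.frame from [overlap_report()].
#' @param threshold Overlap threshold on d (default 2).
#' @return `report` with an added logical `overlap` column.
#' @export
classify_overlap <- function(report, threshold = 2) {
  dcols <- grep("^d_", names(report), value = TRUE)
  if (!length(dcols)) stop("report has no d_<axis> columns")
  dmat <- as.matrix(report[dcols])
  ok <- rowSums(is.na(dmat)) == 0 & !report$insufficient
  report$overlap <- ifelse(ok, rowSums(dmat < threshold) == length(dcols), NA)
  report
}

# Mean pairwise Cohen's d from precomputed per-species summaries, vectorized
# across null draws. idx: draws x community-size matrix of species indices.
.mean_pairwise_d <- function(idx, mu, v, n) {
  s <- ncol(idx)
  pairs <- combn(s, 2)
  acc <- 0
  for (k in seq_len(ncol(pairs))) {
    a <- idx[, pairs[1, k]]; b <- idx[, pairs[2, k]]
    sp2 <- ((n[a] - 1) * v[a] + (n[b] - 1) * v[b]) / (n[a] + n[b] - 2)
    acc <- acc + abs(mu[a] - mu[b]) / sqrt(sp2)
  }
  acc / ncol(pairs)
}

#' Community trait-dispersion Z-score by randomization
#'
#' The observed statistic is the mean pairwise Cohen's d over all community
#' member pairs (species with fewer than 3 values are excluded from both the
#' community and the pool, keeping observed and null comparable). The null
#' draws `n_draws` pseudo-communities of the same species count from the
#' family-wide pool and recomputes the statistic; `Z = (observed - mean(null))
#' / sd(null)`. The whole null construction is repeated `n_replicates` times
#' and the mean Z reported. The empirical p is the fraction of all null
#' statistics >= observed (overdispersion = large observed dispersion).
#'
#' @param pool Named list: species -> numeric vector of trait values (e.g.
#'   PC1 scores of its specimens, or per-recording mean peak frequencies).
#' @param members Character vector of community member species (must be in
#'   `pool`).
#' @param n_draws Null pseudo-communities per replicate (default 10000).
#' @param n_replicates Independent null rebuilds averaged into the mean Z
#'   (default 100).
#' @param unit `"species"` (default): each null draw samples whole species,
#'   without replacement, each bringing its full specimen value set — the
#'   statistic needs within-species variance and community size is a species
#'   count. `"values"`: each draw builds pseudo-species by sampling individual
#'   values (without replacement, from the pooled values) matching the
#'   observed members' sample sizes.
#' @param seed Optional integer seed.
#' @return Object of class `dispersion_result`: `observed`, `z` (per
#'   replicate), `mean_z`, `p`, `null_mean`, `null_sd` (per replicate),
#'   `n_members`, `n_pool`, `unit`, `degenerate` (TRUE when sd(null) = 0 in
#'   any replicate).
#' @export
dispersion_z <- function(pool, members, n_draws = 10000, n_replicates = 100,
                         unit = c("species", "values"), seed = NULL) {
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  missing <- setdiff(members, names(pool))
  if (length(missing)) {
    stop("community members not in pool: ", paste(missing, collapse = ", "))
  }
  if (length(members) < 2) stop("community must have >= 2 members")

  sizes <- vapply(pool, length, 0L)
  keep <- sizes >= 3
  dropped <- setdiff(members, names(pool)[keep])
  if (length(dropped)) {
    warning("excluding members with n < 3: ", paste(dropped, collapse = ", "))
  }
  pool <- pool[keep]
  members <- intersect(members, names(pool))
  s <- length(members)
  if (s < 2) stop("fewer than 2 members with n >= 3")
  if (length(pool) <= s && unit == "species") {
    stop("pool must be larger than the community for a species-draw null")
  }

  mu <- vapply(pool, mean, 0)
  v <- vapply(pool, var, 0)
  n <- vapply(pool, length, 0L)
  obs <- unname(.mean_pairwise_d(matrix(match(members, names(pool)), nrow = 1),
                                 mu, v, n))

  member_sizes <- n[match(members, names(pool))]
  all_values <- unlist(pool, use.names = FALSE)

  z <- null_mu <- null_sd <- numeric(n_replicates)
  p_count <- 0
  for (r in seq_len(n_replicates)) {
    if (unit == "species") {
      idx <- t(vapply(seq_len(n_draws),
                      function(i) sample.int(length(pool), s), integer(s)))
      stat <- .mean_pairwise_d(idx, mu, v, n)
    } else {
      stat <- vapply(seq_len(n_draws), function(i) {
        vals <- sample(all_values, sum(member_sizes))
        grp <- rep(seq_len(s), member_sizes)
        gm <- tapply(vals, grp, mean); gv <- tapply(vals, grp, var)
        .mean_pairwise_d(matrix(seq_len(s), nrow = 1),
                         gm, gv, member_sizes)
      }, 0)
    }
    null_mu[r] <- mean(stat)
    null_sd[r] <- sd(stat)
    z[r] <- if (null_sd[r] > 0) (obs - null_mu[r]) / null_sd[r] else NA_real_
    p_count <- p_count + sum(stat >= obs)
  }
  structure(list(
    observed = obs, z = z, mean_z = mean(z), p = p_count / (n_draws * n_replicates),
    null_mean = null_mu, null_sd = null_sd,
    n_members = s, n_pool = length(pool), unit = unit,
    degenerate = anyNA(z)
  ), class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Community trait dispersion vs family-pool null (", x$unit,
      " draws)\n", sep = "")
  cat(sprintf("  observed mean pairwise d: %.4f over %d members (pool %d)\n",
              x$observed, x$n_members, x$n_pool))
  cat(sprintf("  mean Z over %d replicates: %.3f   empirical p: %.4f\n",
              length(x$z), x$mean_z, x$p))
  if (x$degenerate) cat("  warning: sd(null) = 0 in some replicate(s)\n")
  invisible(x)
}
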