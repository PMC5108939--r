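#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' Forward-time simulation: starting from two crown lineages, each lineage
#' splits independently at rate `birth` (exponential waiting times, total rate
#' `k * birth` with k extant lineages). Growth stops when `n_species`
#' lineages exist; one further waiting time is drawn so terminal branches are
#' positive, and all tips end at the present (ultrametric by construction).
#'
#' @param n_species Number of tips (>= 2).
#' @param birth Speciation rate per lineage per unit time (default 1).
#' @param seed Optional integer seed.
#' @return An [ape::phylo] tree with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_species, birth = 1, seed = NULL) {
  stopifnot(n_species >= 2, birth > 0)
  if (!is.null(seed)) set.seed(seed)
  # active lineages: id and birth time; splits: id, time, child ids
  act_id <- c(1L, 2L); act_birth <- c(0, 0)
  next_id <- 3L
  split_id <- integer(0); split_time <- numeric(0)
  split_child <- list()
  t <- 0; k <- 2L
  while (k < n_species) {
    t <- t + rexp(1, rate = birth * k)
    i <- sample.int(k, 1)
    split_id <- c(split_id, act_id[i])
    split_time <- c(split_time, t)
    split_child[[length(split_child) + 1L]] <- c(next_id, next_id + 1L)
    act_id <- c(act_id[-i], next_id, next_id + 1L)
    act_birth <- c(act_birth[-i], t, t)
    next_id <- next_id + 2L
    k <- k + 1L
  }
  t_end <- t + rexp(1, rate = birth * n_species)

  # phylo numbering: tips 1..n, root n+1, split j -> n+1+j
  n <- n_species
  tip_no <- setNames(seq_len(n), act_id)                 # lineage id -> tip
  node_no <- setNames(n + 1L + seq_along(split_id), split_id)
  birth_of <- setNames(c(0, 0, rep(split_time, each = 2)),
                       c(1L, 2L, unlist(split_child)))
  parent_of <- setNames(c(n + 1L, n + 1L,
                          rep(n + 1L + seq_along(split_id), each = 2)),
                        c(1L, 2L, unlist(split_child)))
  all_ids <- as.integer(names(parent_of))
  end_time <- ifelse(all_ids %in% split_id,
                     split_time[match(all_ids, split_id)], t_end)
  child_node <- ifelse(all_ids %in% split_id,
                       node_no[as.character(all_ids)],
                       tip_no[as.character(all_ids)])
  edge <- cbind(unname(parent_of), as.integer(child_node))
  tree <- list(edge = edge,
               edge.length = unname(end_time - birth_of[as.character(all_ids)]),
               tip.label = paste0("t", seq_len(n)),
               Nnode = n - 1L)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Number of lineages of a pure-birth process at a time horizon
#'
#' Runs the unconditioned Yule counting process from one lineage for `t_max`
#' time units; the expected count is `exp(birth * t_max)`. Used to check the
#' tree simulator's clock.
#'
#' @param t_max Time horizon.
#' @param birth Speciation rate (default 1).
#' @return Integer lineage count at `t_max`.
#' @export
yule_lineage_count <- function(t_max, birth = 1) {
  k <- 1L; t <- rexp(1, birth)
  while (t <= t_max) {
    k <- k + 1L
    t <- t + rexp(1, birth * k)
  }
  k
}

#' Simulate trait evolution on a tree
#'
#' `"none"`: Brownian motion — root value 0, each branch adds a
#' `Normal(0, sigma2 * branch length)` increment. `"lambda"`: draws from a
#' multivariate normal whose phylogenetic covariance has off-diagonals scaled
#' by `delta` in `[0, 1]` (`delta = 1` is Brownian, `delta = 0` removes all
#' shared history). `"white"`: independent tip values with the same marginal
#' variances as Brownian motion (`sigma2 *` root-to-tip depth) — a zero-signal
#' trait.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length, default 1).
#' @param transform `"none"`, `"lambda"` or `"white"`.
#' @param delta Off-diagonal scaling for `transform = "lambda"`.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1,
                               transform = c("none", "lambda", "white"),
                               delta = 1, seed = NULL) {
  transform <- match.arg(transform)
  validate_phylogeny(tree)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sigma2 >= 0)
  nt <- length(tree$tip.label)

  if (transform == "none") {
    tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
    val <- numeric(nt + tr$Nnode)             # root = 0
    for (r in seq_len(nrow(tr$edge))) {
      p <- tr$edge[r, 1]; ch <- tr$edge[r, 2]
      val[ch] <- val[p] + rnorm(1, 0, sqrt(sigma2 * tr$edge.length[r]))
    }
    return(setNames(val[seq_len(nt)], tr$tip.label))
  }

  V <- ape::vcv(tree)
  if (transform == "lambda") {
    stopifnot(delta >= 0, delta <= 1)
    Vd <- V * delta
    diag(Vd) <- diag(V)
    x <- drop(t(chol(sigma2 * Vd)) %*% rnorm(nt))
    return(setNames(x, colnames(V)))
  }
  setNames(rnorm(nt, 0, sqrt(sigma2 * diag(V))), colnames(V))
}

#' Simulate specimen-level morphometrics around species values
#'
#' Generates the seven log-normal linear measurements per specimen from a
#' one-factor size model: every trait's log measurement equals a
#' trait-specific baseline plus the specimen's size score (the species value
#' plus `Normal(0, within_sd^2)` specimen noise) plus independent
#' `Normal(0, trait_sd^2)` trait noise. With trait noise small relative to
#' the spread of species values, PC1 of the log data recovers the size axis.
#'
#' @param species_values Named numeric vector, species -> size score (log
#'   scale), e.g. from [simulate_bm_traits()].
#' @param counts Specimens per species: a single integer or a vector matching
#'   `species_values`.
#' @param within_sd Within-species sd of the specimen size score (default
#'   0.05).
#' @param trait_sd Sd of independent per-trait noise (default 0.02).
#' @param seed Optional integer seed.
#' @return A trait table (see [read_traits()]): `specimen_id`, `species`, and
#'   the seven measurements in mm (strictly positive by construction).
#' @export
simulate_specimens <- function(species_values, counts = 10, within_sd = 0.05,
                               trait_sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!is.null(names(species_values)), all(counts >= 1))
  if (length(counts) == 1) counts <- rep(counts, length(species_values))
  # baseline log sizes (mm) typical of the seven measurements
  base <- log(c(beak_length = 30, beak_width = 10, beak_depth = 12,
                tail_length = 70, tarsus_length = 28, body_length = 220,
                wing_length = 100))
  rows <- lapply(seq_along(species_values), function(i) {
    sp <- names(species_values)[i]
    ni <- counts[i]
    size <- species_values[i] + rnorm(ni, 0, within_sd)
    logm <- outer(size, base, `+`) +
      matrix(rnorm(ni * 7, 0, trait_sd), ni, 7)
    df <- as.data.frame(exp(logm))
    names(df) <- trait_measurement_names()
    cbind(data.frame(specimen_id = sprintf("%s_%02d", sp, seq_len(ni)),
                     species = sp, stringsAsFactors = FALSE), df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_traits(out)
  out
}

#' Assemble synthetic communities and an occurrence grid
#'
#' Builds `n_communities` communities of `size` species from a trait pool:
#' `"random"` draws uniformly; `"overdispersed"` grows each community
#' greedily, starting from the two most trait-distant species and adding the
#' species maximizing the minimum trait gap to current members;
#' `"clustered"` takes a random focal species plus its nearest trait
#' neighbours. Each community occupies its own block of grid cells; every
#' member leaves an occurrence record in each of the community's
#' `cells_per_community` cells with probability `detection_prob` (and is
#' guaranteed at least one record so the community is observable).
#'
#' @param species_values Named numeric vector of species trait values.
#' @param mode `"random"`, `"clustered"` or `"overdispersed"`.
#' @param size Species per community.
#' @param n_communities Number of communities (default 1).
#' @param detection_prob Per-cell detection probability (default 1).
#' @param cells_per_community Grid cells per community block (default 3).
#' @param cell_size Grid cell size in degrees (default 0.2).
#' @param seed Optional integer seed.
#' @return List: `communities` (list of member vectors), `occurrences`
#'   (data.frame `species`, `lat`, `lon`), `mode`, `cell_size`.
#' @export
assemble_communities <- function(species_values,
                                 mode = c("random", "clustered", "overdispersed"),
                                 size, n_communities = 1, detection_prob = 1,
                                 cells_per_community = 3, cell_size = 0.2,
                                 seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  sp <- names(species_values)
  stopifnot(size >= 2, size <= length(sp),
            detection_prob >= 0, detection_prob <= 1)

  pick <- function() {
    if (mode == "random") {
      sample(sp, size)
    } else if (mode == "clustered") {
      focal <- sample(sp, 1)
      d <- abs(species_values - species_values[focal])
      names(sort(d))[seq_len(size)]
    } else {
      d <- abs(outer(species_values, species_values, `-`))
      far <- which(d == max(d), arr.ind = TRUE)[1, ]
      members <- sp[far]
      while (length(members) < size) {
        rest <- setdiff(sp, members)
        mind <- vapply(rest, function(s)
          min(abs(species_values[s] - species_values[members])), 0)
        members <- c(members, rest[which.max(mind)])
      }
      members
    }
  }

  communities <- lapply(seq_len(n_communities), function(i) pick())
  occ <- list()
  for (ci in seq_len(n_communities)) {
    members <- communities[[ci]]
    # each community gets a disjoint block of cells along the longitude axis
    lat0 <- 0.5 * cell_size
    lon0 <- (ci - 1) * (cells_per_community + 2) * cell_size
    for (cell in seq_len(cells_per_community)) {
      lon <- lon0 + (cell - 0.5) * cell_size
      seen <- runif(length(members)) <= detection_prob
      if (cell == 1) seen[] <- TRUE  # anchor cell: all members recorded
      if (any(seen)) {
        occ[[length(occ) + 1L]] <- data.frame(
          species = members[seen], lat = lat0, lon = lon,
          stringsAsFactors = FALSE)
      }
    }
  }
  occurrences <- do.call(rbind, occ)
  rownames(occurrences) <- NULL
  list(communities = communities, occurrences = occurrences,
       mode = mode, cell_size = cell_size)
}

#' Synthesize a multi-species chorus recording with annotations
#'
#' Each species emits periodic tonal elements (pure sine tones with 5 ms
#' cosine on/off ramps) at its peak frequency. In the guaranteed
#' non-overlapping variant (`non_overlapping = TRUE`, the layout used for
#' chorus statistics) elements are laid out on a round-robin slot grid so no
#' two elements share any time, and each species' effective phrase period is
#' the slot cycle. Otherwise each species follows its own `period_s`
#' independently and elements may overlap.
#'
#' @param chorus_spec data.frame with columns `species`, `peak_hz`,
#'   `period_s`, `element_s`, and optionally `amplitude` (default 0.8).
#' @param sample_rate Sampling rate in Hz (default 22050).
#' @param duration Total recording length in seconds.
#' @param freq_jitter Per-element sd of frequency jitter in Hz (default 0).
#' @param onset_jitter Per-element sd of onset jitter in seconds, truncated so
#'   non-overlap is preserved (default 0).
#' @param non_overlapping Guarantee elements never overlap (default TRUE).
#' @param recording_id Label used in the annotation table.
#' @param seed Optional integer seed.
#' @return List: `waveform`, `sample_rate`, `annotations` (data.frame
#'   `recording_id`, `species`, `onset_s`, `offset_s`, `freq_hz`).
#' @export
simulate_chorus <- function(chorus_spec, sample_rate = 22050, duration = 10,
                            freq_jitter = 0, onset_jitter = 0,
                            non_overlapping = TRUE, recording_id = "synthetic",
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("species", "peak_hz", "period_s", "element_s")
                %in% names(chorus_spec)))
  if (any(chorus_spec$peak_hz >= sample_rate / 2)) {
    stop("peak frequency at or above Nyquist (", sample_rate / 2, " Hz)")
  }
  if (is.null(chorus_spec$amplitude)) chorus_spec$amplitude <- 0.8
  n <- floor(duration * sample_rate)
  empty <- data.frame(recording_id = character(0), species = character(0),
                      onset_s = numeric(0), offset_s = numeric(0),
                      freq_hz = numeric(0), stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(waveform = numeric(0), sample_rate = sample_rate,
                annotations = empty))
  }
  wave <- numeric(n)
  ann <- list()
  ns <- nrow(chorus_spec)

  add_element <- function(sp_row, onset) {
    el <- chorus_spec$element_s[sp_row]
    f <- chorus_spec$peak_hz[sp_row] +
      (if (freq_jitter > 0) rnorm(1, 0, freq_jitter) else 0)
    from <- floor(onset * sample_rate) + 1L
    len <- floor(el * sample_rate)
    if (len < 2 || from + len - 1L > n) return(NULL)
    tt <- seq_len(len) / sample_rate
    tone <- chorus_spec$amplitude[sp_row] * sin(2 * pi * f * tt)
    ramp <- max(2L, min(round(0.005 * sample_rate), len %/% 4L))
    env <- rep(1, len)
    env[seq_len(ramp)] <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
    env[len - ramp + seq_len(ramp)] <- rev(env[seq_len(ramp)])
    wave[from:(from + len - 1L)] <<- wave[from:(from + len - 1L)] + tone * env
    data.frame(recording_id = recording_id,
               species = chorus_spec$species[sp_row],
               onset_s = onset, offset_s = onset + el, freq_hz = f,
               stringsAsFactors = FALSE)
  }

  if (non_overlapping) {
    slot <- max(chorus_spec$element_s) * 1.5
    n_slots <- floor(duration / slot)
    for (k in seq_len(n_slots)) {
      sp_row <- ((k - 1L) %% ns) + 1L
      onset <- (k - 1L) * slot
      if (onset_jitter > 0) {
        margin <- (slot - chorus_spec$element_s[sp_row]) / 2
        onset <- onset + min(margin, abs(rnorm(1, 0, onset_jitter)))
      }
      ann[[length(ann) + 1L]] <- add_element(sp_row, onset)
    }
  } else {
    for (sp_row in seq_len(ns)) {
      onsets <- seq(0, duration, by = chorus_spec$period_s[sp_row])
      if (onset_jitter > 0) {
        onsets <- pmax(0, onsets + rnorm(length(onsets), 0, onset_jitter))
      }
      for (onset in onsets) {
        ann[[length(ann) + 1L]] <- add_element(sp_row, onset)
      }
    }
  }
  ann <- ann[!vapply(ann, is.null, TRUE)]
  annotations <- if (length(ann)) do.call(rbind, ann) else empty
  rownames(annotations) <- NULL
  peak <- max(abs(wave), 1)
  list(waveform = wave / peak, sample_rate = sample_rate,
       annotations = annotations)
}
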