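#' Run the community-divergence pipeline from one configuration
#'
#' Executes the analysis stages in dependency order (simulate first if
#' requested, co-occurrence before phylogenetic structure, morphospace before
#' divergence) from a single nested key-value configuration (YAML file or
#' list). Inputs either come from the `simulate` stage or from files named
#' under `inputs:` (`tree`, `occurrences`, `traits`, `wav`, `annotations`);
#' referenced files are checked before any stage runs. Every stochastic stage
#' records its seed in the report. Thresholds default to the analysis'
#' standard values (overlap d < 2, alpha 0.05, 999 swap replicates, 10000
#' null draws x 100 replicates, 1000 tip shuffles) and are overridable under
#' `thresholds:`.
#'
#' @param config Path to a YAML file or an equivalent nested list. Keys:
#'   `seed` (master seed), `stages` (character vector from `simulate`,
#'   `cooccur`, `phylostructure`, `morphospace`, `divergence`, `acoustics`,
#'   `phylosignal`), `inputs`, `simulate` (generator parameters), and
#'   `thresholds`.
#' @param out_path Optional path for a JSON run report.
#' @return Run report: nested list of per-stage parameters, seeds and
#'   statistics (serializable with jsonlite, re-loadable).
#' @export
run_pipeline <- function(config, out_path = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config has an empty stage list")
  known <- c("simulate", "cooccur", "phylostructure", "morphospace",
             "divergence", "acoustics", "phylosignal")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- known[known %in% stages]  # dependency order

  # pre-flight: every referenced input file must exist before any stage runs
  for (f in unlist(config$inputs)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }

  th <- config$thresholds
  thr <- list(d_overlap = 2, alpha = 0.05, swap_reps = 999,
              null_draws = 10000, z_replicates = 100, shuffles = 1000)
  thr[names(th)] <- th
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  state <- list()
  report <- list(seed = seed, stages = stages, thresholds = thr,
                 results = list())

  if ("simulate" %in% stages) {
    sc <- config$simulate
    p <- list(n_species = 20, birth = 1, sigma2 = 1, transform = "none",
              specimens = 8, within_sd = 0.1, trait_sd = 0.05,
              community_mode = "random", community_size = 5,
              n_communities = 4, detection_prob = 0.9,
              cells_per_community = 4,
              chorus_hz = c(800, 1600, 2400), chorus_elements = 0.2,
              chorus_duration = 12, sample_rate = 22050)
    p[names(sc)] <- sc
    state$tree <- simulate_yule_tree(p$n_species, p$birth, seed = seed)
    state$trait <- simulate_bm_traits(state$tree, p$sigma2,
                                      transform = p$transform,
                                      seed = seed + 1L)
    state$traits <- simulate_specimens(state$trait, counts = p$specimens,
                                       within_sd = p$within_sd,
                                       trait_sd = p$trait_sd,
                                       seed = seed + 2L)
    asm <- assemble_communities(state$trait, mode = p$community_mode,
                                size = p$community_size,
                                n_communities = p$n_communities,
                                detection_prob = p$detection_prob,
                                cells_per_community = p$cells_per_community,
                                seed = seed + 3L)
    state$communities <- asm$communities
    state$occurrences <- asm$occurrences
    spec <- data.frame(species = paste0("chorus_sp", seq_along(p$chorus_hz)),
                       peak_hz = p$chorus_hz,
                       period_s = 1, element_s = p$chorus_elements)
    ch <- simulate_chorus(spec, sample_rate = p$sample_rate,
                          duration = p$chorus_duration, freq_jitter = 5,
                          seed = seed + 4L)
    state$wav <- list(sample_rate = ch$sample_rate, waveform = ch$waveform)
    state$annotations <- ch$annotations
    report$results$simulate <- list(
      parameters = p, seed = seed,
      n_species = length(state$tree$tip.label),
      n_specimens = nrow(state$traits),
      n_occurrences = nrow(state$occurrences),
      n_elements = nrow(state$annotations))
  }

  inp <- config$inputs
  if (!is.null(inp$tree)) state$tree <- read_newick(inp$tree)
  if (!is.null(inp$occurrences)) state$occurrences <- read_occurrences(inp$occurrences)
  if (!is.null(inp$traits)) state$traits <- read_traits(inp$traits)
  if (!is.null(inp$wav)) state$wav <- read_wav(inp$wav)
  if (!is.null(inp$annotations)) state$annotations <- read_annotations(inp$annotations)

  if ("cooccur" %in% stages) {
    if (is.null(state$occurrences)) stop("cooccur stage needs occurrence records")
    cell <- if (is.null(config$cell_size_deg)) 0.2 else config$cell_size_deg
    state$matrix <- grid_occurrences(state$occurrences, cell)
    state$do <- do_index(state$matrix)
    report$results$cooccur <- list(
      cell_size_deg = cell, n_sites = nrow(state$matrix),
      n_species = ncol(state$matrix),
      n_pairs_defined = sum(state$do$defined),
      mean_do = mean(state$do$do[state$do$defined]))
  }

  if ("phylostructure" %in% stages) {
    if (is.null(state$matrix) || is.null(state$tree)) {
      stop("phylostructure stage needs a community matrix and a tree")
    }
    ps <- randomization_test(state$matrix, state$tree,
                             n_reps = thr$swap_reps, seed = seed + 10L)
    report$results$phylostructure <- list(
      seed = seed + 10L, r = ps$r, p_parametric = ps$p_parametric,
      p_lower = ps$p_lower, p_upper = ps$p_upper,
      p_two_tailed = ps$p_two_tailed, n_reps = ps$n_reps)
    state$phylostructure <- ps
  }

  if ("morphospace" %in% stages) {
    if (is.null(state$traits)) stop("morphospace stage needs a trait table")
    pca <- pca_svd(log_transform(state$traits))
    state$pca <- pca
    cls <- tryCatch(
      assign_morphospace_classes(pca$scores, seed = seed + 20L),
      error = function(e) NULL)
    report$results$morphospace <- list(
      seed = seed + 20L,
      percent_var = unname(pca$percent_var),
      cumulative_var = unname(pca$cumulative_var),
      classes = if (!is.null(cls)) {
        setNames(as.character(cls$class), cls$species)
      })
    state$classes <- cls
  }

  if ("divergence" %in% stages) {
    if (is.null(state$pca)) stop("divergence stage needs morphospace scores")
    rep_tab <- classify_overlap(overlap_report(state$pca$scores),
                                threshold = thr$d_overlap)
    pool <- split(state$pca$scores$PC1, state$pca$scores$species)
    disp <- NULL
    if (!is.null(state$communities)) {
      disp <- lapply(state$communities, function(members) {
        dz <- dispersion_z(pool, members, n_draws = thr$null_draws,
                           n_replicates = thr$z_replicates,
                           seed = seed + 30L)
        list(members = members, mean_z = dz$mean_z, p = dz$p)
      })
    }
    report$results$divergence <- list(
      seed = seed + 30L,
      n_pairs = nrow(rep_tab),
      n_overlapping = sum(rep_tab$overlap, na.rm = TRUE),
      n_qualitative = sum(is.na(rep_tab$overlap)),
      dispersion = disp)
    state$overlap <- rep_tab
  }

  if ("acoustics" %in% stages) {
    if (is.null(state$wav) || is.null(state$annotations)) {
      stop("acoustics stage needs a waveform and annotations")
    }
    spectra <- extract_peak_frequencies(state$wav$waveform,
                                        state$wav$sample_rate,
                                        state$annotations, fmin = 0)
    state$spectra <- spectra
    summaries <- summarize_recordings(spectra)
    tests <- lapply(split(spectra, spectra$recording_id), function(s) {
      if (length(unique(s$species)) < 2) return(NULL)
      ct <- compare_chorus(s, alpha = thr$alpha)
      list(recording_id = ct$recording_id, method = ct$method, p = ct$p,
           all_pairs_distinct = all(ct$pairs$significant))
    })
    report$results$acoustics <- list(
      n_elements = nrow(spectra),
      summaries = summaries,
      chorus_tests = tests[!vapply(tests, is.null, TRUE)])
  }

  if ("phylosignal" %in% stages) {
    if (is.null(state$tree)) stop("phylosignal stage needs a tree")
    trait <- if (!is.null(state$pca)) {
      means <- tapply(state$pca$scores$PC1, state$pca$scores$species, mean)
      setNames(as.numeric(means), names(means))
    } else state$trait
    if (is.null(trait)) stop("phylosignal stage needs species trait values")
    trait <- trait[intersect(state$tree$tip.label, names(trait))]
    sig <- tip_shuffle_p(state$tree, trait, n_shuffles = thr$shuffles,
                         seed = seed + 40L)
    report$results$phylosignal <- list(
      seed = seed + 40L, n_taxa = sig$n_taxa, K = sig$K,
      observed_pic_variance = sig$observed, p = sig$p)
    state$signal <- sig
  }

  if (!is.null(out_path)) {
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
  }
  invisible(structure(list(report = report, state = state),
                      class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (seed ", x$report$seed, "): stages ",
      paste(x$report$stages, collapse = " -> "), "\n", sep = "")
  utils::str(x$report$results, max.level = 2, give.attr = FALSE)
  invisible(x)
}
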