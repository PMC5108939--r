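#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system every later stage consumes —
# an ultrametric phylogeny, a Brownian size trait, specimen-level
# morphometrics, occurrence grids for three assembly regimes, and an
# annotated multi-species chorus recording.

suppressPackageStartupMessages(library(barbetdiv))
seed <- 101L
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tree <- simulate_yule_tree(30, birth = 1, seed = seed)
ape::write.tree(tree, file.path(out, "tree.nwk"))

sizes <- simulate_bm_traits(tree, sigma2 = 0.2, seed = seed + 1L)
write.csv(data.frame(species = names(sizes), size = sizes, row.names = NULL),
          file.path(out, "species_sizes.csv"), row.names = FALSE)

traits <- simulate_specimens(sizes, counts = 10, within_sd = 0.1,
                             trait_sd = 0.05, seed = seed + 2L)
write_traits(traits, file.path(out, "traits.csv"))

for (mode in c("random", "clustered", "overdispersed")) {
  asm <- assemble_communities(sizes, mode, size = 6, n_communities = 6,
                              detection_prob = 0.9, seed = seed + 3L)
  write_occurrences(asm$occurrences,
                    file.path(out, paste0("occurrences_", mode, ".csv")))
  writeLines(vapply(asm$communities, paste, "", collapse = ","),
             file.path(out, paste0("communities_", mode, ".txt")))
}

spec <- data.frame(species = c("low", "mid", "high"),
                   peak_hz = c(800, 1600, 2400),
                   period_s = 1, element_s = 0.2)
ch <- simulate_chorus(spec, duration = 15, freq_jitter = 5, seed = seed + 4L)
write_wav(ch$waveform, ch$sample_rate, file.path(out, "chorus.wav"))
write_annotations(ch$annotations[c("recording_id", "species",
                                   "onset_s", "offset_s")],
                  file.path(out, "annotations.csv"))
write.csv(ch$annotations, file.path(out, "annotations_truth.csv"),
          row.names = FALSE)

cat("Simulated study system (seed ", seed, "):\n", sep = "")
cat("  ", length(tree$tip.label), "species;", nrow(traits), "specimens;",
    nrow(ch$annotations), "chorus elements\n")
cat("  fixtures in", out, "\n")
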