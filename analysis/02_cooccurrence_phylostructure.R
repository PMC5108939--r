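#!/usr/bin/env Rscript
# Stage 2: grid occurrences into presence-absence matrices, compute the DO
# co-occurrence index, and test whether co-occurrence tracks phylogenetic
# distance against the independent-swap null, for each assembly regime.

suppressPackageStartupMessages(library(barbetdiv))
seed <- 202L
fx <- "results/fixtures"
tree <- read_newick(file.path(fx, "tree.nwk"))

summary_rows <- list()
for (mode in c("random", "clustered", "overdispersed")) {
  occ <- read_occurrences(file.path(fx, paste0("occurrences_", mode, ".csv")))
  m <- grid_occurrences(occ, cell_size_deg = 0.2)
  do_tab <- do_index(m)
  write.csv(do_tab, sprintf("results/do_index_%s.csv", mode),
            row.names = FALSE)
  res <- randomization_test(m, tree, n_reps = 999, seed = seed)
  summary_rows[[mode]] <- data.frame(
    mode = mode, n_sites = nrow(m), n_species = ncol(m),
    r = res$r, p_parametric = res$p_parametric,
    p_lower = res$p_lower, p_upper = res$p_upper,
    p_two_tailed = res$p_two_tailed)
  cat(sprintf("%-13s r = %+.3f  parametric p = %.3f  swap-null p (lower) = %.3f\n",
              mode, res$r, res$p_parametric, res$p_lower))
}
tab <- do.call(rbind, summary_rows)
write.csv(tab, "results/phylostructure.csv", row.names = FALSE)

cat("\nExpectation: clustered assembly drives r negative (relatives co-occur)\n")
cat("and a small lower-tail p; random assembly shows no structure.\n")
cat("Written: results/phylostructure.csv, results/do_index_<mode>.csv\n")
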