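#!/usr/bin/env Rscript
# Stage 3: log-transform the specimen measurements, ordinate them by
# covariance PCA (SVD), and sort species into three size classes along PC1.

suppressPackageStartupMessages(library(barbetdiv))
traits <- read_traits("results/fixtures/traits.csv")
pca <- pca_svd(log_transform(traits))
print(pca)

write.csv(pca$scores, "results/pca_scores.csv", row.names = FALSE)
write.csv(data.frame(trait = rownames(pca$loadings), pca$loadings),
          "results/pca_loadings.csv", row.names = FALSE)
write.csv(data.frame(component = names(pca$eigenvalues),
                     eigenvalue = pca$eigenvalues,
                     percent_var = pca$percent_var,
                     cumulative = pca$cumulative_var),
          "results/pca_variance.csv", row.names = FALSE)

cls <- assign_morphospace_classes(pca$scores, k = 3, seed = 303L)
write.csv(cls, "results/morphospace_classes.csv", row.names = FALSE)
cat("\nSize classes along PC1 (k-means, k = 3):\n")
print(table(cls$class))
cat("Written: results/pca_*.csv, results/morphospace_classes.csv\n")
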