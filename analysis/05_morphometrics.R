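#!/usr/bin/env Rscript
# Shape analysis of the mandible-system landmark configurations:
# generalized Procrustes alignment, tangent-space PCA, group separation in
# PC1-2, and the linear measurements (mandible index, latch angle).
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

long <- read.delim(file.path(OUT_DIR, "landmarks.csv"), comment.char = "#")
configs <- lapply(split(long, long$specimen), function(d) {
  as.matrix(d[order(d$landmark), c("x", "y", "z")])
})
groups <- vapply(split(long$group, long$specimen), `[`, "", 1)

g <- gpa(configs)
p <- tangent_pca(g)
scores <- data.frame(specimen = names(configs), group = groups,
                     round(p$scores[, 1:4], 6))
write_tsv_with_header(scores, "pca_scores.tsv", "05_morphometrics.R")
pv <- round(100 * p$proportion_variance[1:4], 1)
message("variance explained PC1-4: ", paste0(pv, "%", collapse = ", "))

if (requireNamespace("cluster", quietly = TRUE)) {
  sil <- cluster::silhouette(as.integer(factor(groups)),
                             dist(p$scores[, 1:2]))
  message("ecomorph silhouette on PC1-2: ", round(mean(sil[, 3]), 3))
}

# linear measurements for two specimens digitized from the landmark space:
# mandible index from lengths, latch angle from apical/basal-process points
meas <- data.frame(
  specimen = c("trap_1", "grip_1"),
  mandible_index = c(mandible_index(median_of_range(0.9, 1.1), 1.0),
                     mandible_index(0.35, 1.0)),
  latch_angle = c(latch_angle(c(-0.6, 1.0, 0), c(0, 0.4, 0),
                              c(-0.6, -1.0, 0), c(0, -0.4, 0),
                              anterior = c(1, 0, 0)),
                  NA))
write_tsv_with_header(meas, "linear_measures.tsv", "05_morphometrics.R")
message("trap latch angle: ", round(meas$latch_angle[1], 1), " deg (reflex)")
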