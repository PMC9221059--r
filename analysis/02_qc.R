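#!/usr/bin/env Rscript
# Stage 2 — quality control of the abundance matrix.
#
# Applies the curation rules in their fixed order: drop proteins missing
# in more than 60 samples, remove metadata-flagged samples (none in the
# synthetic study), require complete measurements in the healthy group
# (the contrast anchor), then fill remaining gaps with per-protein
# medians.

library(pcnet)

md <- read_sample_metadata("results/data/metadata.tsv")
m <- read_expression_matrix("results/data/matrix.tsv", metadata = md)
n0 <- nrow(m$values)

m <- filter_pgenes_by_missingness(m, max_missing = 60)
n1 <- nrow(m$values)
flagged <- md$sample_id[md$flagged]
if (length(flagged)) m <- drop_flagged_samples(m, flagged)
m <- require_complete_in_group(m, "healthy")
n2 <- nrow(m$values)
m <- impute_missing(m)

dir.create("results/qc", showWarnings = FALSE)
write_expression_matrix(m, "results/qc/matrix_clean.tsv")
qc <- data.frame(step = c("input", "missingness<=60", "complete_in_healthy",
                          "imputed"),
                 n_proteins = c(n0, n1, n2, nrow(m$values)),
                 n_samples = ncol(m$values))
write.table(qc, "results/qc/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(qc)
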