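#!/usr/bin/env Rscript
# Stage 4 — mutual-information co-expression network.
#
# Tumor samples only (3 healthy samples cannot support co-expression
# estimation). Rank (copula) transform, adaptive-partitioning MI for all
# pairs, permutation-calibrated p-values (1e5 permuted pairs, log-linear
# tail extrapolation), and two edge sets: the significance-thresholded
# network (FWER-style cut p < 0.05/n_pairs at this problem size) and the
# top-1000 highest-MI edges, mirroring the top-fraction selection used
# for large-scale network views.

library(pcnet)

md <- read_sample_metadata("results/data/metadata.tsv")
m <- read_expression_matrix("results/qc/matrix_clean.tsv", metadata = md)
tumors <- samples_in_group(m, "tumor")
tm <- expression_matrix(m$values[, tumors], m$group[tumors])

ranked <- copula_rank_transform(tm, seed = 101)
null <- calibrate_null(ranked, n_perm = 1e5, seed = 102)
print(null)

n_pairs <- choose(nrow(ranked), 2)
p_cut <- 0.05 / n_pairs
net <- infer_network(ranked, null, p_thresh = p_cut)
net_topk <- top_k_edges(net, 1000)

dir.create("results/network", showWarnings = FALSE)
write_edge_list(net, "results/network/edges_full.tsv")
write_edge_list(net_topk, "results/network/edges_top1000.tsv")
write_sif(net_topk, "results/network/network_top1000.sif")

cat(sprintf("MI threshold at p < %.2e: %.3f nats\n", p_cut,
            mi_at_p(null, p_cut)))
cat(sprintf("%d significant edges of %d pairs (%.2f%%); top set: %d edges\n",
            nrow(net$edges), n_pairs, 100 * nrow(net$edges) / n_pairs,
            nrow(net_topk$edges)))

# ground-truth check: edges should connect same-module proteins
truth <- read.delim("results/data/truth.tsv")
mod <- setNames(truth$module, truth$protein)
within <- mod[net$edges$a] == mod[net$edges$b]
cat(sprintf("within-module edges: %d / %d (%.1f%%)\n",
            sum(within), length(within), 100 * mean(within)))
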