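#!/usr/bin/env Rscript
# Step 2: treatment effect on target activity.
#
# Per direction, a negative-binomial GLM (log mean ~ allele + treatment with
# size-factor offsets) tests each target for a caffeine effect; targets are
# called at BH FDR < 10% in either direction. PCA on the sample x allele
# columns checks that the dominant axis of variation is the allele, as
# expected for a biallelic library.

library(mpragxe)

act <- read.delim("results/sim/activity_counts.tsv", check.names = FALSE)
counts <- as.matrix(act[, -1])
rownames(counts) <- act$construct
samples <- read.delim("results/sim/activity_samples.tsv")
stopifnot(all(colnames(counts) == samples$sample_id))

# PCA QC: columns = sample x allele, so the allele axis is visible
fwd <- counts[grepl("\\|fwd$", rownames(counts)), ]
ref <- fwd[grepl("\\|ref\\|", rownames(fwd)), ]
alt <- fwd[grepl("\\|alt\\|", rownames(fwd)), ]
qc <- cbind(ref, alt)
colnames(qc) <- c(paste0(colnames(ref), ":ref"), paste0(colnames(alt), ":alt"))
pc <- pca_qc(qc)
message(sprintf("PCA QC: PC1 explains %.1f%% of variance", 100 * pc$var_explained[1]))
write_tsv_table(data.frame(column = rownames(pc$scores),
                           pc$scores[, 1:3, drop = FALSE]),
                "results/da_pca_scores.tsv")

res <- run_da(counts, samples)
write_tsv_table(res, "results/da_per_direction.tsv")
calls <- da_classify(res, fdr = 0.10)
write_tsv_table(calls, "results/da_target_calls.tsv")

n_up <- sum(calls$direction_of_change == "up", na.rm = TRUE)
n_dn <- sum(calls$direction_of_change == "down", na.rm = TRUE)
message(sprintf(
  "differential activity: %d significant targets (FDR<10%% either direction): %d up, %d down",
  sum(calls$significant), n_up, n_dn))
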