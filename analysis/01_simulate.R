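#!/usr/bin/env Rscript
# Step 1: simulate a desk-scale biallelic MPRA study.
#
# 4,000 targets (200 nt, centered SNP, ~3.8% negative controls), 6 RNA
# replicates per condition (control, caffeine) plus a deeply sequenced DNA
# pool, with 5% shared allelic effects, 1% condition-specific effects, and
# three motifs planted in the sequences - one preferentially (2x) in targets
# carrying a true allelic effect. Writes the library FASTA, the PFMs, the
# ground truth, and the count tables under results/sim/.

library(mpragxe)

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

pfm_from_consensus <- function(cons) {
  chars <- strsplit(cons, "")[[1]]
  m <- matrix(0, 4, length(chars), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(chars, rownames(m)), seq_along(chars))] <- 12
  m
}
motifs <- list(PLANTED = pfm_from_consensus("ACGTACGG"),
               M2 = pfm_from_consensus("GGATCCTA"),
               M3 = pfm_from_consensus("TTGCAAGC"))

cfg <- sim_config(n_targets = 4000, frac_ase = 0.05, frac_case = 0.01,
                  effect_sd = 1, motif_set = motifs, motif_plant_rate = 0.12,
                  motif_ase_multiplier = c(PLANTED = 2, M2 = 1, M3 = 1),
                  da_frac = 0.05, da_lfc_sd = 1, seed = 20240901)

lib <- simulate_library(cfg)
message(sprintf("library: %d targets -> %d oriented allelic constructs",
                nrow(lib$truth), length(lib$sequences)))
message(sprintf("truth: %d negative controls, %d shared ASE, %d conditional ASE",
                sum(lib$truth$is_negative_control), sum(lib$truth$is_ase),
                sum(lib$truth$is_case)))

Biostrings::writeXStringSet(lib$sequences, "results/sim/library.fasta")
write_jaspar_pfm(motifs, "results/sim/motifs.pfm")
write_tsv_table(lib$truth, "results/sim/truth.tsv")

counts <- simulate_allele_counts(lib$truth, cfg)
write_allele_counts(counts, "results/sim/allele_counts.tsv")
message(sprintf("allele counts: %d rows (%d SNP/direction pairs x samples x alleles)",
                nrow(counts), 2 * nrow(lib$truth)))

act <- simulate_activity_counts(lib$truth, cfg)
write_tsv_table(data.frame(construct = rownames(act$counts), act$counts,
                           check.names = FALSE),
                "results/sim/activity_counts.tsv")
write_tsv_table(act$samples, "results/sim/activity_samples.tsv")
message(sprintf("activity matrix: %d constructs x %d RNA samples",
                nrow(act$counts), ncol(act$counts)))
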