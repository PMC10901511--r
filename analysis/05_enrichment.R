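#!/usr/bin/env Rscript
# Step 5: motif and annotation enrichment.
#
# Scans the library for the study PFMs (10-bit threshold, both strands,
# motifs in fewer than 100 targets dropped), then asks whether any motif is
# over-represented among targets with significant ASE via the per-motif test
# of proportions against the any-motif baseline. A Fisher's exact test
# checks enrichment of ASE calls within a (synthetic) open-chromatin
# annotation laid over pseudo-coordinates of the targets.

library(mpragxe)

seqs <- Biostrings::readDNAStringSet("results/sim/library.fasta")
fwd_ref <- seqs[grepl("\\|ref\\|fwd", names(seqs))]
names(fwd_ref) <- sub("\\|.*", "", names(fwd_ref))
motifs <- read_jaspar_pfm("results/sim/motifs.pfm")

hits <- do.call(rbind, lapply(names(motifs), function(id) {
  scan_sequences(pfm_to_pwm(motifs[[id]], motif_id = id), fwd_ref,
                 threshold_bits = 10)
}))
write_tsv_table(hits, "results/motif_hits.tsv")
message(sprintf("motif scan: %d hits over %d motifs", nrow(hits),
                length(unique(hits$motif_id))))

ase <- read.delim("results/ase_results.tsv")
sig_snps <- unique(ase$snp_id[ase$significant])
enr <- motif_enrichment(hits, sig_snps, min_occurrence = 100)
write_tsv_table(enr, "results/motif_enrichment.tsv")
print(as.data.frame(enr))
top <- enr[enr$p < 0.05 & enr$obs_prop > enr$null_prop, ]
message(sprintf("motifs enriched within ASE targets (p<0.05): %s",
                if (nrow(top)) paste(top$motif_id, collapse = ", ") else "none"))

# synthetic open-chromatin annotation on pseudo-coordinates: each target is
# a 200-nt island at 1000 * index on one contig, its SNP at island + 100;
# "open" intervals cover 60% of targets carrying a true regulatory effect
# and 30% of the rest, emulating the clustering of regulatory variants in
# accessible chromatin
truth <- read.delim("results/sim/truth.tsv")
idx <- seq_len(nrow(truth))
variants <- data.frame(chrom = "contig1", pos = 1000L * idx + 100L)
set.seed(20240905)
has_effect <- truth$true_beta_control != 0 | truth$true_beta_caffeine != 0
open <- runif(nrow(truth)) < ifelse(has_effect, 0.6, 0.3)
bed <- data.frame(chrom = "contig1", start = 1000L * idx[open],
                  end = 1000L * idx[open] + 200L)
write_tsv_table(bed, "results/sim/open_chromatin.bed")
in_open <- intersect_variants(variants, bed)
fe <- fisher_enrichment(truth$snp_id %in% sig_snps, in_open)
write_tsv_table(fe, "results/ase_open_chromatin_fisher.tsv")
message(sprintf(
  "ASE vs open chromatin: fold enrichment %.2f, odds ratio %.2f, p = %.3g",
  fe$fold_enrichment, fe$odds_ratio, fe$p))
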