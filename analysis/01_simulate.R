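#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data under the default design --
# 2000 genes, 20 root QC cells, two replicate bisulfite methylomes with
# planted gbM / unmethylated / ambiguous / highly-methylated classes,
# covariates collinear with gbM, and class-specific intron retention.

suppressPackageStartupMessages(library(gbmnoise))

outdir <- "results/run"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = 1)

genes <- simulate_genome(cfg)
write_gff3(genes, file.path(outdir, "annotation.gff3"))

meth <- simulate_methylomes(cfg, genes)
write_cytosine_report(meth$replicates[[1]], file.path(outdir, "methylome_rep1.tsv"))
write_cytosine_report(meth$replicates[[2]], file.path(outdir, "methylome_rep2.tsv"))
write_tsv_table(meth$truth, file.path(outdir, "ground_truth.tsv"))

mat <- simulate_expression(cfg, meth$truth)
write_fpkm_matrix(mat, file.path(outdir, "fpkm.tsv"))
write_tsv_table(simulate_features(cfg, meth$truth), file.path(outdir, "features.tsv"))

reads <- simulate_reads(cfg, genes, mat, meth$truth)
write_bed_reads(reads, file.path(outdir, "reads.bed"))

cat("simulated", length(genes), "genes on Chr1;",
    nrow(meth$replicates[[1]]), "cytosine records per replicate;",
    ncol(mat), "cells;", length(reads), "reads\n")
cat("planted classes:\n")
print(table(meth$truth$class))
cat("outputs under", outdir, "\n")
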