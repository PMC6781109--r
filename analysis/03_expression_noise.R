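#!/usr/bin/env Rscript
# Stage 3: per-gene expression noise and consistency from the single-cell
# FPKM matrix. Genes pass the log2(FPKM + 1) > 1.5 filter; the lowest
# polynomial degree whose F* is decorrelated from the mean (Kendall test)
# supplies the expected variance; F' is the coefficient of variation;
# consistency counts the cells with FPKM > 0.

suppressPackageStartupMessages(library(gbmnoise))

outdir <- "results/run"
mat <- read_fpkm_matrix(file.path(outdir, "fpkm.tsv"))
nt <- noise_table(mat)

write_tsv_table(nt$table, file.path(outdir, "noise.tsv"))
jsonlite::write_json(
  list(degree = nt$model$degree, coefficients = nt$model$coefficients,
       kendall_tau = nt$model$tau, kendall_p = nt$model$tau_p,
       decorrelated = !nt$model$warning),
  file.path(outdir, "variance_model.json"), auto_unbox = TRUE, digits = NA)

cat(nrow(nt$table), "of", nrow(mat), "genes pass the expression filter\n")
print(nt$model)
cat(sprintf("median F* = %.3f, median F' = %.3f, median consistency = %d of %d cells\n",
            median(nt$table$fstar, na.rm = TRUE),
            median(nt$table$fprime), median(nt$table$consistency), ncol(mat)))
rho <- spearman_rho(nt$table$fstar[!is.na(nt$table$fstar)],
                    nt$table$consistency[!is.na(nt$table$fstar)])
cat(sprintf("Spearman rho(F*, consistency) = %.3f (P = %.3g)\n", rho$rho, rho$p))
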