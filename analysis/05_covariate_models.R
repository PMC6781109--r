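#!/usr/bin/env Rscript
# Stage 5: the statistical layer. Marginal gbM-vs-unmethylated contrasts
# (Mann-Whitney, BH-adjusted), then centred/scaled ANCOVA with all-subsets
# BIC model averaging for F*, F', consistency and log intron FPKM, a
# principal-component regression cross-check, and the reverse regression
# asking which features predict gbM.

suppressPackageStartupMessages(library(gbmnoise))

outdir <- "results/run"
noise <- read_tsv_table(file.path(outdir, "noise.tsv"))
calls <- read_tsv_table(file.path(outdir, "methylation_calls.tsv"))
feats <- read_tsv_table(file.path(outdir, "features.tsv"))
introns <- filter_intron_genes(read_tsv_table(file.path(outdir, "intron_counts.tsv")))

cons <- data.frame(gene_id = calls$gene_id, class = calls$consensus)
md <- assemble_model_data(noise, cons, feats)
cat("modelling table:", nrow(md), "consensus gbM/unmethylated genes with complete data\n\n")

tab1 <- group_comparison_table(
  md, c("fstar", "fprime", "consistency", "mu", "gene_length", "lethal",
        "kaks", "module_size", "breadth", "alpha_wgd", "betagamma_wgd",
        "tandem"))
write_tsv_table(tab1, file.path(outdir, "table1_group_comparison.tsv"))
cat("[marginal contrasts, gbM vs unmethylated]\n")
print(tab1, digits = 3)

fits <- list(fstar = noise_model_analysis(md, "fstar"),
             fprime = noise_model_analysis(md, "fprime"),
             consistency = noise_model_analysis(md, "consistency"),
             intron = intron_model_analysis(introns, md))
for (nm in names(fits)) {
  av <- fits[[nm]]$averaged
  cat(sprintf("\n[%s] best model: %s\n", nm,
              if (length(av$best)) paste(av$best, collapse = " + ")
              else "(intercept only)"))
  cat(sprintf("  gbM: importance %.3f, averaged coefficient %.4f%s\n",
              av$importance[["gbM"]], av$coefficients[["gbM"]],
              if ("gbM" %in% av$best) " (in best model)" else ""))
  imp <- data.frame(term = names(av$importance),
                    importance = unname(av$importance),
                    in_best = names(av$importance) %in% av$best)
  write_tsv_table(imp, file.path(outdir, paste0("importance_", nm, ".tsv")))
  bf <- fits[[nm]]$best_fit
  if (!is.null(bf)) {
    tab <- merge(data.frame(term = names(bf$coefficients),
                            coefficient = unname(bf$coefficients)),
                 bf$anova, by = "term", all.x = TRUE)
    write_tsv_table(tab, file.path(outdir, paste0("best_model_", nm, ".tsv")))
  }
}

# PCR cross-check: gbM term with orthogonal components of the other features
for (resp in c("fstar", "consistency")) {
  d <- fits[[resp]]$averaged
  base <- standardize(
    data.frame(y = md[[resp]], gbM = md$gbM, log_len = log(md$gene_length),
               mu = md$mu, breadth = md$breadth, alpha = md$alpha_wgd))
  pf <- pcr_fit(base[, c("log_len", "mu", "breadth", "alpha")],
                base$gbM, base$y)
  cat(sprintf("\n[PCR %s] gbM coefficient %.4f (P = %.3g)\n",
              resp, pf$gbm_coef, pf$gbm_p))
}

# which features predict gbM?
cand <- gbm_prediction_candidates(md, introns)
pred <- predict_gbm_model(standardize(cand), setdiff(names(cand), "gbM"))
cat("\n[gbM prediction] vif-dropped:",
    if (length(pred$dropped)) paste(pred$dropped, collapse = ", ") else "none",
    "\n  best model:", paste(pred$model$best, collapse = " + "), "\n")
write_tsv_table(data.frame(term = names(pred$model$importance),
                           importance = unname(pred$model$importance),
                           in_best = names(pred$model$importance) %in%
                             pred$model$best),
                file.path(outdir, "gbm_prediction_model.tsv"))
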