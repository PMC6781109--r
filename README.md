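# gbmnoise

Does gene-body methylation (gbM) stabilise gene expression? `gbmnoise` is
an R package plus analysis workflow that links gbM to single-cell
expression noise, expression consistency and intron retention in
*Arabidopsis thaliana* root quiescent-centre cells — and, crucially, asks
whether those links are direct or carried by covariates (gene length,
expression breadth, whole-genome-duplication retention, …) that correlate
with gbM. A seeded synthetic-data generator plants a known ground truth
for every stage, so the entire chain of inference is testable end to end
without downloading any external dataset.

## What it computes

* **Methylation classification.** Per gene and context c ∈ {CG, CHG, CHH},
  methylated calls k and total calls n are pooled over the gene body and
  scored by the binomial upper tail P_c = Pr(X ≥ k), X ~ Bin(n, p̄_c),
  against the pooled genomic average p̄_c. Genes with P_CHG < 0.05 or
  P_CHH < 0.05 are *highly methylated non-gbM*; otherwise P_CG < 0.05 →
  *gbM*, P_CG > 0.95 → *unmethylated*, else *ambiguous*. Final labels
  require agreement of two replicate methylomes.
* **Expression noise.** After the log₂(FPKM+1) > 1.5 filter, stochastic
  expression F\* = σ²/σ̂²(μ), where σ̂² is exp of the lowest-degree
  polynomial fit of log σ² on log μ whose F\* is decorrelated from μ
  (Kendall test); transcriptional noise F′ = sd/mean; consistency = number
  of cells with FPKM > 0.
* **Intron retention.** For non-overlapping genes, introns = span −
  (exons ∪ UTRs); reads are counted over intron and exon sets in two
  passes; intron FPKM and total FPKM come from pooled counts.
* **Statistics.** Mann–Whitney contrasts with Benjamini–Hochberg
  adjustment; centred/scaled ANCOVA with greedy log-transform selection;
  all-subsets BIC model averaging (weights ∝ exp(−ΔBIC/2), full-average
  coefficients, importance = summed weights, minimum-BIC best model with
  Type II F tests); vif screening at √vif < 2; principal-component
  regression as a collinearity-proof cross-check.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (seed 1; 2000 genes, 20 cells):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_classify_methylation.R
Rscript analysis/03_expression_noise.R
Rscript analysis/04_intron_retention.R
Rscript analysis/05_covariate_models.R
Rscript analysis/06_report.R
```

Stage 2 prints, for this seed:

```
replicate-consensus classes:
         gbM         none unmethylated
         590          223         1187
recovery of planted gbM: 98.3% (n = 600)
recovery of planted unmethylated: 99.8% (n = 900)
exon-only vs gene-body identical calls: 99.0%
```

i.e. the binomial consensus classifier recovers planted labels almost
perfectly, and classifying from exons only barely changes the calls.
Stage 3 prints:

```
1904 of 2000 genes pass the expression filter
variance_model: degree 1 on 1904 genes; Kendall tau(F*, mu) = 0.0105 (P = 0.494)
Spearman rho(F*, consistency) = -0.557 (P = 6.01e-156)
```

— the selected polynomial decorrelates F\* from the mean (the Kendall test
is non-significant), and noisier genes are detected in fewer cells.
Stage 5 shows the headline contrast:

```
[fstar]       best model: gene_length + kaks + alpha_wgd + breadth
  gbM: importance 0.029, averaged coefficient -0.0005
[consistency] best model: gbM + mu + gene_length + alpha_wgd + breadth
  gbM: importance 1.000, averaged coefficient 0.3482 (in best model)
[intron]      best model: gbM + total_FPKM + gene_length + total_intron_length
  gbM: importance 1.000, averaged coefficient -0.3187 (in best model)
```

Marginally, gbM genes are less noisy (Mann–Whitney on F\*, BH-adjusted
P = 2.4e-23, medians 0.84 vs 1.11) — but after covariate adjustment gbM
drops out of the noise model entirely (importance 0.03), while keeping a
positive direct effect on expression consistency and a negative one on
intron FPKM. That is exactly the planted regime: the generator gives gbM
*no* direct noise effect (the marginal difference is pure covariate
collinearity) but a real consistency effect and lower intron retention.

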