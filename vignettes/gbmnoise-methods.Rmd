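---
title: "Methods: gene-body methylation, single-cell expression noise and intron retention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-body methylation, single-cell expression noise and intron retention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmnoise)
```

## The question

Gene-body methylation (gbM) — CG-context methylation enriched inside a
gene's transcribed region, with CHG/CHH depletion — is conserved over long
evolutionary times in many plants, yet its function is unclear. One family
of hypotheses holds that gbM stabilises transcription: lowering cell-to-cell
expression noise, keeping genes consistently expressed, and reducing
erroneous transcripts such as retained introns. Testing this requires
(i) classifying genes by methylation status from bisulfite sequencing,
(ii) quantifying expression noise and consistency from single-cell RNA-seq,
(iii) quantifying reads mapping to introns, and (iv) statistics that
separate a *direct* gbM effect from associations carried by covariates that
correlate with gbM (gene length, expression breadth, retention from ancient
whole-genome duplications, and so on).

`gbmnoise` implements that full analysis as a reusable, tested pipeline,
together with a seeded synthetic-data generator that plants a known ground
truth for every stage, so the whole chain of inference can be exercised —
and its error rates measured — without any external download.

## Methylation classification

For each gene the per-context (CG, CHG, CHH) methylated call count $k_c$
and total call count $n_c$ are summed over the cytosines inside the gene
body (transcription start to termination, exons and introns; an exon-only
variant is available). Calls on either strand are pooled. The genomic
background $\bar p_c$ is the *pooled* ratio $\sum_g k_{gc} / \sum_g n_{gc}$
— not the mean of per-gene levels, so deeply covered genes weigh more.

Each gene/context is scored by the binomial upper tail
$P_c = \Pr(X \ge k_c),\; X \sim \mathrm{Bin}(n_c, \bar p_c)$, computed
through the survival function (`pbinom(k - 1, n, p, lower.tail = FALSE)`)
so it remains accurate at $n$ in the millions. The decision rule, applied
with raw $\alpha = 0.05$ and no multiple-testing correction:

1. $P_{CHG} < \alpha$ **or** $P_{CHH} < \alpha$ → *highly methylated
   non-gbM* (excluded from gbM/unmethylated contrasts);
2. otherwise $P_{CG} < \alpha$ → *gbM*;
3. otherwise $P_{CG} > 1 - \alpha$ → *unmethylated*;
4. otherwise → *ambiguous*.

A context with no covered cytosine gets $P = 1$: with no evidence it cannot
be "significantly higher" than the average. The upper tail includes the
observed $k$, which makes the two thresholds symmetric. A gene is finally
labelled gbM (or unmethylated) only when **both** replicate methylomes
agree; all other genes carry no consensus label. `concordance_report()`
summarises agreement between two independent classifications of the same
genes as fractions identical / strictly conflicting / intermediate
(ambiguous in the second set).

## Expression noise, F*, F′ and consistency

Genes enter the expression analysis when $\log_2(\mathrm{FPKM}+1) > 1.5$
in at least one cell (base and threshold configurable). Per gene, $\mu$ is
the mean FPKM over all cells (zeros included) and $\sigma^2$ the sample
variance ($n-1$ denominator).

Because variance scales with the mean, raw variance is not a usable noise
measure. *Stochastic gene expression* $F^*$ is the ratio of the observed
variance to the variance expected at the gene's mean, where the expectation
comes from the lowest-degree polynomial regression of $\log \sigma^2$ on
$\log \mu$ that decorrelates the result from the mean: starting at degree
1, the degree is accepted as soon as Kendall's rank correlation between
$F^*(d)$ and $\mu$ is non-significant ($P \ge 0.05$); degrees up to 6 are
tried and a warning flag records the (never observed in our tests) case
where none suffices. Genes with $\sigma^2 = 0$ are excluded from the fit
and carry `NA` F*. By construction the log-scale residuals average zero, so
the geometric mean of $F^*$ over the fitted genes is 1.

*Transcriptional noise* $F'$ is the plain coefficient of variation
(sd/mean), kept as a cross-check that results do not hinge on the
mean-correction. *Expression consistency* is the number of cells with
FPKM strictly above 0 — a detection count in $0..n_\text{cells}$.

## Intron retention

Genes whose spans overlap another gene (either strand) are removed.
Introns are derived as the gene span minus the merged exon and UTR
intervals; `derive_introns()` can write the modified annotation in which
those introns are typed `exon` — the representation feature-counting tools
expect when counting "intronic" reads. Reads are tallied against the
intron set and the exon set in two independent passes (a junction-spanning
read increments both, mirroring two separate mapping/counting runs;
`min_overlap` is configurable). Counts are pooled over cells;
intron FPKM uses the summed intron length, total FPKM the gene length, and
genes pass into the model when $\log_2(\text{total FPKM}+1) > 1.5$,
identically to the expression filter.

## The statistical layer

Marginal gbM-vs-unmethylated differences use two-sided Mann–Whitney tests
(exact for small untied samples) with Benjamini–Hochberg adjustment across
the feature battery; rank correlations use Spearman's $\rho$ and Kendall's
tie-corrected $\tau_b$.

The covariate-adjusted models follow one procedure for every response
($F^*$, $F'$, consistency, $\log(\text{intron FPKM}+1)$):

* **Transform selection.** A single greedy pass over the predictors in
  declared order: a predictor is log-transformed iff that increases the
  $R^2$ of the full additive model ($\log(x+1)$ when zeros are present;
  binary predictors never transformed). When the response is $F^*$ the mean
  expression level is exempt, to avoid re-introducing a mean correlation
  through the transform.
* **Centring/scaling.** All variables — binary indicators included — are
  standardized to mean 0, sd 1.
* **BIC model averaging.** Every subset of the candidate predictors is fit
  by least squares (all-subsets enumeration, capped at 20 predictors;
  computed from pre-accumulated cross-products so $2^p$ fits are cheap).
  Using $\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + (p+1)\ln n$ — a convention
  whose model-independent offset cancels in the $\Delta$BIC that drives
  everything — models are weighted $w_m \propto e^{-\Delta\mathrm{BIC}_m/2}$.
  Reported are full-average coefficients (a predictor absent from a model
  contributes zero), per-predictor importance (the summed weight of models
  containing it), and the minimum-BIC best model, which is refit with
  per-term Type II (drop-one) sums of squares and F tests.
* **Collinearity.** $\mathrm{vif}_j = 1/(1-R_j^2)$; where the procedure
  screens (the gbM-prediction model), predictors violating
  $\sqrt{\mathrm{vif}} < 2$ are dropped worst-first before averaging.
* **PCR cross-check.** Regressing the response on gbM plus the principal
  components of the remaining (standardized) features removes
  multicollinearity by construction; with orthonormal features the gbM term
  is identical to the ANCOVA's.

Genes with any missing feature are dropped listwise before modelling.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, one
planted mechanism per inferential claim. Defaults mirror the study design:
20 cells, two replicate methylomes, ~20× cytosine coverage, 2000 genes
(5000 in the model-layer Monte-Carlo runs).

* **Genome.** 1–12 exons per gene, lognormal exon (mode ≈ 250 bp) and
  intron (≈ 150 bp) lengths, 60 bp UTRs carved from long terminal exons; a
  configurable fraction of genes (default 5%) overlaps its neighbour to
  exercise the non-overlapping-gene filter.
* **Classes and covariates.** A single latent Gaussian axis drives class
  assignment (unmethylated lowest, gbM highest) and a one-factor Gaussian
  copula ties the covariates to it, so binary and continuous features share
  one correlation structure and no covariate pair exceeds the configured
  cap. The loading on gene length is calibrated *empirically by bisection
  on the realised data* so the point-biserial correlation between the gbM
  indicator and log length hits its target (default 0.4) exactly — the
  closed-form thresholded-Gaussian formula is biased for non-Gaussian
  length margins.
* **Methylomes.** Sites are placed uniformly over the gene (so gene-body
  and exon-only summaries see the same rates); methylated counts are
  Binomial(coverage, rate) with per-class, per-context rates: gbM elevated
  in CG only (0.25 vs 0.02), highly methylated genes elevated in CHG/CHH
  too, an ambiguous class near the pooled background.
* **Expression.** Per gene, a true mean (class-specific lognormal; gbM
  intermediate and narrow) and a true variance = cubic trend in log mean ×
  the gene's noise multiplier. Cells drop out with a per-gene probability
  (logit-linear in expression level and planted noise, minus the planted
  gbM consistency effect); the non-zero cells are lognormal with parameters
  **moment-matched so the full zero-inflated mixture has exactly the
  planted mean and variance at any dropout level**. This matters: the
  sample variance then stays an unbiased readout of the planted noise
  multiplier whatever the dropout, so the gbM → consistency channel cannot
  masquerade as a gbM → noise effect — which is precisely the regime the
  study design needs (marginal noise association through covariates only,
  plus a genuine direct consistency effect). When the planted variance is
  unattainable at the gene's dropout level the non-zero CV is floored at
  0.05; such genes are essentially unexpressed and rarely pass the filter.
* **Noise multipliers** are a function of the *observed* covariates (log
  length, breadth, α-WGD retention; default −0.2 each per sd, lognormal
  residual sd 0.25), with a zero direct gbM term by default. Driving the
  multiplier from latent rather than observed covariates would leak a
  spurious direct gbM effect through measurement error — the feature table
  would then be an incomplete proxy for what generates the noise.
* **Trend scale.** The default cubic gives per-cell CVs around 0.6–0.7.
  At 20 cells the sample variance of heavy-tailed data is median-biased
  downward, increasingly so with CV; at CVs near 1 that bias attenuates a
  planted 2× multiplier below what median-F* recovery can resolve. The
  moderate-CV default keeps F* a faithful estimator at the study's cell
  count — a deliberate design requirement, since multiplier recovery is one
  of the generator's contract properties.
* **Reads.** Per-gene read totals are multinomial with weights FPKM × gene
  length (default 25 000 reads × 20 cells); each read lands fully inside an
  intron with the gene's retention fraction (gbM 0.05, others 0.10), else
  an exon, features chosen with probability proportional to placeable
  width.
* **Seeding.** Every stage derives its own RNG stream deterministically
  from the master seed and the stage name, so stages can be rerun
  independently and a fixed seed reproduces every output byte-for-byte.

What the generator does *not* emulate: read-level sequencing error, UMIs,
isoform structure, cell-type heterogeneity, spatially autocorrelated
methylation, or technical batch effects. Passing tests therefore show that
the *inference machinery* recovers planted truth under the assumed
statistical structure — not that real root QC data satisfies that
structure.

## Numerical choices and degenerate inputs

* Binomial tails via the survival function; stable to $n \ge 10^6$.
* The variance trend is fit by QR least squares on raw polynomial powers;
  at the degrees used (≤ 6) and centred predictor ranges this is
  well-conditioned.
* All-subsets averaging solves each subset's normal equations from one
  cross-product matrix; RSS is floored at $10^{-12}$ so a saturated model
  cannot produce $-\infty$ BIC.
* Type II sums of squares are computed as drop-one RSS increases, which
  stays defined (F = ∞, P = 0) when the full model fits exactly.
* Zero-variance columns, rank-deficient designs, $k > n$, probabilities
  outside $[0,1]$, constant vectors in rank tests, empty samples and
  end-before-start reads all raise immediately with descriptive errors;
  uncovered contexts and intron-less genes are representable values
  ($P = 1$, intron FPKM 0), not errors.
* Ties: Kendall is $\tau_b$; Mann–Whitney switches from the exact to the
  tie-corrected normal distribution when ties are present or samples are
  large; Spearman uses mid-ranks with the t approximation.

## Problem sizes

The test suite runs the generator at 2000 genes (classification recovery,
pipeline determinism), 5000 genes × 20 Monte-Carlo seeds (the
marginal-vs-conditional gbM contrast and the intron-retention sign), 400
null simulations at n = 5000 (PCR type-I calibration), and 20 draws of a
planted 3-of-10 active set (BIC selection). These sizes give the Monte-Carlo
estimates comfortable margins around their acceptance thresholds while the
whole suite stays in the minutes range.

## Known limitations

* The gbM/unmethylated contrast inherits any contamination of the
  consensus sets: planted-ambiguous genes whose CG level sits below the
  pooled background are legitimately called unmethylated.
* $F'$ and the gbM-prediction candidate set are affected by dropout's
  shape effects (the CV of a zero-inflated mixture is not moment-matched
  away); only $F^*$ carries the unbiasedness argument above.
* Ordinary least squares on a 0/1 gbM response (the prediction model) is a
  linear-probability model; coefficients are interpretable as association
  strengths, not probabilities.
* The all-subsets enumeration is exponential; beyond 20 candidate
  predictors a different search strategy would be needed.
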