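---
title: "Endotype discovery in synovial-fluid proteomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endotype discovery in synovial-fluid proteomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Osteoarthritis is clinically heterogeneous, and a long-standing hypothesis
is that it hides discrete molecular subgroups — *endotypes* — that could be
targeted separately. Synovial fluid (SF) bathes the joint and is the most
proximal accessible biofluid; aptamer panels (SOMAmer reagents) measure
thousands of proteins in it as positive relative-fluorescence (RFU) values.

The statistical difficulty is that SF proteomes carry a dominant nuisance
axis: cell lysis during sampling releases intracellular proteins, and this
contamination gradient can account for nearly half the variance of the
processed data. A clustering algorithm applied naively will happily cut
that continuum in two and report "endotypes". The pipeline in this package
therefore runs every clustering analysis twice — with and without residual
adjustment for an intracellular protein score (IPS) — and treats a cluster
call that survives only without adjustment as a contamination artefact, not
a discovery.

`sfendotyper` implements that analysis end to end on synthetic cohorts with
known ground truth: data generation, preprocessing, the f(K) cluster
significance test, per-protein association scans with replication logic,
preranked set enrichment, and a simulation-based power tool.

# The synthetic cohort generator

`generate_cohort()` draws log abundance for sample $i$, aptamer $j$ as

$$x_{ij} = \mu_j + \lambda_j c_i + \sum_k \beta_{jk}\, z_{ik}
        + \delta_{j,g(i)} + b_{j} \mathbb{1}[\text{unspun}_i] + \varepsilon_{ij},$$

with $c_i \sim N(0,1)$ the contamination factor, $z_{ik}$ standardised
clinical outcomes (KL grade, WOMAC pain, BMI), $\delta$ optional endotype
shifts, and $\varepsilon_{ij} \sim N(0, \sigma^2)$ (variance inflated for
unspun samples). Reported abundance is $\exp(x_{ij})$, so values are
strictly positive RFU-like numbers.

Key defaults and why:

* **708 + 653 samples.** The Discovery/Replication split sizes of the
  cohort design the analysis assumes.
* **`ips_variance_share = 0.48`.** The contamination factor is calibrated
  so the leading principal component of the standardised log matrix
  carries ~48% of total variance. The per-aptamer contamination share
  $\rho$ solves $0.48\,p = n_{ic}\rho + n_{spill}\rho/4$, capped at 0.97.
* **55% of aptamers flagged intracellular** (`n_intracellular = 1100` of
  2000). Arithmetic forces this: with loadings confined to flagged
  aptamers plus a 5% spillover, a 48% global share is unreachable unless
  the flagged fraction exceeds ~one half. Broad panels do contain large
  intracellular fractions, so this is biologically defensible; it is a
  calibration constraint first.
* **5% spillover loadings** (quarter share) on non-flagged aptamers, so
  the IPS is a good but imperfect proxy of the factor rather than being
  identical to PC1 by construction.
* **Clinical anchors**: age ~ N(64.46, 11.0), BMI ~ N(30.68, 5.92)
  truncated at 15, WOMAC pain ~ N(44.91, 21.08) clamped to 0–100, KL grade
  from a latent proportional-odds model (~76% advanced), blood staining
  1–4 with probabilities (394, 77, 26, 18)/515 — the marginal
  distributions of the target cohort.
* **`noise_sd = 0.5`** on the natural-log scale, a typical inter-sample CV
  for mid-abundance plasma/SF proteins. Endotype separation and clinical
  effect sizes are expressed in units of this residual SD.
* **Designated markers**: one haemoglobin aptamer shifted +0.35 log units
  per blood-staining grade; one adipokine aptamer with a target BMI
  correlation (default 0.5).

What the generator does **not** emulate: plate-level calibration and
hybridisation controls, missing data, heavy-tailed or skewed residuals,
correlated protein modules beyond the single contamination factor, and any
real biological endotype signature. A green test therefore establishes
that the *procedures* behave as specified on data with the assumed
covariance structure — not that real SF cohorts contain or lack endotypes.

# Preprocessing and the transform ledger

Order matters (log before standardisation; batch adjustment before IPS
residualisation), so `AbundanceMatrix` carries a ledger of applied
transforms and each step validates it. The steps:

1. **Natural log** of strictly positive RFU values.
2. **Median normalisation** — subtract the per-sample median, add back the
   grand median (median of the sample medians). This is a deliberately
   simplified stand-in for the platform's normalisation pipeline. Note a
   real side effect it shares with the platform's approach: when a
   dominant factor loads on most aptamers, the per-sample median carries
   part of that factor and normalisation redistributes it onto every
   aptamer, diluting (but not destroying) planted clinical links.
3. **Empirical-Bayes batch adjustment** for spin status: per aptamer,
   standardise against the batch-design fit, estimate per-batch location
   and scale, shrink both toward moment-matched normal/inverse-gamma
   priors across aptamers (the parametric variant; the non-parametric one
   is out of scope), remove, and restore scale. We add one deviation from
   the stock algorithm: each aptamer is re-centred on its pre-adjustment
   mean, making grand-mean preservation exact. A caveat worth knowing:
   with a perfectly homogeneous planted shift the prior is estimated from
   pure noise and shrinkage retains ~2/3 of the noise-level between-batch
   difference; with heterogeneous per-aptamer shifts (the realistic case,
   and what the generator produces) the residual difference is far below
   0.05 log units.
4. **IPS** — the mean of per-aptamer-standardised log abundance over
   intracellular-flagged aptamers. The score's defining property is its
   high correlation with PC1 (r ≈ 0.94 on real data); the mean-of-z form
   is the simplest score with that property and is flagged as an
   approximation of the original (unpublished) construction. Constant
   flagged aptamers are dropped with a warning; all-constant is an error.
5. **IPS residualisation** — per aptamer, OLS residuals on intercept +
   IPS; idempotent, mean-zero output.
6. **Per-protein standardisation** within Discovery / Replication /
   Combined (sample SD, n − 1) — applied for association scans only.

A deliberate design choice, resolving an ambiguity in the source pipeline:
**clustering uses centred but unscaled data** ("unscaled PCA"), while
standardisation is reserved for regression modelling and for the PC1
variance-share calibration. On unscaled data, planted cluster separation
concentrates variance in the separated aptamers and is visible to k-means;
standardising first dilutes a 5-SD separation on 10% of aptamers below the
f(K) threshold. The ledger records which path was taken.

# The clustering decision

* **`pca_reduce`**: eigendecomposition of the centred matrix (computed on
  the smaller of the Gram/covariance sides), retaining the smallest number
  of leading components reaching 80% cumulative variance. Component signs
  are fixed by making each component's largest-magnitude loading positive.
* **`kmeans_scan`**: Lloyd's algorithm with random-point initialisation,
  10 restarts per K, K = 1..9 by default (the scanned range is a
  convention for f(K) plots; it is configurable). $S_K$ is the minimal
  total within-cluster sum of squares; monotone non-increase is a checked
  invariant repaired by extra restarts.
* **`f_of_k`**: $f(1) = 1$, $f(K) = S_K / (a_K S_{K-1})$ with
  $a_2 = 1 - 3/(4N_d)$ and $a_K = a_{K-1} + (1 - a_{K-1})/6$; $f(K) = 1$
  when $S_{K-1} = 0$. $N_d$ is the retained PCA dimension.
* **`decide_clustering`**: clustered iff $\min_{K \ge 2} f(K) < 0.85$
  (the a-priori threshold).
* **`majority_vote_k`**: each index votes for its best K; modal vote wins,
  ties go to the smallest K (parsimony; the tie rule is not specified
  upstream). The default index set is silhouette, Calinski–Harabasz,
  Davies–Bouldin and the f(K) argmin — a configurable stand-in for the
  30-index suite used on the real data. The gap statistic is implemented
  (`indices = c(..., "gap")`) but excluded from the default vote: its
  bootstrap references cost roughly ten times the rest of the vote and
  never changed a decision in our simulations.
* **`embed_2d`**: visualisation only. The default is the deterministic
  projection onto the first two PCs; UMAP is available via the optional
  `uwot` package. The scientific content (the cluster decision) never
  depends on the embedding.

# Association scans, replication, enrichment

Per aptamer, the clinical feature is the dependent variable and the
standardised log abundance the independent one: linear, logistic or
proportional-odds ordinal regression by outcome type, adjusted for age and
sex by default, with optional fixed-effect or random-intercept (linear
outcomes; lme4) cohort adjustment. Effects are therefore per-SD betas or
log odds ratios. Benjamini–Hochberg adjustment is applied within each
analysis (outcome × dataset × stratum). Replication means padj ≤ 0.05 in
both Discovery and Replication with the same effect direction. Logistic
separation is flagged (p set to NA) rather than dropped; models with fewer
than 30 complete cases are refused; covariates that are constant within a
stratum (sex, in sex-stratified runs) are dropped automatically.

Enrichment uses the signed rank metric $-\ln(p) \cdot \mathrm{sign}(\beta)$
(natural log — the base is configurable in effect through the metric's
scale; it cancels from nothing, so it is documented rather than hidden),
duplicate aptamers collapsed to the smallest p per gene. The running sum
increments by $|m|^q/N_R$ on hits (q = 1) and decrements by $1/(N - N_h)$
on misses. The upstream description says "maximum value of the running
sum"; the standard preranked method uses the maximum *absolute* deviation,
signed. The default is the signed maximum deviation for compatibility with
the standard tool, with `mode = "max"` available. Significance comes from
gene-label permutations (the only valid permutation scheme for preranked
input): NES = ES divided by the mean |null ES| of matching sign, p with a
+1 pseudo-count, BH across sets, set-size bounds 10–500 by default.

# Power simulation

`estimate_power()` replays the entire generate → preprocess → cluster
pipeline per replicate and records the f(K) decision. IPS regression is on
by default, matching the primary analysis. Simulated cohorts use 500
aptamers by default — the decision operates in PC space, and beyond a few
hundred aptamers the retained geometry changes little while runtime grows
linearly. At zero separation the detection proportion estimates the
procedure's false-positive rate (≤ ~5% in our runs, comfortably under the
0.10 bound); power rises monotonically in separation, n, and the
informative fraction.

# Numerical choices and degenerate inputs

* Sample SD uses n − 1 everywhere.
* k-means: `iter.max = 100`, empty-cluster starts retried; K may equal n
  (all singleton clusters, $S_n = 0$), enabling the elbow plot's terminal
  point.
* Residualisation guarantees corr(residual, covariate) < 1e-8 and is
  idempotent to 1e-10.
* p = 0 in the rank metric is clamped to the smallest positive double with
  a warning.
* Ties: majority vote → smallest K; ranked-list metric ties → lexicographic
  gene order; duplicate-aptamer padj ties → smaller p, then lexicographic
  aptamer id.
* Seeds: a single global seed is fanned out through a deterministic string
  hash (`substream_seed`) so each stage gets an independent, reproducible
  stream below 2^31.

# Known limitations

* The IPS formula is an idealisation; only its correlation properties are
  validated.
* The generator's single-factor contamination model cannot express
  multiple overlapping technical gradients.
* Random-intercept cohort adjustment is implemented for linear outcomes
  only; binary/ordinal outcomes fall back to fixed effects.
* Interaction models include only the protein-by-modifier term, not
  covariate-by-modifier terms.
* No consensus clustering, Gaussian-mixture alternatives, or bootstrap
  cluster stability; no over-representation enrichment mode; no
  longitudinal outcomes.
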