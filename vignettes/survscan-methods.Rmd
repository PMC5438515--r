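---
title: "Methods: per-variant survival models for imputed genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-variant survival models for imputed genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survscan)
```

`survscan` tests each variant in an imputed genotype file for association
with a right-censored time-to-event outcome. This vignette documents the
statistical models, the conversions applied to imputed genotypes, the
numerical choices in the fitting engines, what the simulation module does
and does not emulate, and the design decisions taken where more than one
reasonable convention exists.

## Dosages, allele frequencies and imputation quality

Imputation produces, per subject $i$ and variant, a probability triple
$(p_{i0}, p_{i1}, p_{i2})$ for carrying 0, 1 or 2 copies of one allele.
Analysing the expected allele count

$$S_i = p_{i1} + 2\,p_{i2} \in [0, 2]$$

under an additive genetic model propagates imputation uncertainty into the
regression instead of forcing a hard call. Triples whose sum falls in
$[0.9, 1)$ or above 1 are renormalised to sum to one (imputation software
emits shortfall for uncertain genotypes; renormalising keeps $S_i$ in
$[0,2]$); a sum below 0.9 marks the subject's genotype as missing at that
variant rather than discarding the variant.

Two conventions had to be reconciled: the dosage is conventionally counted
for the *minor* allele, while the reported effect allele frequency (EAF) is
defined as the frequency of the *most common* allele. `survscan` counts the
empirical minor allele — if the dosage mean over the analysed subjects
exceeds 1 the vector is flipped ($S' = 2 - S$) and the allele labels
swapped; a frequency of exactly 0.5 is left unflipped — and reports
EAF $= 1 -$ MAF. Both allele names appear in every output row, so no
information is lost. The minor allele is determined from the subjects that
actually enter the model (after listwise deletion), so the reported
frequencies and the regression describe the same sample; this also makes
batched scans exactly reproducible, because each variant's analysis depends
only on its own data.

Imputation quality is summarised by the IMPUTE info score. With
$e_i = p_{i1} + 2p_{i2}$, $f_i = p_{i1} + 4p_{i2}$ and
$\theta = \sum_i e_i / 2N$,

$$\mathrm{info} = 1 - \frac{\sum_i (f_i - e_i^2)}{2N\,\theta(1-\theta)},$$

a ratio-of-variances measure that equals 1 when every genotype is certain
(and, by convention, for monomorphic variants) and decreases with
imputation uncertainty. It is reported as computed — slightly negative
values are possible and diagnostic, so the score is not clamped. For
dosage-only VCF records the triple-level variance is unknown and info is
reported as missing.

Subjects with a missing (`NA`) survival time, censoring indicator, any
covariate used in the model, or a missing genotype are removed from that
variant's analysis; unused covariate columns do not cause removals.

## The two analysis models

**Cox proportional hazards.** The hazard is
$h(t \mid x) = h_0(t)\exp(x'\beta)$ with unspecified baseline $h_0$.
`survscan` maximises the Breslow-ties log partial likelihood

$$\ell(\beta) = \sum_k \left[ s_k'\beta - d_k \log\!\!\sum_{j \in R(t_k)}
\exp(x_j'\beta) \right],$$

summing over distinct event times $t_k$ with $d_k$ events, covariate sum
$s_k$ over those events, and risk set $R(t_k)$. Breslow's approximation was
chosen for ties because it is the standard in genome-scale survival tools,
is cheap, and has a well-defined reference implementation to validate
against (`survival::coxph(ties = "breslow")`; the test suite requires
agreement of estimates, standard errors and log likelihoods to $10^{-6}$).
Efron/exact ties, stratification, frailties and time-varying covariates are
out of scope. Per-coefficient inference uses Wald tests
$z = \hat\beta/\mathrm{SE}$ with 95% confidence intervals reported on the
hazard-ratio scale, $\exp(\hat\beta \pm 1.959964\,\mathrm{SE})$ —
confidence intervals are reported for the Cox model only.

**Weibull regression.** The fully parametric alternative uses the
proportional-hazards form of the Weibull model,

$$h(t \mid x) = \gamma t^{\gamma-1} \exp(\alpha + x'\beta),$$

so that $\beta$ are log hazard ratios directly comparable with the Cox
fit. The likelihood is maximised in the unconstrained parameterisation
$(\alpha, \log\gamma, \beta)$; the intercept $\alpha$ and shape $\gamma$
are reported as their own output rows. Because the model is parametric it
remains informative when the data have an accelerated-failure-time (AFT)
structure: the same family is the AFT model with
$\beta_{\mathrm{AFT}} = -\beta_{\mathrm{PH}}/\gamma$, an identity the test
suite checks against `survival::survreg` to $10^{-6}$. Per-coefficient
p-values for regression terms come from Rao score tests: the restricted
model with the tested coefficient at zero is fitted (all other terms,
$\alpha$ and $\log\gamma$ remaining free), the full-model score $U$ and
observed information $I$ are evaluated there, and $U'I^{-1}U$ is referred
to $\chi^2_1$ — equivalent to using the efficient (Schur-complement)
information for the tested block. The intercept and shape rows instead
carry Wald tests ($\gamma$ with a delta-method standard error, testing
$\log\gamma = 0$, i.e. the exponential sub-model), since a score test
against zero is not a meaningful association test for those parameters.
Zero survival times, for which $\log t$ is undefined, are shifted to half
the smallest positive time with a warning; the Cox model is unaffected by
them.

Both families also report the likelihood-ratio test of the overall model,
$2(\ell_{\mathrm{full}} - \ell_{\mathrm{null}})$ clamped at zero, with one
degree of freedom per regression coefficient (the Weibull $\alpha$ and
$\gamma$ appear in both models and contribute none). The Cox null is
$\ell(0)$; the Weibull null is the refitted intercept+shape model.

## Newton–Raphson and numerical choices

Both engines use damped Newton-Raphson: a step that would decrease the
objective is halved up to 10 times; convergence is declared when the
relative change in the objective falls below $10^{-10}$ or the maximum
absolute score below $10^{-8}$, within 30 iterations. These tolerances are
deliberately tight — termination tests on a quadratically convergent
iteration overshoot their threshold, and the package promises agreement
with reference implementations to $10^{-6}$ on estimates, which looser
criteria cannot guarantee. When a halved step no longer changes the
objective to within float resolution, the fit is accepted as converged;
a genuinely non-improving step with a large score, a singular information
matrix, or iteration exhaustion flags the fit as non-converged.

Per-variant failures never abort a scan: a variant with no events, no
complete cases, a monomorphic dosage in the analysed subjects, or a
non-converged or singular fit yields a single output row with `NA`
statistics and a machine-readable reason code in the `note` column.
Starting values are $\beta = 0$ (Cox) and the exponential-model solution
$\alpha_0 = \log(\sum d_i / \sum t_i)$, $\log\gamma = 0$, $\beta = 0$
(Weibull).

The Cox engine computes risk-set sums with cumulative sums over subjects
sorted by descending time, grouped at tied times, so one iteration costs
$O(np^2)$ with no per-risk-set loops. Output files render floats with six
significant digits and p-values in scientific notation; `NA` marks missing
values.

## Input conventions

GEN files carry five metadata columns (SNP id, rs id, position, two
alleles) and three probabilities per subject; the chromosome label comes
from the `-chr` flag. `-lstart`/`-lstop` are **0-based inclusive** line
indices — the upstream convention is ambiguous (a 0-based start is
documented alongside a count-like stop), so the package fixes one
convention, documents it, and tests that any contiguous partition of the
range reproduces the full scan byte for byte. The optional base-pair window
(`-sp`/`-ep`, 1-based inclusive) is applied after line-range selection.
Compression (gzip/zip) is sniffed from magic bytes with extension
fallback. The GEN path streams with memory independent of the number of
variants; the VCF path (via `vcfR`) materialises the file and applies the
same range semantics afterwards, so very large VCFs are better converted
to GEN for batched cluster runs. At VCF sites, genotype evidence is taken
with priority GP > DS > GT; multi-allelic sites are skipped with a warning
because the dosage model is biallelic. Sample files may carry the optional
Oxford type-code row, which is auto-detected rather than required.
Categorical covariates are rejected with instructions to recode as binary
columns — only continuous and 0/1 covariates are supported.

## What the simulator emulates — and what it does not

`sim_scenario()` describes a cohort of $n$ subjects and $m$ independent
biallelic SNPs. Hard genotypes are drawn $\mathrm{Binomial}(2, f)$ per
subject with $f$ uniform over a configurable MAF range (the causal SNP's
MAF is set separately, default 0.3); an `imputation_noise` weight mixes
each one-hot triple with a random normalised triple to emulate imputation
uncertainty, driving the info score below 1. The binary treatment is
assigned exactly 1:1 by random permutation — the balanced design typical of
treatment-response studies, and deterministic in its group sizes. Survival
times come from a Weibull baseline via inverse-transform sampling under
either a proportional-hazards model
($T = \mathrm{scale}\,(-\log U / e^\eta)^{1/\mathrm{shape}}$) or an AFT
model ($\log T = \log \mathrm{scale} - \eta + G/\mathrm{shape}$, $G$
standard minimum-Gumbel), with
$\eta = \beta_{\mathrm{snp}} S + \beta_{\mathrm{trt}} Z +
\beta_{\mathrm{int}} S Z$; the two coincide when
$\beta_{\mathrm{AFT}} = \beta_{\mathrm{PH}}/\mathrm{shape}$, which the test
suite verifies distributionally. Censoring is uniform on $[0, c_{\max}]$
with $c_{\max}$ solved on the simulated event times so the realised
censored fraction approximates the target (default 20%, emulating random
censoring of roughly a fifth of the cohort). Default effect sizes — hazard
ratio 2 per allele at a causal MAF of 0.3 in a cohort of 1000 — make the
causal SNP clearly genome-wide significant, the qualitative outcome the
scan is designed to reproduce.

The genotype, treatment and survival components draw from separate seed
streams derived from the scenario seed. This matters: during development,
sharing one stream between genotypes and treatment induced enough
dependence to inflate the empirical type-I error of downstream tests by
about one percentage point.

Deliberately **not** emulated: linkage disequilibrium between SNPs
(genotypes are independent, whereas real GWAS panels are haplotype-
structured), population structure and relatedness, informative or
covariate-dependent censoring, genotyping batch effects, and non-Weibull
baseline hazards. Passing tests on these fixtures therefore validate the
engine's statistical correctness and calibration — not robustness to
confounding or model misspecification in real cohorts.

## Validation included in the package

The test suite ties every layer to an independent check: hand-derived
micro-identities (the score of the 4-subject worked example, info-score
values for certain and maximally uncertain genotypes, dosage identities);
a brute-force partial-likelihood grid search; agreement with
`survival::coxph` and `survival::survreg` to $10^{-6}$; Weibull parameter
recovery within three standard errors on 50 simulated cohorts of 2000; and
the empirical size of both association tests at nominal 0.05 over 2000
null replicates at the default cohort size of 1000, judged by the exact
binomial interval and a Kolmogorov-Smirnov uniformity check. Replicate
counts were chosen so the whole suite runs in a few minutes on one core
while leaving the binomial interval at roughly $\pm 1$ percentage point.
The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

- Breslow ties only; heavy ties (coarsely discretised times) bias Cox
  estimates toward zero, as with any Breslow-based tool.
- The Weibull score test requires the restricted model to converge; data
  separable in the nuisance covariates yield `NA` rather than a p-value.
- No multiple-testing correction, genomic control or meta-analysis
  output; MAF filtering (e.g. MAF < 0.01) is left to downstream
  processing of the association table, where it is conventionally applied.
- VCF input is not streamed; BGEN and indexed access are unsupported.
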