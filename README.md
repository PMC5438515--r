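# survscan

Genome-wide association scans for **time-to-event outcomes** on imputed
genotype data. `survscan` is aimed at pharmacogenetic studies where the
endpoint is overall survival, time to remission, or the occurrence of an
adverse drug reaction, and where each of many imputed variants must be
tested for association — including SNP-treatment interaction effects —
without loading the whole genotype file into memory.

## What it computes

Imputed genotypes arrive as per-subject probability triples
(p<sub>i0</sub>, p<sub>i1</sub>, p<sub>i2</sub>) of carrying 0/1/2 copies
of an allele. Each variant is converted to an additive **dosage**

> S<sub>i</sub> = p<sub>i1</sub> + 2 p<sub>i2</sub>,

oriented so the effect allele is the empirical minor allele, and annotated
with the effect/minor allele frequencies and the **IMPUTE info** measure of
imputation quality. Per variant, one of two regression models is fitted to
the survival times with the dosage, any covariates, and optional
SNP-covariate interaction terms:

- **Cox proportional hazards** — Breslow-ties log partial likelihood
  maximised by Newton-Raphson; per-coefficient Wald tests with 95%
  hazard-ratio confidence intervals;
- **parametric Weibull regression** — proportional-hazards form
  h(t|x) = γ t<sup>γ−1</sup> exp(α + x′β) maximised by Newton-Raphson in
  (α, log γ, β); per-coefficient Rao score tests, plus intercept and shape
  rows.

Both models also report the likelihood-ratio test of the overall model.
Subjects with missing survival time, censoring indicator, used covariate or
genotype are removed per variant (listwise deletion). Input formats are
Oxford GEN/sample files (plain, gzip or zip) and VCF with GP, DS or GT
fields; output is a tab-delimited association table. Scans stream the GEN
file in user-specified line ranges, which is how a genome-wide run is split
into parallel batches on a cluster.

A simulation module (`sim_scenario()`, `write_fixture()`, …) generates
matched genotype/phenotype fixtures under proportional-hazards or
accelerated-failure-time generative models with a balanced binary treatment
and calibrated random censoring.

## Worked example

```r
library(survscan)

# a simulated cohort: 1000 patients, 5 SNPs, causal SNP 3 with hazard
# ratio 2 per minor allele (MAF 0.3), ~20% random censoring
sc <- sim_scenario(n_subjects = 1000, n_snps = 5, causal_index = 3,
                   causal_maf = 0.3, beta_snp = log(2),
                   censor_fraction = 0.2, seed = 42)
fx <- write_fixture(sc, tempdir())

phen <- read_sample(fx$sample_path, "event_times", "censoring", "treatment")
out <- file.path(tempdir(), "assoc.txt")
run_scan(fx$gen_path, phen,
         model_spec("cox", covariates = "treatment", print_mode = "onlysnp"),
         out, chromosome = "1")
read_assoc(out)[, c("variable", "coef", "HR", "p", "MAF", "info", "n")]
#> # A tibble: 5 × 7
#>   variable     coef    HR        p   MAF  info     n
#>   <chr>       <dbl> <dbl>    <dbl> <dbl> <int> <int>
#> 1 snp00001  0.00915 1.01  8.52e- 1 0.452     1  1000
#> 2 snp00002 -0.0386  0.962 4.39e- 1 0.462     1  1000
#> 3 snp00003  0.663   1.94  1.09e-31 0.306     1  1000
#> 4 snp00004 -0.0564  0.945 2.57e- 1 0.436     1  1000
#> 5 snp00005  0.0454  1.05  3.88e- 1 0.358     1  1000
```

The causal variant is recovered with an estimated hazard ratio of 1.94
(truth: 2) at p = 1.1×10⁻³¹, far beyond genome-wide significance
(5×10⁻⁸); the null variants sit at p ≈ 0.3–0.9. Fits are also available
directly, with broom-style accessors:

```r
g   <- read_gen(fx$gen_path, chromosome = "1")
dos <- compute_dosage(g[3, ])
d   <- align_complete_cases(dos, phen, covariates = "treatment")$data
fit <- fit_cox(d, terms = c("dosage", "treatment"))
tidy(fit)
#>   term      estimate std.error statistic  p.value conf.low conf.high
#> 1 dosage      0.663     0.0566    11.7   1.09e-31    0.552    0.774
#> 2 treatment  -0.0592    0.0709    -0.835 4.04e- 1   -0.198    0.0798
```

## Command line

The installed package ships a thin driver (`exec/survscan`) mirroring the
flag set of the batch workflow:

```sh
survscan -gf=data.gen -sf=data.sample -t=event_times -c=censoring \
         -cov=covariate1,covariate2 -chr=1 -lstart=0 -lstop=10000 \
         -m=cox -p=onlysnp -o=output.txt
```

`-lstart`/`-lstop` are 0-based inclusive line indices into the genotype
file; running disjoint ranges in parallel and concatenating the outputs is
exactly equivalent to one full run. `-m=weibull` selects the Weibull model,
`-int=` adds SNP-covariate interactions, `-sp=`/`-ep=` restrict to a
base-pair window, and `-help` lists everything.

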