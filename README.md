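# quantherit

Quantile-specific narrow-sense heritability from family phenotype data.

## The problem

Family and twin studies usually report a single heritability for a
quantitative trait, which assumes genetic effect sizes are the same
whether an individual sits at the 10th or the 90th percentile of the
trait distribution. For traits such as serum uric acid concentration that
assumption can fail: genetic effects may be *quantile-dependent*, larger
where the trait is high. When that happens, groups selected for
conditions that raise the trait (male sex, obesity, alcohol intake,
disease) show larger genetic effects — a pattern easily mistaken for
gene–environment interaction.

`quantherit` is for quantitative-genetic and epidemiological analysts
with pedigree phenotype data (multi-cohort, repeated exams). It estimates
the heritability *function* across trait percentiles and tests whether it
is flat:

- sex/age adjustment within cohort (sex, age, age², sex×age, sex×age²),
  averaging residuals over exams;
- offspring–parent pairs (one pair per phenotyped parent) and full-sib
  pairs (all k(k−1) ordered pairs per sibship, weight 1/(k−1)), plus the
  spouse correlation r<sub>spouse</sub> from couples sharing offspring;
- exact weighted quantile regression of the dependent relative's adjusted
  value on the other's at each percentile q of a grid (default 5…95),
  with standard errors and the full cross-percentile covariance from a
  joint bootstrap (cluster resampling by default);
- heritability under phenotypic assortative mating,

  h² = 2β<sub>OP</sub>/(1 + r<sub>spouse</sub>)  and
  h² = {(1 + 8 r<sub>spouse</sub> β<sub>FS</sub>)<sup>1/2</sup> − 1}/(2 r<sub>spouse</sub>),

  with fixed-r delta-method SEs;
- orthogonal-polynomial trend tests (linear/quadratic/cubic) of h²(q)
  across percentiles, the degree-1 estimate scaled as change in h² per
  one-percent increment.

A synthetic pedigree generator with a known additive-genetic model,
assortative mating, and a tunable monotone quantile-dependence mechanism
makes every stage verifiable without restricted cohort data.

## Worked example

Simulate 2000 families under a quantile-dependent model and run the whole
pipeline:

```r
library(quantherit)
params <- sim_params(n_families = 2000, gamma = gamma_calibrated, seed = 42)
report <- run_pipeline(pipeline_config(
  sim    = params,
  grid   = quantile_grid(seq(5, 95, 5)),
  n_boot = 200,
  seed   = 42))
print(report)
```

```
<quantherit_report> seed=42, 9034 individuals, 2000 couples (r_spouse=0.1167)

OP analysis: 10068 pairs; overall beta=0.2125 +/- 0.0100, h2=0.3805 +/- 0.0180
 percentile   beta     h2  se_h2
         10 0.1180 0.2114 0.0216
         25 0.1667 0.2986 0.0217
         50 0.1963 0.3516 0.0322
         75 0.2609 0.4673 0.0437
         90 0.3214 0.5755 0.0612
linear trend (h2 per percent): 0.0042 +/- 0.0006, p = 3.02e-12

FS analysis: 10190 pairs; overall beta=0.2177 +/- 0.0097, h2=0.4153 +/- 0.0176
 percentile   beta     h2  se_h2
         10 0.1294 0.2513 0.0240
         25 0.1589 0.3069 0.0343
         50 0.2099 0.4010 0.0365
         75 0.2714 0.5122 0.0418
         90 0.3219 0.6015 0.0657
linear trend (h2 per percent): 0.0044 +/- 0.0006, p = 4.1e-12
```

Reading the output: the overall offspring–parent slope (0.2125) and
spouse correlation (0.1167) give a whole-distribution heritability of
0.38 — but the quantile-specific estimates rise from ≈ 0.21 at the 10th
percentile to ≈ 0.58 at the 90th, and the linear trend test rejects a
flat heritability function decisively on both the offspring–parent and
full-sib designs. Setting `gamma = 0` in `sim_params()` produces a flat
h²(q) and non-significant trends. `run_pipeline(..., out_dir = "out")`
additionally writes per-percentile TSV reports, trend JSON, and a run
manifest (seed, pair/sibship/couple counts).

With no quantile dependence, the classical arithmetic applies directly;
for example, an offspring–parent slope of 0.2235 ± 0.0133 with
r<sub>spouse</sub> = 0.1062 gives

```r
h2_from_op(0.2235, 0.1062)   # 0.4041
h2_se_op(0.0133, 0.1062)     # 0.0240
h2_from_fs(0.2313, 0.1062)   # 0.4419
```

## Package layout

- `R/pedigree.R` — pedigree table container, TSV I/O, total validation
- `R/synthgen.R` — synthetic family generator and quantile-slope oracle
- `R/adjust.R` — within-cohort sex/age adjustment, exam averaging
- `R/pairs.R` — offspring–parent / full-sib pair sets, spouse correlation
- `R/quantreg.R`, `src/qreg.cpp` — exact weighted quantile regression,
  grid fits, joint bootstrap
- `R/herit.R` — heritability transforms, delta SEs, trend tests
- `R/pipeline.R` — end-to-end runner and report bundle
- `vignettes/quantile-heritability.Rmd` — model, assumptions, design
  choices, limitations
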