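---
title: "Methods: joint SNP-methylation analysis of leflunomide response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint SNP-methylation analysis of leflunomide response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Roughly a third of rheumatoid arthritis (RA) patients respond poorly to
leflunomide (LEF), and no routine biomarker predicts who. The *PON1*
promoter carries both a CpG island (cg17330251, 12 measurable CpG sites
in blood) and a functional polymorphism inside it, rs705379 (−108C>T).
The C allele binds the transcription factor Sp1 more strongly and is
associated with *lower* promoter methylation — an allele-specific
methylation (ASM) pattern — and hypomethylation of the promoter is in
turn associated with better response to LEF. `ponlef` implements the
complete analysis that quantifies this joint genetic/epigenetic effect,
together with a synthetic cohort generator so the pipeline can be run
and verified end to end without patient data.

## Outcome definition

Disease activity is the 4-variable, ESR-based DAS28:

$$DAS28 = 0.56\sqrt{TJC28} + 0.28\sqrt{SJC28} + 0.70\ln ESR + 0.014\,VAS$$

with the VAS in millimetres (the 0.014 coefficient is only consistent
with the 0–100 mm scale). Response after six months uses the EULAR
rules: *good* requires an improvement $\Delta = DAS28_0 - DAS28_6 > 1.2$
with endpoint $\le 3.2$; *non-response* is $\Delta \le 0.6$, or
$0.6 < \Delta \le 1.2$ with endpoint $> 5.1$; everything else is
*moderate*. The published criteria overlap at $\Delta = 0.6$ ("$\le
0.6$" and "$0.6 \le \Delta$"); we resolve the boundary as half-open,
$\Delta = 0.6$ being non-response regardless of endpoint, matching the
standard EULAR table. Good and moderate responders are pooled into the
binary `responder` outcome (non-responder coded 0) used by every model.

Patients may supply either raw visit components or precomputed DAS28
values; when both are present the raw components win and discrepancies
above 0.01 are counted in the run report.

## Statistical kernel

* **Pearson chi-squared** with *no* continuity correction anywhere —
  the uncorrected statistic is what the genetic-model tables report.
  Zero margins are an error naming the degenerate row or column.
* **Odds ratios** by the Woolf log method:
  $\exp(\ln OR \mp z_{0.975}\sqrt{1/a+1/b+1/c+1/d})$, with an optional
  Haldane–Anscombe 0.5 correction for zero cells.
* **Logistic regression** by Newton/IRLS written in the package
  (convergence when the largest coefficient change drops below 1e-8,
  at most 100 iterations). Separation is declared when any coefficient
  passes 15 in absolute value during iteration — on these
  moderately-scaled predictors that magnitude (odds ratios beyond
  $e^{15}$) only arises from separation. Wald standard errors come
  from the inverse observed information; all confidence intervals are
  Wald intervals. Base R's `glm` serves as an independent cross-check
  in the test suite, never as the implementation.
* **Nonparametrics**: Spearman correlation uses mid-ranks and the
  large-sample $t$ approximation; Kruskal–Wallis and Mann–Whitney are
  tie-corrected (the latter two delegate to `kruskal.test` /
  `wilcox.test` with `exact = FALSE, correct = FALSE` behind the
  package's argument-checking surface).
* **Hardy–Weinberg**: Pearson goodness of fit against
  $N(\hat p^2, 2\hat p\hat q, \hat q^2)$ on 1 df.
* All p-values are two-sided at $\alpha = 0.05$; no multiple-testing
  correction is applied anywhere, matching the exploratory design.

## Genetic models

Four cross-tabulations of rs705379 against response: codominant
(CC/CT/TT), dominant (CC vs CT+TT), recessive (CC+CT vs TT), and allele
(C vs T, two alleles per subject). The reference level is always CC
(or C). Genotype models get crude Woolf ORs plus age/sex-adjusted
logistic ORs (indicator coding, sex female = 1). The allele model
reports the crude OR only: its rows are alleles, not independent
subjects, so covariate adjustment over doubled records would be
statistically dubious — and the published allele interval is in fact
exactly the crude Woolf computation from the counts.

## Methylation analysis

Each CpG is split at the cohort's 25th/75th percentiles into
low/medium/high. Percentiles use linear interpolation between order
statistics (R's type-7 default), stated explicitly so results are
bit-reproducible; values exactly at a cutoff are *medium* (strict
inequalities for low/high), which keeps the outer groups at no more
than a quarter each under heavy ties. Each CpG's association with
response is reported three ways, because the published per-site
exposure coding is not recoverable: an ordinal protective coding
(high = 0, medium = 1, low = 2) in an age/sex-adjusted logistic fit,
adjusted pairwise contrasts medium-vs-low and high-vs-low, and the
chi-squared test on the 2×3 table. Patient-level average methylation
(the arithmetic mean over the 12 sites) is summarised per genotype as
median (IQR) with a Kruskal–Wallis test, and correlated with
$\Delta DAS28$ by Spearman.

## Composite genetic protective score

Protective codings: methylation high→0, medium→1, low→2 per scored CpG
(default: the nine response-associated sites, `cg17330251_`
2,3,4,6,7,8,9,10,12) and genotype TT→0, CT→1, CC→2; the score is their
sum, an integer in [0, 20]. The score enters the models as its cohort
quartile category coded 1–4 by default — the published analysis states
the score "was further categorized into quartiles" — with the raw sum
available behind `score_coding = "raw"`, because the per-unit
interpretation of the published OR is ambiguous. Model 1 is
`responder ~ score`; Model 2 adds every covariate retained by
univariate screening at Wald $P < 0.2$ (candidates: PCT, MONO, PLT,
SIRI — the blood-count indices NLR/PLR/SII/SIRI are computed from their
defining quotients). Collinearity in Model 2 is assessed by variance
inflation factors with a flag at 5; perfectly collinear designs are
reported via an unbounded VIF and Model 2 is withheld.

## The synthetic cohort generator

The generator encodes the statistical structure the analysis assumes,
and its defaults are the study conditions:

* n = 240; rs705379 genotypes drawn with Hardy–Weinberg probabilities
  at C-allele frequency 0.525 (pooled from the published genotype
  counts 70/112/58).
* ASM is modelled at the patient level: each patient draws a latent
  methylation level from a Beta distribution matched to their
  genotype's published median/IQR — CC 0.229 (0.195–0.287), CT 0.363
  (0.332–0.395), TT 0.531 (0.496–0.557) — and the 12 sites scatter
  around the latent level on the logit scale with small per-site
  offsets (symmetric, sum 0) and noise sd
  $0.25\sqrt{1 - \rho}$ at within-patient correlation $\rho = 0.85$.
  No per-allele haplotype phasing is modelled; the per-genotype
  summaries do not require it. The Beta parameters come from
  numerically inverting the Beta quantile function; the CC and TT
  median/IQR triples are slightly more skewed than any two-parameter
  Beta allows, so those fits are least-squares compromises with
  root-mean-square quantile errors of about 0.005 and 0.002
  respectively (reported by `beta_params_from_median_iqr`), which is
  immaterial at the ±0.02 recovery tolerance used in verification.
* The six-month improvement is
  $\Delta_i = 1.3 - 1.0\,(\bar m_i - \mu_m) + \varepsilon_i$,
  $\varepsilon_i \sim N(0, 1)$, where $\bar m_i$ is average methylation
  and $\mu_m$ its expected value under the genotype mixture. The slope
  −1.0 with residual sd 1.0 sizes the methylation–$\Delta DAS28$
  Spearman correlation near the published −0.13 at n = 240 (the
  generator's median across seeds is about −0.11). Genotype affects
  the outcome only through methylation, the mediation structure the
  ASM hypothesis asserts.
* Baseline DAS28 ~ Normal(5.1, 1.0) truncated to [0.5, 9.0] — active
  disease at treatment start; month-6 DAS28 is baseline minus
  improvement, floored at 0. Raw TJC/SJC/ESR/VAS are back-solved from
  each target DAS28: ESR and VAS are drawn first (ESR's contribution
  capped at 60% of the target), joint counts absorb the remainder, and
  the continuous VAS takes up the integer-rounding residual, so the
  recomputed DAS28 matches the target to within 0.15 except at clamped
  extremes (residuals are recorded on the cohort).
* The published study gives no distributions for demographics,
  baseline severity or hematology; the defaults — age Normal(55, 10²)
  truncated to [18, 90], 80% female (RA is strongly female-biased),
  log-normal blood counts centred at typical adult values (neutrophils
  4, lymphocytes 1.8, monocytes 0.45, platelets 250 ×10⁹/L,
  plateletcrit 0.22%) — are realistic calibration choices documented
  here, not claims about the study population.
* One global seed drives a single RNG stream in a fixed draw order
  (age, sex, genotype, methylation, outcomes, hematology), making
  cohorts bit-identical across runs.

What the generator deliberately does **not** emulate: measurement and
bisulfite-conversion error, longitudinal visits beyond two, population
stratification, or any direct SIRI/hematology effect on response.
Passing calibration tests therefore shows the pipeline recovers the
assumed ASM structure from data that contain it — not that real
cohorts satisfy these assumptions.

## Missing data

The published analysis used multiple imputation below 10% missingness.
This package deliberately defaults to complete-case analysis with a
logged count of dropped rows, plus an optional single median/mode
imputation switch; full multiple imputation is out of scope, and the
simpler policy is reported in the run log so the divergence is visible.

## Numerical and verification choices

Problem sizes in the shipped tests were chosen to make the checks
sharp yet quick: parameter-recovery at n = 5000 (medians within ±0.02
of the configured values), calibration of the methylation–improvement
correlation over 200 cohorts of n = 240, type-I error and
confidence-interval coverage under a null configuration
(genotype-independent methylation, zero methylation effect) over 1000
replicates, and closed-form/brute-force oracles for every statistic
(expected-count chi-squared, pairwise-count Mann–Whitney, rank-formula
Kruskal–Wallis, contingency-table logistic equivalence). The published
genotype-by-response counts are reconstructed as an explicit cohort
(`reconstruct_published_cohort()`) and pushed through the same code path
as any other cohort.

Two published numbers are knowingly not reproduced: the allele-model
chi-squared prints 2.643 but recomputes to 2.634 from its own counts
(whose p = 0.105 matches the recomputed value; likely a digit
transposition), and the adjusted ORs cannot be recomputed without the
unreleased subject-level covariates — they are covered by
direction-recovery simulations instead.

## Known limitations

* The per-CpG exposure coding behind the published per-site ORs
  (≈0.42–0.49) is not recoverable; both the ordinal coding and the
  pairwise contrasts are reported, neither is claimed to match
  numerically.
* The composite-score models are reported for both quartile and raw
  codings; the published per-unit OR (1.313/1.277) is a direction
  target only.
* Separation detection by a coefficient bound is a heuristic; it is
  appropriate for the bounded codings used here but would misfire on
  predictors with tiny numeric scales.
* The generator's hematology block is independent of outcome, so
  Model 2 covariate effects are null by construction in simulated
  cohorts.
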