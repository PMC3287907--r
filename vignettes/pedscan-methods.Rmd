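---
title: "Models and methods behind pedscan"
author: "pedscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pedscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pedscan` maps trait variants in large extended pedigrees by combining
linkage scans, family-based association, and carrier-based screening of
rare variants. This vignette explains the models, the defaults, the
numerical choices, and what the simulation-based validation does and does
not establish.

## Identity by descent and its null moments

All linkage statistics are built on the proportion of alleles a relative
pair shares identical by descent (IBD) at a locus, π_ij ∈ {0, 1/2, 1} for
non-inbred pairs. Its null expectation is twice the kinship coefficient,
E[π_ij] = 2φ_ij, with φ = 1/2^(d+1) for an outbred d-th-degree pair, and
its variance follows from the pair type (1/8 for full siblings;
φ(1 − 4φ) for unilineal pairs). The package works with *known* IBD:
either recorded by the simulator's gene dropping, or supplied by the
user. Estimating IBD from marker genotypes (Lander–Green /
Elston–Stewart, LD-aware emission models) is deliberately out of scope;
at the pedigree sizes targeted here those algorithms are the bottleneck
the package exists to avoid.

The null covariance Cov(π_ij, π_kl) is a function of pedigree structure
only. `pairCovariance()` computes it two ways:

* **enumerate** — exact: every transmission vector of the nonfounders in
  the ancestor closure of the pair members is enumerated (4 choices per
  nonfounder, permitted up to 12 meioses). This is the correctness oracle
  in the tests; it reproduces, e.g., Var(π) = 1/8 for siblings and the
  classical zero covariance between overlapping sibling pairs.
* **montecarlo** — seeded gene dropping with chunked accumulation and
  elementwise Monte-Carlo standard errors, for closures too large to
  enumerate. Cross-family entries are structural zeros.

Scans never form the full pair-covariance matrix for large problems: the
null variance of a weighted pair sum is estimated directly as the
variance of that sum over fresh gene drops (50,000 drops for the NPL
denominator, relative error ≈ 0.6%; 2,000–8,000 for the QT scan, whose
statistic pools tens of thousands of pairs and is far less sensitive).

## NPL scan for the dichotomous trait

For affected relative pairs, linkage means excess sharing:

Z = Σ w_ij (π_ij − 2φ_ij) / sqrt( ΣΣ w_ij w_kl Cov(π_ij, π_kl) ).

Design choices:

* **Pair set.** All within-family affected pairs of degree ≥ 1.
  Parent-offspring pairs are excluded (π ≡ 1/2, no variance). Because age
  is a dominant risk factor for the modelled trait, pairs more than 16
  years apart (default, configurable; `nplAgeSweep()` re-runs the scan
  across thresholds) are dropped as etiologically heterogeneous.
* **Weights.** Distant pairs share little by chance, so shared alleles
  there are more informative about rare variants. The default
  `inverse_sd` weight 1/sqrt(Var π) standardizes each pair's
  contribution; `uniform` and `inverse_expected_sharing` (1/(2φ)) are
  alternatives. Z is invariant to rescaling all weights.
* **One-sided LOD.** LOD = Z²/(2 ln 10) for Z > 0, else 0: affected pairs
  under linkage share more, sharing deficits are reported only through
  negative Z.
* **Per-family decomposition.** Families are independent, so the overall
  numerator (variance) is the sum of per-family numerators (variances);
  per-family Z and LOD are emitted, and a family with no eligible pairs
  contributes exactly 0.

## Score linkage for quantitative traits

The trait is first residualized by ordinary least squares on Age, Smoking
and the first structure component (and, for conditional scans, candidate
SNP dosages). With residuals standardized to unit sample variance, the
per-locus score is

N = Σ_{i<j} r̃_i r̃_j (π_ij − 2φ_ij),  Z = N / sqrt(Var N),

over *all* within-family pairs (parent-offspring included — trait
linkage uses them). Var(N) is the gene-drop variance of N with the
residual cross-products held fixed, i.e. the score test conditions on the
trait. The numerator is computed in O(n) per locus by grouping allele
slots by founder label (pairs sharing a label are exactly the IBD pairs),
which is what makes 128-member families and thousands of loci cheap; the
tests verify it against the explicit pair sum. Z is invariant to affine
transformations of the trait. A trait fully explained by its covariates
yields a flat zero scan rather than an error.

Conditional linkage re-residualizes with the candidate SNPs as additive
covariates and re-scans: a LOD that collapses says the variants account
for the linkage signal. Monomorphic or collinear adjustment columns are
dropped with a warning, reproducing the unadjusted scan.

## Variance-component models

The polygenic model per family is y ~ MVN(Xβ, 2Φσ²_g + Iσ²_e). The
likelihood is profiled over β and total variance and maximized over
h² ∈ [0, 1) (1-D golden-section search, tolerance 1e-8; variance
components nonnegative by construction; the h² = 0 boundary is always
evaluated explicitly, where the likelihood equals the independent-normal
regression likelihood exactly). Each family enters through one
eigendecomposition of its 2Φ block, so no whole-cohort solve occurs. ML
is the default — it keeps likelihood-ratio comparisons and the
variance-explained arithmetic coherent — with REML as an option; at
~700 individuals the two differ by <0.03 in h². Samples without relative
pairs leave σ²_g unidentifiable: flagged, h² reported 0 with a warning.

The bivariate model stacks two traits with genetic covariance 2Φ ⊗ G and
environmental I ⊗ E (G, E 2×2), parameterized by log-variances and
atanh-correlations (|r| capped at 0.995 so degenerate identical-trait
inputs hit a finite boundary), β profiled by GLS inside the BFGS
objective. Fixing rG = rE = 0 decouples it into the two univariate fits,
which the tests assert via the log-likelihoods.

Per-SNP association uses the null polygenic fit once, then scores each
dosage: U = g'V⁻¹(y − Xβ̂), information g'V⁻¹g −
g'V⁻¹X(X'V⁻¹X)⁻¹X'V⁻¹g, U²/I ~ χ²₁, one-step effect U/I. Monomorphic
SNPs are flagged untested.

**Variance explained.** Fitting candidate variants as fixed effects
moves their variance out of σ²_g; the heritability drop is the share of
phenotypic variance they explain. For the subtraction to be coherent the
two heritabilities must share a denominator, so the fit that adjusts
variants contributes σ²_g / (σ²_g + σ²_e + V_SNP), where V_SNP is the
sample variance of the fitted variant effects. Without this, the
"with-variants" heritability is measured against a smaller total and the
drop understates the variants' contribution by roughly a factor of two
at the default architecture.

## Family-based association and screening

* **TDT** counts minor-allele transmissions from heterozygous parents to
  affected offspring in genotyped trios; double-heterozygous parents are
  resolved jointly through the offspring dosage. No reconstruction of
  missing parental genotypes.
* **GDT** contrasts allele counts over all affected–unaffected pairs
  within each family: U_f = Σ (g_aff − g_unaff), T = Σ_f U_f,
  Var = Σ_f U_f² (family-robust), implemented in the unweighted form.
  Covariates enter neither test (they are within-family contrasts).
* **Sandwich logistic regression** fits affection on Age, Smoking and
  candidate dosages by ML and reports cluster-robust standard errors with
  families as clusters (HC0 meat without the cluster small-sample factor,
  so one-individual clusters reduce exactly to the heteroskedasticity-
  robust form). Separation is detected and the offending column named.
* **Carrier screen.** Allele frequencies come from founders only — they
  are the draw from the source population, whereas nonfounders over-count
  whatever segregates in large sibships. At each SNP with founder
  MAF < 0.05 the screen computes the affected:unaffected odds among
  carriers (default flag at odds ≥ 1, ≥ 3 carriers; both configurable; a
  protective-direction screen and a binomial likelihood-ratio score that
  damps tiny carrier groups exist but are off by default). Quantitative
  screening flags carrier groups whose mean covariate-adjusted residual
  shifts by ≥ 1 residual SD. Hits record whether all carriers sit in one
  family — the signature of a private founder variant. LD pruning
  estimates two-locus haplotype frequencies among founders by EM (phase
  is unknown only for double heterozygotes), groups hits at r² ≈ 1,
  keeps the most extreme statistic (ties: lower position), and annotates
  carrier-subset relations.
* **Gene collapsing** codes an individual 1 if it carries any listed rare
  variant in a gene (homozygotes are carriers; two-copy carriers are rare
  enough to treat as heterozygous), and is idempotent.

## Population structure

Classical MDS on founders: dosages standardized by founder allele
frequencies, Euclidean distances, principal coordinates. SNPs below
founder MAF 0.05 are excluded by default — rare variants carry almost no
ancestry information, but their standardized dosages are many-SD outliers
that otherwise dominate the distance matrix (in testing they reduced the
PC1–ancestry correlation from >0.95 to ~0.05). Nonfounders are projected
by the midparent rule (the expected standardized genotype of an offspring
is the parental mean), resolved in generation order; a kinship-weighted
regression projection is available as an alternative. One component
suffices for the two-subpopulation default and enters downstream models
as the covariate `pc1`.

## The simulator

`simConfig()` encodes the study design the package validates against:
8 four-generation families of 73–128 members grown from a founding couple
(Poisson offspring, marry-in founders), ~200 founders and ~700–800
individuals in total; a site frequency spectrum with 50%/35%/15% of SNPs
at MAF < 0.01 / 0.01–0.05 / ≥ 0.05, realized exactly in the founder
haplotype pool so the spectrum is reproducible (rare variants get at
least one copy); two founder subpopulations with Balding–Nichols
divergence (Fst 0.05) and family-specific mixture proportions; ages by
generation (founders ~N(75, 8), 25 years between generations, truncated
at 18) so the 16-year pair filter binds; smoking at 25% prevalence.

The dichotomous trait is logistic —
logit P = α + 0.077·Age + 0.947·Smoke + Σ log(OR_v)·dosage — with α
bisected so the realized prevalence is 30% (a probit-liability
alternative was considered and rejected: the package validates the
analysis models, so generator–analyzer congruence is the honest
default). Quantitative traits add 0.018·Age + 0.44·Smoke, an ancestry
effect, planted variant effects, a polygenic component with covariance
2Φσ²_g (h² = 0.60/0.45/0.70 for Q1/Q2/Q4, genetic correlation 0.25
between Q1 and Q2) and unit-total residual noise.

Planted variants are founder allele copies — one copy in an
earliest-generation founder of the largest family for the family-private
regime — so genotypes, true IBD and carrier lineages are mutually
consistent by construction (no Mendelian errors, every carrier traces to
the recorded founder). Quantitative effects given as variance shares are
sized from realized dosage variances so the group explains its target
share of phenotypic variance exactly; the default plants one dichotomous
variant at per-allele OR 6.8 and two Q1 variants jointly at 12%.

Loci are unlinked: each SNP is an independent gene drop. That makes every
locus an exact null replicate for calibration, but it means regional
phenomena — LOD curve shape around a peak, support-interval coverage, LD
with flanking markers — are exercised only structurally (the
support-interval code is tested against a brute-force oracle), not
against recombination-driven data. SNP panels default to 2,000 loci; the
validation studies below state their sizes explicitly, chosen so the full
suite replays in minutes while keeping Monte-Carlo error well inside the
assertion tolerances.

## Validation studies and what they show

Replicated studies hold the pedigrees fixed and redraw genotypes and
phenotypes — the design of a replicated family study, where the families
are the design and the data vary.

* `calibrateNull()` — a null study (no planted variants) scanned at 500
  unlinked loci: NPL and QT-score Z have mean ~0 and variance ~1.
* `assessRecovery()` — 50 replicates, 2,000 SNPs: the family-private
  OR-6.8 variant is recovered by the carrier-odds screen in ~90–100% of
  replicates; the heritability-drop accounting recovers the planted 12%
  variance share within ±3 on average; and in every replicate whose
  causal-locus LOD exceeds 3, adjusting for the planted SNPs drops it
  below 1.
* `assessVCRecovery()` — 100/50 phenotype replicates: mean ĥ² within
  ±0.05 of 0.6 and mean r̂_G ≈ 0.26 for a generator value of 0.25. These
  fits adjust Age, Smoking and the generator's true ancestry fraction (in
  place of estimated PC1, whose estimation the structure tests validate
  separately); omitting the structure covariate inflates both h² and r_G,
  which is precisely why the analysis models carry PC1.

## Known limitations

* **Upper-tail calibration of the sharing statistics.** The exact null
  distributions (gene-drop enumeration at 150,000 drops) give
  P(Z > 1.96) ≈ 0.038–0.040 for the NPL statistic and ≈ 0.031–0.035 for
  the QT score, against the nominal 0.025: per-family allele-sharing sums
  are right-skewed, because a family contributes few effective founder
  lineages and a clique of distant affected relatives jumps jointly when
  one ancestral allele spreads. Mean and variance are correct, two-sided
  exceedance at 1.96 is near-nominal (0.047–0.050), and the skew is
  insensitive to family structure; but one-sided normal p-values near
  LOD-significance thresholds are mildly anticonservative in 8-family
  designs, and users should prefer empirical (gene-drop) p-values for
  borderline peaks — the machinery to compute them is the same
  `pairCovariance()`/gene-drop engine used internally.
* **Power of linkage for a lone rare variant is modest.** A single
  private OR≈7 or 6%-variance variant yields causal-locus E[Z] of only
  ~1–2 here: after the age filter a lone variant feeds few informative
  affected pairs. Large LOD scores in comparable real studies rest on
  multiple clustered causal variants per region. Consequently the
  carrier screens, not the scans, are the workhorse for single rare
  variants — which is the strategy the pipeline encodes (linkage to
  define regions, screening to find the variants, conditional scans to
  close the loop).
* The generator draws unlinked loci, outbred pedigrees, and
  generator-congruent trait models; robustness to LD, inbreeding,
  liability-scale misspecification or ascertainment is untested.
* The kinship recursion supports inbreeding, but every statistic's
  moments assume outbred pairs (π ∈ {0, 1/2, 1}); the label-trick
  numerator additionally assumes within-individual label distinctness,
  which inbreeding would break.
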