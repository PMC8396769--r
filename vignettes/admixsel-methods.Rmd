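---
title: "Methods: haplotype association and selection scans in admixed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype association and selection scans in admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixsel)
```

# Scope

`admixsel` implements a candidate-gene pipeline for genetic epidemiology in
admixed populations: choosing tag SNPs for a gene region from PCA loadings,
estimating multi-locus haplotype frequencies from unphased genotypes by EM,
testing case-control association under standard genetic models with
admixture adjustment and meta-analysis across recruitment sites, and
scanning phased panels for signatures of natural selection at three
timescales (allele-frequency differentiation, the site frequency spectrum,
and extended haplotype homozygosity). A synthetic-data layer generates every
input the pipeline needs, so all of its operating characteristics — type-I
error, confidence-interval coverage, scan power — are measured inside the
test suite rather than asserted.

This vignette records the models, the defaults and why they were chosen,
the numerical decisions, and the known limitations. It states no empirical
number that the test suite or `scripts/acceptance.R` does not itself
compute.

# Tag-SNP prioritization from PCA loadings

Genotype dosages are normalized Patterson-style: column $j$ is centred by
its mean dosage $\mu_j$ and scaled by $\sqrt{(\mu_j/2)(1-\mu_j/2)}$, the
binomial standard deviation implied by the allele frequency; missing
entries are set to 0 after centring (mean imputation), and monomorphic
columns become all-zero instead of dividing by zero. The SVD of the
normalized matrix gives sample scores and variant-space loadings; the "SNP
weight" of a variant on PC1 is its entry in the first right singular
vector. We interpret the weight as the loading itself (the quantity
EIGENSOFT's `snpweight` output reports), not loading times eigenvalue; the
ranking uses the *absolute* weight, since the sign of a principal component
is arbitrary. Ties (e.g. perfectly duplicated variants) are broken by
ascending position, with weights rounded to 10 decimals first so
floating-point jitter cannot reorder exact ties.

`select_tag_snps()` ranks variants by `|PC1 weight|`, shortlists the top
`k = 30`, and audits each against four conditions: sample MAF above 10%,
absence of high LD ($r^2 > 0.8$) with a higher-ranked kept SNP, a
coding/regulatory annotation, and a prior-literature flag (consumed as a
boolean input — a literature lookup is not computable). A SNP is kept when
it meets at least three conditions; in the default `hard_maf` mode the MAF
condition is additionally required outright, because a tag SNP that cannot
be genotyped informatively is useless regardless of its other merits (the
soft mode is available via `hard_maf = FALSE`). LD pruning is greedy in
rank order — the procedure the audit trail makes explicit, since published
descriptions of such pipelines rarely state their pruning algorithm — and
guarantees no kept pair exceeds `r2_max`. When only unphased genotypes are
available, pairwise $r^2$ comes from two-locus EM haplotype frequencies.

# LD and EM haplotype frequencies

For phased data, $D = p_{AB} - p_A p_B$, $D' = D/D_{\max}$ with the usual
bound, and $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$, from direct gamete counts.

`em_haplotypes()` is the classical EM for unphased genotypes over up to 8
loci ($2^8$ haplotypes): the E-step weights each individual's compatible
diplotypes proportionally to $p_{h_1}p_{h_2}$ (doubled for heterozygous
diplotypes), the M-step re-estimates frequencies from expected counts.
Individuals missing any locus of the block are excluded listwise and
counted. Numerical decisions:

* **Initialization.** Linkage-equilibrium products of allele frequencies,
  plus `restarts = 3` random Dirichlet starts; the best final
  log-likelihood wins. The all-double-heterozygote dataset makes the LE
  start an exact saddle point of the likelihood — a known EM pathology —
  and a random restart escapes it; this case is covered by a unit test.
* **Convergence.** `max |Δp| < 1e-6` (configurable); the log-likelihood
  trajectory is stored and its monotonicity asserted in tests.
* **Pruning.** Haplotypes with converged frequency below `1e-4` are pruned
  and the rest renormalized; a final E-step recomputes posterior dosages on
  the pruned set. The conventional 5% cutoff is only a *reporting*
  threshold (`tidy(fit, report_min = 0.05)` pools rarer haplotypes into a
  `rare` row); everything is retained internally.

Per-individual expected haplotype counts ("dosages", in $[0,2]$, rows
summing to 2) are the carrier of phase uncertainty into association.

# Case-control association

Quality control mirrors standard practice: samples with missing or
discordant metadata are dropped; variants with call rate $\le 90\%$ in
cases or in controls are dropped; variants violating Hardy–Weinberg
equilibrium in controls (1-df $\chi^2$, $p < 0.05$) are flagged and by
default dropped. Every exclusion is itemized with a reason.

Logistic regression goes through `stats::glm` with a tightened convergence
tolerance (`epsilon = 1e-12`), which makes saturated 2×2 reductions agree
with the closed-form $\ln(ad/bc)$ to well below $10^{-8}$; the wrapper
turns the failure modes that matter for sparse genetic tables into explicit
errors — rank deficiency, and quasi-separation detected as any coefficient
beyond 15 on the logit scale. Wald tests are reported, matching standard
`glm` output.

Genetic models are encoded from the *minor* allele defined in the pooled
sample: codominant (two indicator contrasts in one fit), dominant,
recessive, carrier (identical to dominant by construction — kept as a
separate surface because "minor-allele carriers" is how such results are
often phrased), and allelic. The allelic model uses per-allele expansion
(two observations per individual) rather than a dosage column; the dosage
alternative exists for haplotype contrasts (below). Covariates default to
automatic selection: any candidate differing between cases and controls at
$p<0.05$ (chi-square for categorical, Wilcoxon rank-sum for numeric) is
adjusted for; ancestry enters as $K-1$ admixture proportions to avoid
sum-to-one collinearity. BH-FDR is applied per model across variants by
default; the family is configurable to pool across models, since the
correct family is a judgement call the method itself cannot make.

**Haplotype association** tests each haplotype against a reference
haplotype on EM dosages, restricted to carriers of target-or-reference. Two
contrasts:

* `"allelic"` (default): one weighted pseudo-observation per haplotype
  copy. With unambiguous phase and no covariates this *equals* the allelic
  2×2 cross-ratio — the arithmetic behind crude haplotype ORs quoted
  against a reference haplotype from frequency tables — which is verified
  exactly in the tests.
* `"dosage"`: logistic regression of status on the expected dosage
  (haplo.stats-style). When an effect is generated per haplotype copy on
  the logit scale, this is the consistent estimator of that per-copy
  log-OR, so the parameter-recovery tests use it; the allelic contrast is
  kept as the default because it matches how crude haplotype ORs are
  conventionally computed and reported.

**Meta-analysis** pools per-site log-ORs by DerSimonian–Laird:
$Q$, $\tau^2 = \max(0, (Q - df)/C)$, inverse-variance weights
$1/(se^2+\tau^2)$. A one-stage logistic model with a site random intercept
is the literal "random effects by region" formulation; DL on site log-ORs
is the deterministic, closed-form surface chosen as the default, and is
cross-checked against `metafor::rma(method = "DL")` in the tests. Identical
sites give $\tau^2 = 0$ and return the common estimate unchanged.

# Supervised admixture

Individual admixture proportions $q$ are estimated from an
ancestry-informative-marker (AIM) panel by maximizing, independently per
individual, $\sum_j [g_j \log \sum_k q_k f_{kj} + (2-g_j)\log \sum_k
q_k(1-f_{kj})]$ with the ancestral-population frequencies $f_{kj}$ held
fixed — the fixed-frequency, supervised special case of model-based
ancestry clustering. The EM update assigns each allele copy a
responsibility proportional to $q_k f_{kj}$ (alt) or $q_k(1-f_{kj})$ (ref)
and sets $q$ to the mean responsibility; the estimand matches a supervised
STRUCTURE/ADMIXTURE run without the MCMC machinery (full MCMC with migrant
testing and correlated frequencies is out of scope). $q$ starts uniform,
converges on `max |Δq| < 1e-7`, and is verified against an exhaustive
simplex grid search in the tests. Missing genotypes are skipped;
individuals with no called AIMs are flagged undefined.

A note on attainable accuracy: with $J = 46$ AIMs whose pool frequencies
follow a Balding–Nichols law at $F = 0.2$, the per-individual Fisher
information caps the accuracy of *any* estimator of $q$ at roughly
$\mathrm{sd}(\hat q_k) \approx 0.15$–$0.2$; the test suite verifies that
the EM attains the exact MLE, and the acceptance report states both the
per-individual RMSE (information-limited) and the cohort-mean RMSE (which
averages down to a few percent — the scale at which cohort ancestry
composition is typically quoted and used as a covariate).

# Selection scans

**Weir–Cockerham $F_{ST}$** is computed from genotype counts with the
observed heterozygosity, as the $a$ (among-population), $b$
(among-individual-within-population) and $c$ (within-individual) variance
components; per-variant $F_{ST} = a/(a+b+c)$, reported as computed
(negative estimates are not clamped; a `--clamp0`-style option exists only
at the reporting layer). Windowed values use the **ratio of averages**
$\sum a / \sum (a+b+c)$ — not the average of per-SNP ratios, a distinction
guarded by a regression test — after excluding variants with pooled MAF
below 0.05, which would otherwise inflate the estimator. Window and step
default to 20 and 5 *variants* (smoothing over adjacent SNPs); a bp mode is
provided. The published descriptions this mirrors give window sizes that
read literally as a few bp, which cannot hold more than one SNP; we treat
the intent — smoothing over small groups of adjacent SNPs — as
authoritative and leave both units available.

**Tajima's D** uses the 1989 constants; windows tile the chromosome from
position 1 (the last window partial), at 100/75/50/25 kb. Windows with
$S=0$ are undefined and flagged. Empirical $p$-values are rank-based
within the scan distribution of the same window size:
$p = (1 + \#\{v > v_{obs}\})/(1+N)$ upper-tailed, mirrored for the lower
tail, doubled and capped for the default two-sided version (lower tail
targets sweeps, upper tail balancing selection). The rank form makes the
$p$-value invariant to monotone transformation of the statistic and gives
the scan maximum $1/(N+1)$.

**EHH family.** $EHH(x)$ is the probability that two random core-allele
carriers are identical at every marker from the core to $x$; it is computed
outward in both directions by iterative refinement of haplotype classes,
stops when it decays below `cutoff = 0.05`, at the chromosome end, or at an
inter-marker gap over 200 kb, and the last (below-cutoff) segment is
included in the trapezoidal integral over genetic distance that defines
iHH. Cores whose EHH never decays before truncation are excluded from iHS
(the usual convention; `keep_truncated` overrides). iHS is
$\ln(iHH_{anc}/iHH_{der})$ standardized within 20 equal-width
derived-frequency bins, merging bins under 10 SNPs with their nearest
neighbour. xpEHH is $\ln(iHH_A/iHH_B)$ with *whole-sample* iHH per
population, standardized genome-wide; positive scores mean longer
haplotypes (candidate selection) in population A, and region calls use the
conventional $|score| > 2$ threshold on the absolute value, so the sign
convention cannot change which regions are flagged. SNPs without ancestral
annotation are skipped by iHS but scored by xpEHH, which needs no polarity.

# The synthetic-data layer

**Ancestral pools.** `balding_nichols_pools()` draws per-population allele
frequencies $f_{kj} \sim Beta(p_j(1-F_k)/F_k, (1-p_j)(1-F_k)/F_k)$, clamped
to $[0.01, 0.99]$ so no AIM is degenerate at fixation.

**Admixed cohorts.** `simulate_admixed_cohort()` draws per-individual
$q \sim Dirichlet(\alpha)$ (default $\alpha = (3.5, 5, 1.5)$: mean ancestry
35/50/15%, a plausible tri-hybrid admixed profile), AIM genotypes copy-wise
(ancestry then allele), and focal-block haplotypes *as whole 3-SNP
haplotypes* from per-ancestry frequency tables — this, not per-SNP
independence, is what gives the focal block real LD. The default tables
(`default_focal_haplotypes()`) use published African/European frequency
profiles for a risk-haplotype block of an African-ancestry candidate region
(risk haplotype at 0.47/0.27, reference rare in Africans and common in
Europeans); the Native-American column has no published counterpart and was
fixed once at a plausible intermediate profile. The phenotype follows
$\mathrm{logit} P(case) = \beta_0 + \beta_{hap}\,\mathrm{dos}(risk) +
\beta_{age}(age-40) + \beta_{sex}\,\mathrm{male}$, with defaults
$\beta_{hap} = \ln 1.64$ (the scale of effect the pipeline is designed to
detect), $\beta_{age} = 0.02$/year and $\beta_{sex} = 0.3$ (mild realistic
confounding), $\beta_0 = -1.1$. Case-control ascertainment draws candidates
until both quotas fill (retrospective design); a population mode exists for
calibration tests of prevalence.

What the cohort generator does *not* emulate: genotyping error, batch
effects, relatedness/cryptic kinship, LD between AIMs, more than one
LD block, and ancestry-phenotype confounding (none of the default effects
load on $q$). Passing calibration and recovery tests on these cohorts
therefore shows the estimators are correct under their own assumptions, not
that real cohorts satisfy those assumptions.

**Sweep simulator.** `simulate_sweep()` is a discrete-generation
Wright–Fisher forward simulation of $2N$ haplotypes over `L` tracked sites:
random mating (fitness-weighted during selection), Poisson crossovers at
`r` per bp per generation, allele-flip mutation at `mu`. Standing variation
is initialized from the neutral site-frequency spectrum (count $k$ w.p.
$\propto 1/k$) with no initial LD, followed by a short burn-in that builds
LD; the burn-in-final majority alleles are recorded as ancestral. The
population is then copied: one copy receives the beneficial allele by
flipping a single haplotype's focal allele (the focal column having been
reset to the ancestral state in both copies) and evolves under additive
selection $(1, 1+s, 1+2s)$ until the target frequency or a generation cap;
the other copy is returned *frozen* as the matched neutral control. Lost
sweeps are retried.

Default regime and rationale (chosen once, a priori of any particular
analysis, and documented here):

* `N = 200` diploids with `r = 1e-6`/bp and `mu = 1e-6`/site — a
  deliberately rescaled regime (small population, inflated per-generation
  rates), the standard device for making forward simulation tractable at
  desk scale; the emitted genetic map uses the same `r` (`cM/Mb = r·1e8`),
  so iHH integrals are internally consistent.
* `burnin_gens = 60`, so the background haplotype-identity scale
  $\sim 1/(2r\,t)$ is a few tens of kb — a human-scale LD decay. Running a
  200-diploid population to coalescent equilibrium would instead produce
  background haplotypes far longer than any outbred sample shows, drowning
  sweep signals in small-$N$ artefacts.
* `L = 1000` sites over 400 kb: dense enough that background homozygosity
  decays well inside the sweep footprint.
* `target_freq = 0.99`: the cross-population statistics the simulator feeds
  are at their strongest for essentially complete sweeps; partial sweeps
  are the within-population (iHS) regime. `null_gens = 210` matches the
  expected duration of a completed sweep at the default `s`, so the
  $s = 0$ pair is a time-matched control.

Known limitation, measured rather than hidden: with $s = 0.05$ and
$N = 200$, $Ns = 10$, a completed sweep takes a substantial fraction of the
coalescent timescale, during which drift in the selected copy generates
identical-by-descent tracts whose iHH noise is comparable to the sweep
footprint. With scan-level standardization the focal xpEHH score then
concentrates near the $|2|$ threshold instead of far beyond it, and the
per-SNP detection power stays moderate (the acceptance report prints the
measured value); the frequency-spectrum footprint (focal-window Tajima's D
against the neutral panel's window distribution) is the more reliable
signal in this regime, and the false-positive rate under $s=0$ stays at the
nominal level. Real analyses escape this by standardizing against
genome-wide, mostly-neutral SNP sets and by sample sizes in the hundreds of
haplotypes from populations with $N_e$ in the thousands.

# Problem sizes used by the test suite

Unit tests run on toy instances (tens of samples, up to a few thousand
haplotypes) chosen so every oracle comparison is exact or
Monte-Carlo-stable. The end-to-end checks use: 200 cohort replicates at
2000/2000 cases/controls for OR coverage; 1000 null variants at 500/500 for
type-I calibration; 500 individuals at 46 AIMs for admixture recovery; and
100 sweep plus 100 neutral forward simulations at the default regime for
scan power. `scripts/acceptance.R` recomputes the same quantities at
moderately reduced replicate counts (printed in its output as `n`).

# Degenerate inputs and tie-breaks, collected

* Monomorphic variants: all-zero column after normalization; undefined LD
  and $F_{ST}$ flagged, HWE $p = 1$ with a flag.
* All-missing variant or individual: flagged undefined or excluded with a
  count, never silently imputed (the one exception: PCA mean-imputes
  missing entries, which is the standard choice for that step).
* Multi-allelic VCF records: skipped and counted, never split.
* Empty genotype classes in a model: that contrast is returned as
  undefined with a reason, not fitted.
* EM ties (double-heterozygote ambiguity at equal frequencies): posterior
  dosage splits exactly 1/1, by construction.
* PCA sign: the largest-|weight| entry of each component is made positive;
  rank ties broken by ascending position.
* Windows: 1-based inclusive coordinates everywhere; any half-open
  arithmetic is converted explicitly at the window layer.
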