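---
title: "Modifier GWAS in mutation carriers: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modifier GWAS in mutation carriers: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carriermod)
```

## The problem

Carriers of a high-risk cancer-predisposition mutation show strikingly
variable penetrance: carriers of the same mutation develop disease at very
different ages or not at all. A natural explanation is a polygenic background
of common variants, each multiplying the carrier baseline hazard by a small
amount. Finding such modifier loci requires a genome-wide association scan in
carriers — but carriers are recruited through clinical genetics services, not
at random. Affected carriers (often young ones) are heavily over-sampled, so
an ordinary case-control or prospective Cox analysis of such a sample is
biased.

`carriermod` implements the analysis machinery for this setting:

1. a **retrospective likelihood** of genotypes conditional on phenotypes,
   which is valid under any ascertainment that selects on phenotype alone;
2. a **1-df score test** of a per-allele effect with a **kinship-adjusted
   variance**, since carriers from the same family share genotypes;
3. **hazard-ratio estimation** (per-allele, genotype-specific, age-varying)
   with robust family-clustered standard errors and fixed-effect stage
   combination;
4. a **quality-control cascade** with exact ledger accounting;
5. **gene-set enrichment** of scan p-values and **IBD segment sharing**;
6. a **synthetic cohort generator** that reproduces the statistical structure
   the analysis assumes, so every stage is testable end-to-end without access
   to restricted genotype data.

## Time at risk and censoring

Each carrier contributes a censoring age $t$ and an affection indicator
$\delta$. A carrier is censored at the first of: breast cancer diagnosis
(a case), ovarian cancer diagnosis (unaffected), bilateral prophylactic
mastectomy (unaffected), last observation, or the administrative cap of 80
years (incidence rates above 80 are unreliable). A mastectomy overrides a
later cancer only when it preceded the diagnosis by *strictly more than one
year*; this protects against surgery belonging to the diagnostic episode when
ages are recorded in whole years. Both integer and fractional ages are
accepted.

## The retrospective likelihood

Let $\lambda_0(t)$ be the carrier baseline hazard (piecewise-constant,
supplied externally through `incidence_model()`), $\Lambda_0(t)$ its integral,
and $x(g)$ the genotype coding (dosage for the multiplicative model). The
proportional-hazards model is $\lambda(t \mid g) = \lambda_0(t)
e^{\beta x(g)}$. Conditioning each carrier's genotype on their phenotype
gives

$$
\ell_i \;=\; \delta_i \beta x(g_i) - \Lambda_0(t_i) e^{\beta x(g_i)}
 + \log p_s(g_i)
 - \log \sum_{g'} p_s(g')\,
   \exp\!\left\{ \delta_i \beta x(g') - \Lambda_0(t_i) e^{\beta x(g')} \right\},
$$

where $p_s(\cdot)$ is the Hardy–Weinberg genotype prior at the allele
frequency of stratum $s$ (country of study crossed with founder-mutation
status; stage is appended for combined two-stage fits). The
$\lambda_0(t_i)^{\delta_i}$ factors cancel in the ratio, and at $\beta = 0$
the expression collapses to the multinomial genotype likelihood — both facts
are asserted by tests against a brute-force per-carrier oracle.

The likelihood is per-individual: we condition on each carrier's own
phenotype rather than evaluating a full multi-person pedigree likelihood.
Residual familial dependence is then handled in the variance, not the mean:
the score test uses a kinship-adjusted variance, and estimation uses a
Huber-style sandwich with scores summed over family clusters. This is the
single-individual analogue of maximising the full retrospective likelihood in
pedigree software, and it is what makes a 592k-SNP scan tractable.

### Allele frequencies

Stratum allele frequencies are *profiled jointly* with $\beta$ during
estimation rather than plugged in, because the retrospective term couples
them with the effect size. Under the null they are estimated from all
carriers in the stratum (genotype is independent of phenotype at
$\beta = 0$). Centring genotypes at the stratum mean and at the
Hardy–Weinberg expectation $2\hat p_s$ coincide when $\hat p_s$ comes from
the same carriers, so the implementation has a single centring path.

## The kinship-adjusted score test

Differentiating the likelihood at $\beta = 0$ with the frequencies profiled
out gives the score

$$
U = \sum_s \sum_{i \in s} (c_i - \bar c_s)\, g_i,
\qquad c_i = \delta_i - \Lambda_0(t_i),
$$

a stratum-centred covariance between the martingale-type residual and the
dosage. Its null variance must account for genotype correlation among
relatives, $\mathrm{Cov}(g_i, g_j) = 2\phi_{ij}\sigma^2_s$ with $\phi$ the
pedigree kinship coefficient:

$$
V = \sum_s \sigma^2_s\, a_s^\top (2\Phi_s)\, a_s, \qquad
a_i = c_i - \bar c_s, \quad \sigma^2_s = 2\hat p_s (1 - \hat p_s).
$$

Two numerical choices matter here and are worth stating explicitly:

* **Centred residuals in $V$.** Writing the variance with raw residuals
  $c_i$ (treating the stratum genotype mean as known) overstates $V$
  whenever $\sum_i c_i \neq 0$ within strata — which is the norm under
  phenotype-based ascertainment, where cases contribute $c_i \approx +0.8$
  and controls $c_i \approx -0.3$. The profile-score form with
  $a_i = c_i - \bar c_s$ is the correct variance of $U$ given the
  phenotypes, and simulation shows it is what keeps the genomic inflation
  factor at 1 on null cohorts; the raw form deflates the median statistic by
  10–20%.
* **Finite-sample variance correction.** The plug-in $2\hat p(1-\hat p)$
  underestimates the genotype variance by the factor $(2n_s - 1)/2n_s$; with
  28 country-by-mutation strata some strata are small and the tails of the
  test become visibly anti-conservative without the $2n_s/(2n_s-1)$
  correction.

The statistic is $\chi^2 = U^2/V$ on 1 df. Missing genotypes drop the
carrier for that SNP (complete-case); monomorphic SNPs are flagged and given
$p = 1$. Scan-level diagnostics are the genomic inflation factor
$\lambda = \mathrm{median}(\chi^2)/0.4549364$ and QQ coordinates at the
$(i - 0.5)/n$ plotting positions.

The adjustment demonstrably matters: on sib-trio cohorts with a strong
shared frailty, the naive ($\Phi = 0$) variance rejects at more than 6% at
nominal 5%, while the adjusted test stays at 5% — this contrast is part of
the test suite.

## Hazard-ratio estimation

`fit_hr()` maximises the retrospective likelihood over $\beta$ and the
stratum frequencies with bounded quasi-Newton (`L-BFGS-B`, $|\beta| \le 5$
against separation, frequency logits bounded away from 0/1, convergence
tolerance $10^{-8}$ on the log-likelihood via `factr`). Three codings are
provided:

* `per_allele` — multiplicative dosage model (the headline model);
* `genotype_2df` — heterozygote and rare-homozygote indicators against the
  common-homozygote baseline;
* `age_interaction` — hazard multiplier
  $\exp\{(\beta_0 + \beta_1 (t - t_{\mathrm{ref}}))\,g\}$ with the
  cumulative-hazard integral evaluated exactly band by band; $t_{\mathrm{ref}}
  = 50$ years by default (the centring age is a free choice; 50 sits in the
  middle of the age range where carrier incidence is appreciable). The slope
  is bounded at $|\beta_1| \le 0.25$/year, far beyond any plausible effect,
  to keep the exponential band integrals finite during optimisation. A 1-df
  likelihood-ratio test against the proportional-hazards fit tests
  $\beta_1 = 0$.

Robust variances use the sandwich $A^{-1} B A^{-1}$ with $A$ the observed
information (central finite differences) and $B$ the sum of per-family score
outer products; families never span stages (the stage-2 QC removes
cross-stage duplicates, and `combined_stage_fit()` errors on overlapping
ids). Over 200 synthetic ascertained cohorts of ~2,000 carriers (HR 1.3,
MAF 0.3) the estimator's absolute bias on the log scale is below 0.02 and
robust 95% intervals cover at their nominal rate — asserted in the
acceptance suite.

`meta_fixed_effect()` performs the inverse-variance combination on the log
scale, recovering each stage's SE from its printed CI as
$(\log u - \log l)/(2 \times 1.959964)$; the package's worked examples
reproduce published two-stage combinations to two decimals.

## Quality control

All filters are pure functions that log `(step, threshold, n_removed,
n_remaining)` rows; `qc_ledger()` re-derives any published exclusion
narrative by sequential arithmetic. Defaults (and their `run_config()`
names): sample/SNP call rate 0.95, MAF 0.01, HWE exact $p < 10^{-6}$
(initial) and $10^{-7}$ (stringent final pass), differential missingness
$10^{-3}$ by phenotype and $10^{-10}$ in neighbour-genotype mode, IBS
duplicate threshold 0.95, heterozygosity FDR 0.1%, MDS ancestry cutoff 11%,
LD pruning $r^2 < 0.80$.

Decisions the field leaves open, fixed here and logged:

* The HWE test is the standard exact conditional test (not mid-p), checked
  exhaustively against an independent enumeration oracle for all tables with
  $n \le 60$.
* Duplicate detection is IBS-based for both stages; the retained member of a
  pair is the one with the higher call rate (ties broken lexicographically).
* Heterozygosity outliers: two-sided z-scores of the per-sample heterozygote
  fraction with robust centre/scale (median, MAD), Benjamini–Hochberg FDR.
* Filter order is fixed and logged — samples: call rate, heterozygosity,
  duplicates; SNPs: missingness, MAF, HWE, differential missingness — and
  the sample/SNP passes alternate until a full pass removes nothing
  (`iterative_qc()`, provably monotone, idempotent on its own output).
* The ancestry criterion is a *heuristic*, not a reproduction of any
  specific published metric (which is not recoverable from its one-line
  description): classical MDS of the genomic-kinship distance, main cluster
  defined by the Q3 + 3 IQR rule on distances from the coordinate-wise
  medoid, and a sample flagged when its distance exceeds the cluster span by
  more than the cutoff (11%). Near-duplicate samples are collapsed before
  embedding — a duplicate pair would otherwise create a spurious MDS axis of
  its own — which also guarantees that a duplicate of an inlier is never
  flagged. The heuristic needs a structure-dominated embedding, i.e. a
  pruned panel of at least a few thousand markers for cohorts of hundreds of
  samples.

## Gene-set enrichment

Gene scores are best-SNP minimum p-values over strand-aware windows (110 kb
beyond the 5′ boundary, 40 kb beyond the 3′), corrected for gene-score
confounders by regressing $-\log_{10} p$ on log window length, log SNP
count, and a log LD proxy (SNP count after $r^2 \ge 0.8$ pruning), then
rank-mapping residuals back to $(0, 1]$. The window length (not the bare
gene length) enters the regression because the window is what harvests SNPs.
Enrichment compares the fraction of set genes beating the genome-wide 95th
percentile against random same-size sets (10,000 by default), with the
$+1$ permutation correction to avoid zero p-values, and with genes sharing a
best SNP collapsed to the most significant one — in both the real and the
random sets. Everything is rank-based, so the enrichment p-value is
invariant to monotone transformation of the SNP p-values.

One property of this construction deserves a note: the set statistic (a
fraction over a few dozen genes) takes few distinct values, so the
permutation p-value — which counts ties as extreme, the standard
conservative convention — is discrete and *super*-uniform under the null,
never anti-conservative. `gsea_p()` therefore also reports the tie
diagnostics `n_greater` and `n_equal`; the randomized-tie transform
$(n_{\mathrm{greater}} + U\,(n_{\mathrm{equal}} + 1))/(n_{\mathrm{random}} +
1)$ is exactly Uniform(0,1) when the permutation null is correct, and that
exact statement is what the test suite asserts.

## IBD segment sharing

Haplotype mode is GERMLINE-style: 64-marker half-overlapping windows are
hashed to find exact allele-word matches, runs of matched windows seed
segments, and seeds extend marker-by-marker with a budget of one mismatch
per 100 markers. Segment ends are then anchored on a clean run of 12
matching markers so budgeted mismatches cannot drift an endpoint past the
true boundary; with ~12 markers/cM this keeps endpoint error within
±0.5 cM for planted 8 cM segments. Unphased genotype mode reports maximal
runs without opposite homozygotes under the same budget (the package does
not implement phasing or imputation). Segments of at least 5 cM are
reported; sharing profiles count spanning pairs every 2.5 cM outside
user-supplied telomere/centromere masks, and group contrasts use label
permutation.

## The synthetic cohort generator

The generator is first-class, tested code: it produces exactly the structure
the analysis assumes, and its defaults are the study conditions used by the
acceptance checks.

* **Families.** Sibships of size 1–3 ($P = 0.5, 0.3, 0.2$) sharing two
  unobserved founder parents; founder genotypes are binomial$(2, p)$ under
  HWE and offspring follow Mendelian transmission, giving sibling kinship
  0.25. All subjects are carriers by design (the mutation is family-wide).
* **Strata.** 14 countries with weights mirroring a large international
  carrier consortium, and a per-country probability that the family carries
  the Ashkenazi founder mutation (high in Israel, moderate in North America,
  low elsewhere).
* **Baseline hazard.** Piecewise rates rising by age decade to a cumulative
  risk of ≈47% by age 70 — a synthetic default of the right order for a
  high-penetrance carrier population, deliberately *not* a published
  incidence table (users supply real rates via configuration).
* **Residual familial clustering.** A shared per-family normal frailty on
  the log hazard, sd 0.5 by default — enough to make ignoring kinship
  visibly wrong without dominating the phenotype; the anti-conservativeness
  fixtures raise it to 1.5.
* **Ascertainment.** Individual-level phenotype rules (cases diagnosed at
  or below 50 with extra weight below 40; controls unaffected beyond 40),
  since the retrospective likelihood conditions on phenotype and only
  phenotype-based selection matters for validity. The rules are
  configurable because discovery and replication stages differ.
* **Artifacts.** Differential missingness by phenotype and batch, exact
  duplicates, heterozygosity-inflated samples, heterozygote-deficit SNPs,
  Balding–Nichols-drifted ancestry outliers, and random call errors — each
  recorded in a truth ledger for recovery tests.

What the generator does **not** emulate: chromosome-scale linkage
disequilibrium (null SNPs are independent loci; a two-SNP haplotype would be
needed for LD-aware power studies), genotype intensity artifacts,
imputation uncertainty, competing-risk structure beyond constant ovarian and
mastectomy hazards, and male carriers. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every failure mode of real array data.

## Problem sizes used in the checks

The default test suite works at deliberately chosen sizes: the genomic
control check scans 50,000 null SNPs on ≈1,700 ascertained carriers
(inflation factors estimated from fewer SNPs carry Monte-Carlo error of
±0.03 and would make the ±0.02 band meaningless); type-I error and the
naive-variance contrast use 10,000 SNPs on 1,200 sib-trio carriers;
parameter recovery uses 200 replicates of ≈2,000 carriers; the HWE oracle
comparison is exhaustive over all genotype tables with $n \le 60$; founder
HWE calibration in the generator is spot-checked at 500 SNPs. Each number is
stated where the test lives.

## Known limitations

* The per-individual retrospective likelihood with cluster-robust variance
  is an estimating-equation compromise; a full Elston–Stewart pedigree
  likelihood over untyped relatives would extract more information from
  large families.
* Hard-call genotypes only; no dosage input.
* The MDS ancestry cutoff is a heuristic (above) and should be read as
  "relative distance from the reference cluster", not a calibrated
  probability.
* Birth-cohort incidence lookup is by decade; calendar-year tables are
  accepted but coarsened.
* X-chromosome SNPs receive no special treatment.
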