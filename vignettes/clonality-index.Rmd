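---
title: "The clonality index: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The clonality index: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalCI)
```

## The problem

A patient presents with two synchronous lung tumors. If they arose
independently (multiple synchronous lung cancers, MSLC) each is staged and
treated as an early primary; if one seeded the other (intrapulmonary
metastasis, IPM) the disease is stage IV. Histology and imaging often cannot
tell these apart. Somatic mutations can: two lesions descended from one
clone share many of the founding clone's mutations, while two independent
tumors share mutations only when the same alteration recurs by chance —
which essentially only happens at driver hotspots such as EGFR L858R or
KRAS G12C.

`clonalCI` turns that intuition into a calibrated decision rule.

## The model

Let the two lesions' mutation sets (canonical keys, see below) be $A$ and
$B$, and let $p_m$ be the population prevalence of mutation $m$ in a
reference cohort of the same cancer type. Under independent origin, the
chance of observing $m$ in $k$ of $n$ sampled tumors is binomial,

$$P(X_m) = \binom{n}{k} p_m^k (1 - p_m)^{n-k},$$

and for a two-lesion comparison the only sensible reading is $n = k = 2$
(the mutation was observed in both members of the pair), giving
$P(X_m) = p_m^2$. Assuming independence across mutations, the probability
of the whole shared set $A \cap B$ arising by chance is
$\prod_{m \in A \cap B} P(X_m)$, and the **clonality index** is

$$\mathrm{CI} = -\log_{10} \prod_{m \in A \cap B} P(X_m)
             = \sum_{m \in A \cap B} -\log_{10} P(X_m).$$

Disjoint sets give the empty product, so $\mathrm{CI} = 0$. With the
defaults, each shared mutation contributes $-2\log_{10} p_m$: a hotspot at
$p = 0.04$ adds about 2.8, a mutation seen once in 500 samples adds about
5.4, so even two or three shared passengers dominate any single shared
hotspot. That asymmetry — passengers are strong evidence, hotspots weak —
is the entire scientific content of the index; everything else is
calibration.

Assumptions worth stating: mutations co-occur independently given the
prevalences (ignores mutational-signature correlation and regional
hypermutation); presence/absence is binary (VAF is carried through the data
structures but plays no role in "observing" a mutation); and the reference
cohort's prevalence spectrum is exchangeable with the study population
(a Western reference cohort applied to an Asian study population will
mis-estimate several driver prevalences).

## Mutation identity

"The same mutation" needs a definition before any intersection is taken.
`mutation_keys()` offers two keying modes:

* **genomic** (default): `chrom:pos:ref:alt` after upper-casing and
  reference-free normalization — the shared suffix and then the shared
  prefix of ref/alt are trimmed with the position advanced, which
  reconciles the MAF spelling of an indel (anchor base dropped, `-` for the
  empty allele) with the VCF spelling (anchor base kept). Records lacking
  coordinates fall back to the protein key.
* **protein**: `gene:protein_change`, for call sets only comparable at the
  annotation level; falls back to the genomic key.

Fusions and amplifications key as `gene:event_class`. Full left-alignment
against the reference genome is deliberately out of scope (no reference
handling anywhere in the package); prefix/suffix trimming handles the
dialect differences that actually occur between MAF and VCF spellings of
one call set. Synonymous variants are *included* by default
(`include_synonymous = TRUE`) — the index counts all somatic alterations,
coding consequence is irrelevant to identity-by-descent — and the same
keying/synonymous policy must be used for the catalog, the calibration and
the study pairs; mixing policies is a configuration error.

## The prevalence catalog

`build_catalog()` estimates $p_m$ from a reference cohort. Two estimators
are provided because "population prevalence" is genuinely ambiguous:

* `sample_fraction` (default): carriers / $N$ — the fraction of reference
  *samples* carrying the mutation, with duplicate rows per sample counted
  once. This is what "prevalence" usually means.
* `mutation_fraction`: occurrences / total mutation rows. Prevalences are
  then far smaller for common hotspots (a hotspot in 4% of samples may be
  0.1% of mutation rows), so single-driver CIs come out correspondingly
  larger. Published single-hotspot CI values near 8 are only reachable
  under an estimator of this rarer kind; per-sample prevalence of EGFR
  L858R (~4%) gives $-2\log_{10} 0.04 \approx 2.8$. The package asserts
  neither reading — the mode is a logged configuration knob, and the
  closed-form relationship between mode and CI is what the test suite pins
  down.

Unseen mutations get a smoothing floor, default $1/(N+1)$ — "roughly one in
$N+1$ samples" — which keeps every lookup in $(0, 1]$ and the CI finite.
The floor backs unseen keys only; a seen key below the floor (possible
under `mutation_fraction`) returns its estimated value. $N$ is always taken
from the data actually loaded and is surfaced in the catalog print method,
the catalog TSV header and the pipeline log.

## Cutoff calibration

No analytic null distribution is attempted. Instead `calibrate()` simulates
both classes from the reference cohort:

* **positives** (clonally related): for each sample and each proportion
  $q \in \{0.4, 0.6, 0.8\}$, two *independent* draws of
  $\mathrm{round}(q\,|S|)$ mutations (round-half-up, minimum 1) taken with
  replacement and collapsed to sets. The two draws emulate two lesions
  sampling one ancestral clone at heterogeneity level $q$. The alternative
  reading — one draw reused for both lesions — is rejected: it would make
  every positive pair share 100% of its drawn mutations and could never
  produce sensitivity below 1 at any proportion.
* **negatives** (unrelated): whole mutation sets of two distinct samples,
  drawn uniformly; the pair count matches the positives, so a 505-sample
  reference with three proportions gives exactly 1515 of each.

Every pair is scored with the CI and the **accuracy-optimal cutoff** is
found by exhaustive search over the midpoints between adjacent distinct CI
values plus sentinels beyond both extremes; a pair is called clonal when
$\mathrm{CI} > \text{cutoff}$. Accuracy ties are broken toward the highest
candidate cutoff, which favors specificity over sensitivity — the
appropriate asymmetry when a false IPM call means over-staging a curable
primary. The search is implemented with sorted-vector `findInterval`
counting and is tested for exact agreement with a brute-force oracle.
AUROC is computed (via pROC) as a diagnostic only; the operative rule is
accuracy optimization.

The whole simulation is repeated (default 100 times; repetition $r$ seeds
its substream as `seed + r`) and summarized by the median cutoff and the
2.5/97.5 percentile interval (type-7 linear interpolation). The interval is
not just reporting: the classification rule below uses its upper bound as
the boundary of an explicit uncertainty band.

## The decision flow

Patients are first partitioned by sharing structure (`assign_group()`):
group 1 — at least one lesion has no detected mutations; group 2 — the
lesions share at least one key; group 3 — both have mutations but share
none. Groups 1 and 3 are MSLC outright. For group 2, `classify_pair()`
applies a three-branch rule rather than a bare threshold:

1. $\mathrm{CI} \le$ median cutoff → **MSLC** (the boundary belongs to
   MSLC);
2. $\mathrm{CI} >$ the calibration interval's upper bound *and* the shared
   set contains at least one passenger (a key neither flagged as a hotspot
   nor in a driver gene) → **IPM**;
3. otherwise → **ambiguous**, flagged for clinical review. This covers both
   a CI inside the cutoff's uncertainty band and the characteristic
   confound of this problem: a pair whose only sharing is a driver hotspot
   can exceed the cutoff on hotspot arithmetic alone without any
   identity-by-descent evidence.

A bare threshold cannot reproduce the published behavior of this class of
test (pairs slightly above a cutoff called either way depending on *what*
is shared); making the unresolvable zone explicit, instead of silently
choosing, is the package's position on that open question. Every call
records its rule branch, the cutoffs used and the shared keys so an
auditor can apply an alternative rule to the same evidence. The driver
gene set (default EGFR, KRAS, BRAF, ERBB2, MET, ALK, RET, ROS1, TP53) and
optional hotspot keys are configuration (`driver_config()`, shipped
editable default in `inst/extdata/drivers.tsv`), not code.

## The synthetic cohorts

No patient-level data are redistributable here, so `generate_reference()`
and `generate_paired_cohort()` build the study conditions from scratch,
with all randomness flowing from a single spec seed:

* **Reference**: each sample carries each of 9 classical driver hotspots
  independently with prevalences 0.005–0.12 (KRAS G12C at the top, ERBB2
  insertions at the bottom — the shape, not the exact values, of an
  adenocarcinoma cohort), plus a Poisson(20) number of passengers drawn
  from a 200,000-locus universe. Poisson mean 20 over a 2.2 Mb panel
  footprint corresponds to a TMB around 9/Mb, typical of smoking-associated
  adenocarcinoma through a broad targeted panel; 7% of passengers are
  emitted as synonymous to exercise the inclusion policy. Passenger loci
  map deterministically onto plausible MAF fields (`SYNGENE*` genes, fake
  coordinates) so the generated cohorts exercise the real MAF reader and
  genomic keying end to end.
* **Paired cohort**: 200 patients, 15% IPM. An IPM patient's two lesions
  subsample one parent tumor at a fraction drawn from 0.4–0.8 — mirroring
  the positive-pair construction, so calibration and evaluation share a
  heterogeneity model. An MSLC patient's lesions are independent draws,
  with 12% of pairs forced to share one prevalence-weighted driver hotspot
  so that the decision rule's hotspot-only branch is actually exercised
  (roughly 10–20% of MSLC pairs land in group 2, matching the structure of
  real cohorts where a sizable minority of independent pairs share only
  EGFR L858R).

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: driver mutual exclusivity (hotspots are drawn
independently, so synthetic tumors can carry EGFR and KRAS together —
`check_driver_exclusivity()` will flag them); mutational signatures and
regional mutation-rate variation (passengers are uniform over the
universe, making coincidental passenger sharing rarer than in, say, a
hypermutated cohort); copy-number and structural variation beyond keyed
events; and sequencing noise (no false-positive/false-negative calls, so
real-world sensitivity to variant-calling quality is untested). Group 1
(mutation-free lesions) also never arises from the generator, because
every simulated lesion keeps at least one mutation; the group-1 path is
tested with constructed fixtures instead.

## Numerical choices

* CI is accumulated as a sum of $-\log_{10} P$ (via `dbinom(log = TRUE)`),
  never as a product of probabilities: a pair sharing 40 floor-prevalence
  mutations has a product near $10^{-320}$, at the edge of double range.
  Log-space and direct-product computation are cross-checked to $10^{-9}$
  relative tolerance in the regime where both are representable.
* Subsample sizes use round-half-up with a floor of one pick, so small
  mutation sets are never subsampled to nothing.
* Candidate cutoffs are midpoints, so the returned cutoff is never an
  observed score and `>` vs `>=` at the cutoff cannot flip calls for the
  calibration data itself; for study pairs, exact equality with the median
  cutoff is resolved to MSLC.
* Percentiles use R's default type-7 interpolation; with `reps = 1` the
  median and both interval bounds collapse onto the single cutoff.
* All seeds stay in 32-bit integer range; `calibrate()` derives one
  substream per repetition, so per-repetition results are reproducible
  independent of repetition count.

## Problem sizes

The shipped analysis (`analysis/01`–`05`) and the acceptance script run a
505-sample reference (matching the reference pool size the pair-count
contract is stated for), 100 calibration repetitions (1515 + 1515 pairs
per repetition) and a 200-patient study cohort; the test suite uses the
same machinery at 15–200 samples and 1–25 repetitions. These sizes were
chosen as the smallest at which the Monte-Carlo summaries are stable to
well under the decision margins involved; nothing in the implementation is
specific to them.

## Known limitations

* The binomial exponent, the prevalence estimator and the mutation-identity
  mode are all under-determined by the source description of this class of
  analysis; the package makes each an explicit, logged knob rather than
  asserting one resolution. Calibrated cutoffs are therefore *not*
  transferable across configurations — recalibrate whenever any knob or the
  reference cohort changes.
* Prevalence estimates for rare mutations are dominated by the smoothing
  floor, so the CI of a passenger-sharing pair is effectively
  "count of shared passengers × constant"; with a small reference cohort
  the constant is small and the separation between classes narrows.
* The independence assumption across shared mutations is optimistic for
  mutations in the same signature context; CI values for heavily mutated
  pairs are best read as ranks, not probabilities.
* Tumor purity, sequencing depth and panel design shift which mutations
  are *detected*, and the index only sees detected mutations; a shallow
  lesion can push a truly clonal pair toward group 3.
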