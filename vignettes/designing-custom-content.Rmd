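---
title: "Designing custom fine-mapping array content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing custom fine-mapping array content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finearray)
library(dplyr)
```

## The problem

Genome-wide association studies of complex disease — the motivating case
is multiple sclerosis, with roughly 200 autosomal non-MHC risk signals
identified in European cohorts — leave the causal variant at most loci
unresolved. Fine-mapping in admixed populations (Hispanic, African
American) is attractive because their smaller LD blocks can separate a
causal variant from its proxies, but it needs genotypes at candidate
variants that standard arrays do not carry. `finearray` builds the
custom variant list for such an array: given index association signals,
their replication summary statistics in Hispanic (AMR) and African
American (AA) samples, reference genotype panels, variant annotations, a
base-array manifest, designability scores and imputation INFO scores, it
runs a deterministic two-arm filter cascade and emits the prioritized
content with full provenance and a per-stage funnel report.

The two arms target complementary genetic architectures:

* **Coding/regulatory arm** — robust to allelic and locus heterogeneity.
  Within 1 Mb of each index signal and across the MHC (chr6:27–34 Mb,
  GRCh37), keep common variants that are protein-altering or have strong
  regulatory evidence, regardless of LD with the index.
* **Fine-mapping (LD) arm** — assumes a shared causal variant. Around
  each autosomal non-MHC signal, keep variants in LD with the index,
  where the population pools in which LD is required depend on the
  signal's replication status.

## Regions

Each signal's window is `[pos − 1 Mb, pos + 1 Mb]`, clipped at
position 1 (chromosome-end clipping beyond that is not attempted — end
coordinates vary by build and the windows in practice sit far from
telomeres). Windows on one chromosome that overlap *or abut* (gap of
zero) are merged; merging abutting windows is what lets ~200 signals
span ~156 distinct loci. All internal coordinates are 1-based inclusive;
BED exports convert to 0-based half-open.

```{r regions}
signals <- tibble(chrom = "1", pos = c(5000000L, 5500000L),
                  ref = "A", alt = "G")
build_regions(signals)
```

## The coding/regulatory arm

Four parameters, all overridable in `design_config()`:

| parameter | default | meaning |
|---|---|---|
| MAF gate | AFR > 0.01, AMR > 0.01, NFE > 0.05, EAS > 0.05 | strict disjunction: any one population suffices |
| `min_cadd` | 30 (CADD phred) | inclusive; top 0.1% most deleterious |
| RegulomeDB set | 1a–1e | eQTL + transcription-factor binding evidence |
| effect classes | nonsynonymous, stop-gain/loss, splicing | from the annotation table |

The frequency list is read as a disjunction because the arm's purpose is
power in *some* study population, with the lower AFR/AMR bound
reflecting the admixed cohorts of interest; a missing frequency never
passes. The bounds follow their operators exactly: frequency strictly
`>`, CADD `>= 30`. A variant may satisfy several criteria; it is emitted
once with multi-tag provenance (`crit_effect`, `crit_cadd`,
`crit_regulome`) so per-criterion counts stay computable. Base-array
overlap is matched on position plus *unordered* allele set; strand
flipping and TOP/BOT normalisation are deliberately out of scope (real
manifests differ in convention — a documented limitation), as is
lift-over between builds. Tri-allelic variants are excluded, but only
after being carried through with an explicit flag so funnel counts stay
auditable.

## Replication status and the LD requirement

Replication inputs are per-population effect signs and two-sided
p-values, the form in which summary statistics are usually published.
The one-sided p testing the discovery direction is derived as
`p/2` when the signs agree and `1 − p/2` otherwise. Each signal is
classed:

* `BOTH` — one-sided p ≤ 0.05 in AMR *and* AA → r² ≥ 0.1 with the index
  required in **all** of NFE, AMR, AA;
* `ONE`(pop) — one-sided p ≤ 0.05 in exactly one pool → required in NFE
  **and** that pool;
* `OPPOSITE`(pop) — two-sided p ≤ 0.10 with an effect sign opposite to
  discovery → required in NFE **or** that pool (LD structures evidently
  diverge, so either pool's proxies are informative);
* `NONE` — otherwise → NFE only.

Two genuinely open choices were settled as follows. Precedence is
`BOTH > OPPOSITE > ONE > NONE` (configurable): opposite-direction
evidence outranks single-sample replication because it indicates
LD-structure divergence and triggers the more permissive OR rule. If
both populations qualify for a population-specific class, the smaller
relevant p-value picks the population (ties go to AMR, the larger
replication sample). Missing data never satisfies any test, and sign
alone — without p ≤ 0.10 — never triggers `OPPOSITE`.

## r² estimation

For phased panels, the four gamete frequencies are counted directly and

$$r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad D = p_{AB} - p_A p_B.$$

For unphased genotypes, gamete frequencies are maximum-likelihood
estimates from the 3×3 two-locus genotype table under random union of
gametes. Only the double-heterozygote cell is phase-ambiguous; the EM
step splits it by the expected coupling share
$p_{AB}p_{ab} / (p_{AB}p_{ab} + p_{Ab}p_{aB})$. Numerical choices:

* convergence when the largest frequency change is below `1e-12`, cap
  2000 iterations — tables whose optimum sits on the feasibility
  boundary of $p_{AB}$ approach it slowly, and a looser tolerance can
  leave the log-likelihood measurably (≈1e-6) short;
* the observed-data likelihood can be bimodal in D, so the EM runs from
  linkage equilibrium and from both feasibility extremes of $p_{AB}$ and
  keeps the best mode — deterministic, no random restarts. Exact ties
  (tables that cannot identify phase) return the equilibrium-basin
  solution flagged `tied`;
* an undefined r² (either locus monomorphic in a pool) **fails** the
  requirement rather than erroring: a variant cannot be in LD where it
  does not vary. This matters most for the smaller AA pool and is the
  conservative reading under ALL-combinators;
* threshold comparisons are inclusive (`r² ≥ 0.1`).

A practical note on how closely the unphased estimate tracks the phased
one: both are consistent, and on the same data they differ only through
double-heterozygote phase uncertainty. By the delta method the
difference has standard deviation roughly
$(2D/\text{denom})\cdot\sqrt{n_{dh}\,c(1-c)}/2n$, about 0.02 at 400
haplotypes for common variants with r² in 0.2–0.5. Per-pair agreement
much tighter than that at such sample sizes is not statistically
achievable; the two estimators converge as panels grow (the test suite
checks this at 50/200/1000+ individuals).

## Final pruning and bead accounting

After the arms are merged (a variant selected by both arms keeps one
record with merged provenance), three steps shape the list to the
physical array:

1. **Designability** — records scoring below `designability_min`
   (default 0.5; vendor scoring tools are proprietary, so the cutoff is
   a conventional choice) or with no score are dropped.
2. **Priority partition** — everything from the coding/regulatory arm,
   plus LD-arm content for signals that replicated in at least one
   sample (`BOTH`/`ONE`), is kept unconditionally; the rest is prunable.
3. **INFO pruning** — prunable variants with INFO score **above** a
   threshold t are excluded: a variant the base array already imputes
   well need not be genotyped directly, so pruning *retains* the
   poorly-imputed. t is searched on the grid of observed INFO values for
   the largest value whose retained set still fits the bead budget; if
   even the smallest grid value does not fit, nothing is retained (the
   reported threshold is then 0, and records with missing INFO — which
   are treated as 0, i.e. never excludable — are the one case that can
   make full retention impossible at any threshold).

The INFO score is the ratio-of-variances measure: with per-sample
genotype probabilities $(p_0, p_1, p_2)$, $e_i = p_{i1} + 2p_{i2}$,
$f_i = p_{i1} + 4p_{i2}$ and $\hat\theta = \sum e_i / 2N$,

$$\mathrm{INFO} = 1 - \frac{\sum_i (f_i - e_i^2)}{2N\,\hat\theta(1-\hat\theta)},$$

defined as 1 when $\hat\theta \in \{0, 1\}$ and clamped to [0, 1]; it is
exactly 1 on hard calls. Imputation softwares differ slightly in their
INFO variants; this is the standard ratio-of-variances form.

Bead accounting follows Infinium chemistry: strand-ambiguous SNPs (A/T,
C/G) and indels need the two-bead Infinium I assay, everything else one
bead (Infinium II). The rule is a function of the allele pair only;
per-variant overrides can be joined in before assembly if a vendor
manifest says otherwise.

## The synthetic study generator

Every pipeline input can be generated with controlled structure, so the
whole cascade is testable without downloads:

* **Panels** — default pool sizes are the 1000 Genomes replication pools
  behind the design: NFE 403, AMR 338, AA 149 diploid samples. Index
  haplotypes are Bernoulli draws at MAF 0.3 (a typical common-variant
  frequency); candidate alleles are drawn conditionally on the index
  allele from the exact four-gamete distribution with
  $D = \sqrt{r^2_{\text{target}}\,p_A(1-p_A)p_B(1-p_B)}$, so each pool's
  pairwise r² with the index is planted by construction. The default
  planted map per signal is (0.5, 0.2, 0.05) — one clear proxy, one just
  above the 0.1 bound, one clearly below.
* **Replication tables** — status mixes are specified per signal
  (e.g. a 2/9/1/8 mix over 20 signals, the published 16/85/5/94 split at
  one-tenth scale); p-values and signs are drawn inside ranges that the
  classifier maps back to the intended class, and the intended labels
  are emitted as a ground-truth sidecar so tests never re-derive
  expectations from generator internals.
* **Annotations/manifest/designability** — criterion flags are allocated
  exactly (`round(fraction × n)` keys per criterion, independently
  shuffled), again with a truth sidecar.

What the generator does **not** emulate: recombination maps, coalescent
genealogies, admixture LD, population structure within pools, allele
frequency spectra. Passing tests therefore demonstrate that the
selection logic is correct under known LD structure — not that any
particular real locus would yield a particular variant count; the
published absolute counts depend on external database versions and
unpublished replication data and are out of scope by design.

Haplotypes are drawn independently per individual, so Hardy–Weinberg
holds at the haplotype level, which is also the EM's model assumption;
real panels with structure violate this mildly (pooling subpopulations
into NFE/AMR/AA mirrors common practice and is a documented caveat).

## Problem sizes and determinism

The test suite runs the full pipeline on studies of 4–20 signals with
pools of 60–400 samples, EM checks on 200 random tables of 100–400
individuals against a 1-D likelihood grid search, and planted-recovery
experiments at 2,000 samples per pool — sized so that the ±0.05 planted
r² margin around the 0.1 bound is about four sampling standard
deviations, making 100% recovery/exclusion the correct expectation
rather than a coin flip. All generator randomness derives from a single
integer seed; identical seeds reproduce fixture files bit for bit, and
the pipeline itself contains no randomness.

## Known limitations

* Manifest matching ignores strand; an allele pair recorded on the
  opposite strand in a manifest will not be recognised as overlap.
* X-chromosome signals are out of scope (the motivating signal set is
  autosomal), as are D′, composite-LD estimators for structured samples,
  and any LD clumping beyond the single stated criterion.
* The iSelect-style designability score and the imputation INFO scores
  are consumed as inputs; the package neither scores probes nor imputes.
* Whether the frequency gate should also apply to the LD arm is left as
  a switch (`apply_frequency_filter_fine_mapping`, default off — the
  gate belongs to the coding/regulatory arm's power argument).
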