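---
title: "Methods: SNP-based relatedness, inbreeding and breeder selection"
author: "breedsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-based relatedness, inbreeding and breeder selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsel)
```

`breedsel` turns a multi-sample VCF of biallelic SNPs plus a sample
metadata table into the quantities a conservation-breeding manager needs:
who is inbred, who is related to whom, who is a hybrid, and which pairings
are safe. This vignette explains each model, its assumptions and tunable
parameters, the synthetic-data generator used for validation, and the
numerical choices made where the design was genuinely open.

## Data model

Genotypes are stored as alternate-allele counts in {0, 1, 2, NA}: `NA`
(missing) is a distinct state and never conflated with the homozygous
reference genotype. Half-calls such as `0/.` are conservatively treated as
missing, matching the downstream missingness filters. Coordinates are
1-based and inclusive throughout, as in VCF; chromosome order is a natural
sort of labels (chr2 before chr10), which makes all outputs deterministic
without needing a reference index.

## Quality control

Four filters run in a fixed order: samples with ≥ 15% missing calls are
dropped first; variant statistics are then recomputed on the survivors; and
variants are dropped when missingness exceeds 10% (strict), MAF falls below
0.05 (strict), or the Hardy–Weinberg exact p-value falls below 0.01.
Sample-before-variant ordering matters: a bad sample inflates every
variant's missingness, so removing it first keeps informative markers.
The boundary conventions mirror the usual "greater than" (variant
missingness) versus "at or above" (sample missingness) phrasing of such
filter sets, and each exclusion is recorded with its reason so a QC report
can be audited.

The HWE test is the two-sided conditional exact test over heterozygote
counts: given the allele counts, the probability of each feasible
heterozygote count follows the Levene–Haldane distribution, and the p-value
sums the probabilities of all outcomes no more probable than the observed
one. Probabilities are computed by a log-space recurrence from the smallest
feasible heterozygote count, which is numerically stable beyond 10^4
genotypes; the plain exact p (not mid-p) is used, matching the default of
the widely used implementations. The test suite checks the recurrence
against an independent closed-form enumeration for every genotype table
with up to 200 individuals.

## LD pruning

Pruning uses squared Pearson correlation of genotype dosages (composite
LD), not haplotype r², because input genotypes are unphased. Within each
sliding window (default 50 SNPs, advancing by 5) any pair with r² above
0.5 loses its later member — a deterministic, position-stable tie-break.
The defaults are the common `50 5 0.5` idiom; they are exposed in
`prune_params()` rather than hard-coded, since published analyses often
leave them unstated. Pairs with undefined correlation (monomorphic after
pairwise deletion, or fewer than two complete pairs) never trigger removal.

## Heterozygosity and the moments inbreeding coefficient

For each sample, F̂ = (O_hom − E_hom)/(L − E_hom) over its L non-missing
markers, with the expected homozygosity computed from cohort allele
frequencies and the small-sample factor 2n/(2n−1) that removes the downward
bias of expected heterozygosity at finite n. Frequencies come from the full
post-QC cohort, not per-subpopulation, matching the single-cohort semantics
of the standard tool chain; negative F̂ therefore signals heterozygosity
excess relative to the whole cohort (typical of hybrids). The estimator is
invariant to swapping REF/ALT labels. Subpopulation summaries report mean,
sample SD, min and max, plus pairwise Welch t-tests (headline) and
Mann–Whitney U tests — both, because the original analyses of this kind
rarely name their test.

## Pairwise IBD and relationship classes

For each pair the loci complete in both samples are tallied into IBS
states (equal genotypes = IBS2, opposite homozygotes = IBS0, otherwise
IBS1). Method-of-moments estimation then solves, in order, for the
proportions of loci with 0, 1 and 2 alleles shared identical-by-descent,
using the expected IBS-state probabilities at the cohort allele
frequencies; estimates are clamped to [0, 1] and renormalized to the
simplex, and π̂ = Ẑ₂ + Ẑ₁/2. The finite-sample correction factors of the
original estimator's appendix are deliberately not applied: plug-in cohort
frequencies keep the estimator fully specified here, and validation is by
pedigree recovery (parent–offspring and full sibs at π̂ ≈ 0.5, half sibs
≈ 0.25, unrelated ≈ 0) rather than byte-identity with any particular tool.

Relationship classes follow the conventional cut-offs: π̂ > 0.95 duplicate
or identical twin; ≥ 0.40 first-degree; ≥ 0.20 second-degree; ≥ 0.10
third-degree; below 0.10 unrelated. The boundaries are honored exactly as
stated ("greater than" for duplicates, "or more" for the rest).

The MDS view embeds D_ij = 1 − (IBS2 + ½·IBS1)/N_ij by classical
(Torgerson) scaling: double-center −½D², eigendecompose, scale the top
eigenvectors by the square roots of their eigenvalues. Negative eigenvalues
(non-Euclidean D) are truncated at zero, and each axis's sign is fixed so
its first nonzero loading is positive, making output deterministic.

## Runs of homozygosity

Detection is the sliding-window algorithm familiar from the R ROH
packages, with every parameter exposed and defaulting to the set used for
medium-density wildlife SNP data: windows of 15 SNPs, at most 1
heterozygous and 1 missing call per homozygous window; a SNP is in-run
when more than 5% of the full windows covering it are homozygous
(truncated windows are not formed at chromosome edges; the proportion uses
however many full windows cover the SNP); consecutive in-run SNPs form
candidate runs, split at inter-SNP gaps above 1 Mb; runs are kept with
≥ 20 SNPs, span ≥ 250 kb and ≥ 1 SNP per Mb of run length. Run length is
the distance between the terminal SNPs, consistent with the Mb arithmetic
of the dating formula. The minimum density is interpreted as SNPs per kb
of run length (1/1000 = one SNP per Mb) and is configurable, because the
source conventions are ambiguous on this point.

F_ROH divides summed run length by the SNP-covered map extent (per
chromosome, last minus first position) rather than an assembly length —
computable from the input alone; a genome-length override is available
when an assembly size is preferred. ROH should be detected on the post-QC
but *un-pruned* marker set: LD pruning deliberately destroys the local
marker density the window statistics rely on, and MAF filtering matters in
the other direction — near-fixed markers are homozygous in everyone and
inflate false runs (on simulated data, skipping the MAF filter produced
about 3% spurious F_ROH in outbred founders).

Tract lengths are binned into the five half-open classes 0–6, 6–12,
12–24, 24–48 and > 48 Mb, and dated by g = 100/(2rL): a tract of L Mb that
survived g generations of recombination at r cM/Mb has expected length
100/(2rg) Mb. The default r = 1.04 cM/Mb is a deer genome-wide average. A
24 Mb tract dates to just over two generations; a 50 Mb tract to less than
one.

## Admixture model

Each genotype is modeled as Binomial(2, p_il) with p_il = Σ_k q_ik f_kl,
where q_ik are per-sample ancestry fractions over K clusters and f_kl
per-cluster alternate-allele frequencies. The fit is by plain EM — the
block-relaxation accelerators of the original tool reach the same
stationary points but are far harder to verify; the iteration budget is
exposed instead (`max_iter`, default 2000). Missing genotypes are skipped
in every sum. Parameters are clipped to [10⁻⁶, 1−10⁻⁶]; the
log-likelihood (with the binomial coefficient, so K = 1 reduces exactly to
the closed-form binomial likelihood at pooled frequencies) is
non-decreasing across iterations, which the tests assert step by step.
Five seeded restarts are run by default and the best final likelihood
kept; all seeds are recorded in the fit object.

K is chosen by cross-validation over masked genotype *entries* (not
held-out individuals, which would be ill-defined for Q): a random fold of
non-missing entries is masked, the model refit, and the masked genotypes
scored by mean binomial deviance. Held-out predictions are smoothed away
from 0 and 1 at the Laplace pseudocount scale 1/(2N+2) before scoring —
without smoothing, a single unseen allele at a near-fixed marker
contributes an unbounded deviance term and can reverse the K ranking on
clearly clustered data. Fold assignment is deterministic given the seed.

Cluster labels are aligned to reference subpopulation labels by greedy
assignment maximizing the mean ancestry fraction per label (bijective when
K equals the label count; ties resolved by label sort order with a
warning). Purity calls operationalize "100% ancestry" with a numeric
tolerance — dominant fraction ≥ 0.999 — because interior-point clipping
makes a literal 1.0 unattainable; a non-dominant fraction above 0.40 flags
a sample as admixed, and anything between is low admixture.

## Breeder selection

Candidates and mates are opposite-sex pools, by default gated to purebred
individuals; unknown-sex samples are excluded from both pools with a
warning. "No genetic relationship" is strictly `rel_class == unrelated`
(π̂ < 0.10, on raw values, not percentage-rounded ones). Each candidate is
scored by the number of pool mates it is unrelated to and tiered:
unrelated to the whole pool, unrelated to more than 10 (the cutoff is
configurable), or other. Reports are female-centric as well as
male-centric, sorted by count then id, and are pure functions of their
inputs — rerunning reproduces identical bytes.

## The synthetic-data generator

The simulator provides exact ground truth rather than expectations.
Two subpopulations diverge under the Balding–Nichols model: ancestral
frequencies uniform on 0.05–0.95, subpopulation frequencies
Beta-distributed around them at a configurable Fst (default 0.2, a
subspecies-scale divergence). Pedigrees are gene-dropped with crossovers
placed as a Poisson process at 1.04 cM/Mb (crossover interference is
ignored — adequate for moments-level truth). Every founder haplotype
carries a unique label copied along with its alleles, so the generator
records *realized* quantities: pairwise IBD-state fractions and π̂ from
the labels (locus-weighted), autozygous segments (both labels equal), and
realized ancestry fractions (labels traced to founder subpopulation).
Recovery tests therefore compare estimates against what actually
segregated, not against pedigree expectations — important because realized
IBD on a 10-chromosome genome varies around its expectation by several
percent. Admixed individuals can also be generated directly with a
segment-ancestry process; note that its realized ancestry varies widely
around the target on small genomes, so tests needing exact 50:50 hybrids
cross pop1 × pop2 founders through the pedigree instead. Genotype errors
(replacement by another genotype) and missing calls (defaults 0.1% and
3–5%, comparable to a filtered RADseq call set) are applied last, to the
genotype matrix only, never to the truth.

Default missingness and error rates sit below the QC thresholds on
purpose: the generator emulates a call set *after* upstream variant
calling, the pipeline's actual entry point. What the simulator does not
emulate: linkage-aware ascertainment of markers, allele-specific error
biases, batch effects between sequencing runs, and deep coalescent
structure within subpopulations. Passing recovery tests therefore show the
estimators are correct for well-behaved diploid SNP data, not that any
particular empirical call set meets those assumptions.

## Problem sizes and numerical choices

The shipped validation uses cohorts of a few hundred individuals at
2,000–10,000 markers over 2–20 chromosomes — sizes chosen so realized
quantities are tight enough to verify estimator calibration (standard
errors of a few percent) while keeping the whole suite quick on a laptop.
Degenerate inputs are handled explicitly: all-missing variants fail MAF
with an undefined frequency; monomorphic marker panels make the moments
IBD system singular and raise an error naming the pair; an all-monomorphic
cohort makes F̂ undefined (reported as NA); chromosomes with fewer SNPs
than the ROH window warn and yield no runs; empty candidate pools warn and
produce an empty report.

## Pipeline and reproducibility

`run_pipeline()` executes the stages in a fixed order, writes every
artifact as TSV with a `#`-commented header, echoes the resolved
configuration as YAML, and records a manifest (file, rows, md5). One
master seed drives every stochastic stage, and rerunning an identical
configuration reproduces identical checksums. The package's functions are
the interface — there is no shell wrapper; `scripts/acceptance.R` shows
the intended non-interactive usage.

## Known limitations

The IBD moments estimator assumes a homogeneous reference cohort for its
allele frequencies; strong structure inflates π̂ between members of the
same subpopulation (visible in the study-like demo, where it is the
qualitative contrast between herds that is meaningful). The admixture EM
is slower than accelerated implementations and, like them, has no
guarantee against label-degenerate local optima — hence seeded restarts.
F_ROH depends on the chosen denominator; with sparse maps the SNP-covered
extent understates the genome and F_ROH is correspondingly conservative.
Confidence intervals are not provided for Q or π̂.
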