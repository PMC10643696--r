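# breedsel

Genome-wide SNP analysis for selecting breeders in conservation programs of
small captive populations.

Captive populations of endangered species — the motivating case is the two
subspecies of Eld's deer (*Rucervus eldii*) kept in Thai breeding centres —
are often founded by a handful of animals, so managers must pick breeding
pairs that are genetically unrelated, avoid hybrids between management
units, and monitor inbreeding. `breedsel` implements that workflow as a
single R pipeline over a multi-sample VCF of biallelic SNPs:

1. **Quality control** — per-variant missingness (> 10% excluded), minor
   allele frequency (MAF < 0.05 excluded), Hardy–Weinberg exact test
   (p < 0.01 excluded, Wigginton-style conditional test over heterozygote
   counts), and per-sample call rate (≥ 15% missing excluded), in that
   order.
2. **LD pruning** — windowed pairwise genotype r² (default
   window 50 SNPs / step 5 / r² > 0.5 removes the later variant).
3. **Diversity and inbreeding** — per-individual heterozygosity and the
   method-of-moments genomic inbreeding coefficient
   F̂ = (O_hom − E_hom)/(L − E_hom), with subpopulation summaries and
   Welch / Mann–Whitney comparisons.
4. **Relatedness** — identity-by-state counts, method-of-moments IBD
   estimates (Ẑ₀, Ẑ₁, Ẑ₂) and π̂ = Ẑ₂ + Ẑ₁/2 per pair, classified as
   duplicate/twin (> 0.95), first- (≥ 0.40), second- (≥ 0.20),
   third-degree (≥ 0.10) or unrelated (< 0.10); classical MDS of the
   IBS-sharing distance.
5. **Runs of homozygosity** — sliding-window detection (15-SNP windows,
   ≤ 1 heterozygous and ≤ 1 missing call per window, ≥ 20 SNPs, ≥ 250 kb,
   gap ≤ 1 Mb, ≥ 1 SNP/Mb), F_ROH, the five tract-length classes
   (0–6, 6–12, 12–24, 24–48, > 48 Mb), and generation dating of tracts by
   g = 100/(2rL) with r = 1.04 cM/Mb.
6. **Ancestry** — an admixture model (genotype ~ Binomial(2, Σₖ q_ik f_kl))
   fitted by EM with seeded restarts, cross-validation over K, cluster
   alignment to reference labels, and purity calls (purebred /
   low-admixture / admixed at a 40% flag).
7. **Breeder selection** — candidate ranking by the number of opposite-sex,
   purity-gated pool members with which a candidate is unrelated
   (π̂ < 0.10), tiered as in management reports ("unrelated to all",
   "unrelated to more than 10").

A gene-dropping pedigree simulator (Balding–Nichols divergence between two
subpopulations, Poisson recombination, tracked founder alleles) supplies
exact realized truth — pairwise IBD, autozygous segments, ancestry
fractions — for every estimator, and is what the test suite validates the
pipeline against.

## Worked example

```r
library(breedsel)

# simulate a study-like cohort: an inbred 3-founder herd, an outbred
# 11-founder herd, and two F1 hybrids
dd <- sim_study_scenario(seed = 301)

qc  <- apply_filters(dd$geno, dd$variants, filter_params(hwe_alpha = 1e-4))
kept <- ld_prune(qc$geno, qc$variants, prune_params(20, 5, 0.5))
geno <- qc$geno[, kept]

div <- diversity_table(geno)
herd <- dd$samples$subpopulation[match(div$sample_id, dd$samples$sample_id)]
round(tapply(div$het_rate, herd, mean), 3)
#> BEDlike  hybrid SEDlike
#>   0.360   0.413   0.344
round(tapply(div$f_hat, herd, mean), 3)
#> BEDlike  hybrid SEDlike
#>   0.032  -0.112   0.074

pairs <- snp_relatedness(geno)
subset(pairs, id1 == "SED_G2a" & id2 == "SED_G2b",
       select = c(id1, id2, pi_hat, rel_class))
#>         id1     id2    pi_hat    rel_class
#> 265 SED_G2a SED_G2b 0.4117159 first_degree
```

The inbred herd shows depressed heterozygosity and elevated F̂ relative to
the outbred herd, the hybrids an excess of heterozygosity (negative F̂),
and the full sibs `SED_G2a`/`SED_G2b` are recovered as a first-degree pair. `run_pipeline(run_config(...))` performs
the same stages end to end from a VCF plus metadata TSV and writes every
report (QC, diversity, IBD pairs, MDS, ROH, ancestry Q/P, purity, breeder
tiers) with a checksummed manifest.

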