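---
title: "Methods: population genomics of divergence, domestication and introgression in tetraploid cottons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of divergence, domestication and introgression in tetraploid cottons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cottonpop)
```

## Scope and model

cottonpop implements the statistical core of a resequencing-style
population-genomic analysis for the two cultivated allotetraploid cottons,
*Gossypium hirsutum* (Upland cotton) and *G. barbadense* (extra-long-staple
cotton). The two species carry homologous A and D subgenomes from a single
ancient hybridization; reads are assumed to have been assigned uniquely to
one subgenome before genotyping, so genotypes are ordinary diploid
alternate-allele counts (0/1/2) on subgenome-tagged chromosomes, and
tetraploidy enters the analysis only through the chromosome complement and
the homoeolog map. Every analysis is driven by an accession panel that
splits the accessions into *G. hirsutum* races (wild-proximal forms),
*G. hirsutum* cultivars, *G. barbadense* cultivars, and an outgroup.

The pipeline stages are:

1. **Variant filtering** — non-singleton rule, minor-allele-frequency and
   missing-rate thresholds, and random thinning of sites closer than 10 bp
   (clustered polymorphism is enriched for homoeologous mis-mapping).
2. **SNP classification** — intraspecific versus *nearly fixed
   interspecific* sites (alternate-allele frequency above 95% in one
   species and below 5% in the other).
3. **Windowed diversity and differentiation** — nucleotide diversity
   (&pi;) and Hudson F~ST~ in 100-kb windows.
4. **Selective-sweep scan** — the &pi;~race~/&pi;~cultivar~ ratio with
   masking, a threshold of 25, permutation false-positive estimation,
   homoeologous sweep pairing, and QTL overlap.
5. **Introgression detection** — per-1-Mb-block neighbor-joining trees on
   simple-matching distances, misplaced-accession calling, event support
   thresholds, and direction/subgenome bias tests, plus the f3
   three-population admixture statistic.
6. **Structure** — genome-wide simple-matching distances, an NJ tree and
   variance-normalised PCA.
7. **Expression rules** — tissue-specificity by t-interval and a
   domesticated-versus-wild Fisher/fold-change rule.

## Estimators and their assumptions

**Nucleotide diversity.** Per site the unbiased heterozygosity
$\hat\pi_s = 2\hat p (1-\hat p)\,n/(n-1)$ is used, with $\hat p$ the
population alternate-allele frequency and $n$ the number of called alleles;
window &pi; is the sum over variant sites divided by the *full* window
length, i.e. positions without a variant record are treated as monomorphic.
This equals the mean pairwise allele difference (sampling alleles without
replacement), which the test suite verifies against a brute-force pairwise
oracle. No callable-site mask is applied; if real data have heterogeneous
callability the absolute &pi; values are biased downward, though ratios of
&pi; between groups over the same windows are not.

**F~ST~.** Hudson's two-population estimator, windowed as a ratio of sums
(numerator $(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$ over
denominator $p_1(1-p_2)+p_2(1-p_1)$). It is robust to unequal sample sizes
and reaches 1 only under reciprocal fixation.

**Sweep scan.** Windows with diversity below 0.001/bp in *both* races and
cultivars are masked before the ratio is formed; windows whose cultivar
diversity is exactly zero while the race diversity qualifies receive an
infinite ratio that sorts above any finite signal (real data rarely hit
exact zero; desk-scale simulations can). Windows with ratio strictly
above the threshold (default 25) merge into sweep regions only when
directly adjacent; a masked or sub-threshold window breaks the region.
This is the simplest deterministic merge rule; a different rule would
change region counts but not the set of implicated windows. The
permutation test shuffles race/cultivar labels with group sizes preserved
and reports the per-window exceedance fraction, the direct interpretation
of a per-window false-positive rate (not a max-statistic family-wise
rate). QTL "overlap" is strict half-open interval intersection with a
configurable flank defaulting to 0 bp, since no flank distance is
standard.

**Ka/Ks.** Synonymous and nonsynonymous SNP counts are normalised by NG86
codon site counts computed from the CDS; this is a count ratio over SNP
classes, not a divergence model — no multiple-hit correction is applied,
which is appropriate for intraspecific polymorphism data.

**Simple-matching distance and NJ.** The genetic distance between two
accessions is one minus the fraction of jointly called sites with
identical genotype states (pairwise-complete in the presence of missing
data; how missing sites are treated is a choice — pairwise-complete keeps
every accession comparable at the cost of slightly different effective
site sets per pair). Neighbor joining follows Saitou–Nei with the
Studier–Keppler criterion; on ties the lowest-index pair is joined, which
makes the tree deterministic for a fixed input. Negative branch-length
estimates are kept as computed so that path lengths remain additive; the
suite checks exact recovery of additive matrices and agreement with an
independent NJ implementation.

**Introgression calling.** Within each 1-Mb block a rooted (on the
outgroup) NJ tree is scanned for accessions of one species placed in the
other species' clade. The "clade" of a species is operationalised as its
*core clade*: the rooted clade maximising the net species content (species
tips minus alien tips), among clades containing at least 80% of the
species, no outgroup tip, and a strict majority of species tips. Two
failure modes drove this choice. A "smallest clade containing 90%" rule
balloons across the entire other species as soon as more than 10% of a
species is introgressed in one block, and it can also trim introgressed
accessions that nest basally inside the clade. Secondly, an introgressed
accession sometimes attaches as the immediate *sister* of the donor
species' clade rather than inside it; such accessions — left outside their
own species' core — are assigned to whichever core clade is closer in mean
patristic distance. Both the 0.8 core fraction and the 0.5 purity are
exposed parameters. One event is called per block and direction when at
least two accessions support it; a hirsutum accession placed among
barbadense carries barbadense-like sequence, so it records gene flow from
barbadense into hirsutum.

**Direction and subgenome bias.** The observed event counts in the two
directions (or the two subgenomes) are tested against a balanced
expectation in the 2×2 table `[[n1, n2], [E, E]]`, `E = round((n1+n2)/2)`.
Two routes are provided. The default is the Pearson chi-square without
continuity correction; `method = "fisher"` gives the two-sided exact test
by hypergeometric point-probability summation. On the published cotton
event counts (265 vs 119 and 250 vs 134) the chi-square route reproduces
the p-values reported for this design (8.04e-08 and 2.29e-05) exactly to
their printed precision, while the exact test gives slightly larger values
(1.09e-07 and 3.05e-05) that agree with an independent enumeration oracle;
the conclusions are identical. Both routes are kept so that users can
report either.

**f3 statistic.** $f_3(C;A,B)$ is the ratio-of-sums over sites of
$(c-a)(c-b) - \hat h_C/n_C$ to the unbiased target heterozygosity
$\hat h_C = 2c(1-c)\,n_C/(n_C-1)$, with standard error and Z score from a
delete-one block jackknife over contiguous 1-Mb blocks (matching the
analysis block size). Without allele counts the uncorrected product and
$2c(1-c)$ are used. A significantly negative f3 indicates the target is a
mixture of A-like and B-like ancestry; under pure drift its expectation is
positive.

**PCA.** EIGENSTRAT-style: columns centred by $2\hat p$ and scaled by
$\sqrt{\hat p(1-\hat p)}$, missing entries mean-imputed (zero after
centring), eigendecomposition of the accession covariance, and each
component's sign fixed so its largest-magnitude loading is positive.
Mean imputation is the simplest choice consistent with not modelling
linkage; genotype imputation from haplotype structure is out of scope.

**Expression rules.** A gene is "special tissue-related" when one
tissue's FPKM falls outside the two-sided 95% t-interval of the other
tissues. The interval is a *prediction* interval
($\bar x \pm t_{0.975}\, s \sqrt{1+1/k}$) by default because the question
is whether one observation is consistent with the spread of the others; a
mean-confidence interval (`interval = "mean"`) is far narrower and flags
most genes at realistic noise levels. The domesticated-versus-wild rule
calls a gene when a two-sided Fisher exact test on read counts gives
p < 0.05 *and* FPKM fold change exceeds 2, with the direction recorded.

## The synthetic data generator

All tests run on synthetic panels from a hierarchical Balding–Nichols
model: ancestral frequencies uniform on (0.05, 0.95); the two species
drift from the ancestor with coefficient `f_species`; a configurable
fraction of sites is instead set to alternate fixation between the
species; the three groups drift further from their species frequencies;
the outgroup drifts heavily from the ancestor; genotypes are
Binomial(2, frequency) with missingness masked at random. A drift
coefficient `F` multiplies expected heterozygosity by `1 − F`, so group
diversity ratios are set directly by the `F` values.

Default study conditions (chosen once, as the conditions the analysis
assumes, and used by the acceptance checks):

| parameter | default | rationale |
|---|---|---|
| layout | 4 chromosomes (A01, A02, D01, D02) × 2 Mb | desk-scale stand-in for 26 chromosomes / 1.9 Gb; full scale reachable via `genome_layout()` |
| accessions | 16 races, 24 hirsutum cultivars, 24 barbadense, 3 outgroup | proportions of the real 147-accession panel at a third of its size |
| `snp_density` | 15 /kb | calibrated so realized race diversity is ≈ 0.002/bp, the empirical scale for races; at ~5 /kb the simulated diversity sits below the 0.001 masking floor and the sweep scan is vacuous |
| `f_race`, `f_cultivar` | 0.25, 0.75 | cultivar drift triple the race drift gives an expected cultivar/race diversity ratio of 1/3, matching the ~34% domestication bottleneck |
| `f_barbadense` | 0.5 | intermediate: an all-cultivated species without a wild-proximal group |
| `fixed_diff_fraction` | 0.3 | ≈ the 34.4% nearly-fixed share of common SNPs |
| `f_species` | 0.1 | modest extra species drift beyond the fixed differences |
| `missing_rate` | 0.05 | comparable to the reported missing-data rate |

With these conditions the realized species-level F~ST~ is ≈ 0.75, somewhat
above the 0.63–0.65 reported for the real panel: the bottleneck and the
fixed-difference share jointly overdetermine F~ST~ in a pure-drift model
with no recombination or mutation-rate heterogeneity, and matching all
three quantities simultaneously would require a richer demographic model
than the frequency-based statistics under test need.

Sweeps are planted by redrawing cultivar genotypes from frequencies pushed
a fraction `suppression` of the way to fixation of the window's major
allele; `suppression = 0.97` targets a realized ratio near 50 under the
default drift settings (the cultivar heterozygosity shrinks by roughly
`2(1 − suppression)` at intermediate frequencies, on a baseline ratio of
3). Introgression blocks are planted by redrawing recipient genotypes from
the donor species' realized frequencies across the block, the block-sized
tract being an assumption — no empirical tract-length distribution is
modelled. Linkage exists only through these block-level operations; there
is no recombination map, so LD decay in the simulator is flat rather than
distance-dependent, and LD tests only check null behaviour and perfect
correlation. Gene models are single-exon ORFs on a generated reference
with variant effects recorded at planting time; expression matrices are
log-normal with one inflated tissue for a planted fraction of genes.
Truth tables (group frequencies, site classes, planted windows, events,
effects, tissue-specific genes) accompany every run.

What passing tests therefore do show: the estimators implement their
formulas exactly (oracle checks), the scan and the block-phylogeny calls
recover planted signals of realistic magnitude at the stated thresholds,
and the statistical tests hold their nominal levels under the null. What
they do not show: behaviour under read-level artefacts, callability
variation, linkage-driven backgrounds, or demographic histories richer
than drift — conclusions about real cotton data still require the usual
caution.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; VCF/GFF are
  1-based at the boundary, BED is native. Conversions are involutive.
* Allele frequency = alternate-allele count / called-allele count;
  missing genotypes never enter denominators.
* The non-singleton rule keeps sites with the alternate allele in ≥ 2
  accessions; the threshold is a parameter because both "at least two"
  and "more than two" readings circulate for this filter.
* The MAF/missing filter is applied over all accessions (not per
  species), with strict inequalities (`MAF > 0.05`, `missing < 0.10`).
* The spacing filter removes a uniformly random member of the closest
  conflicting pair, repeatedly, independently within each run of
  close sites; it is reproducible from its seed.
* The sweep threshold is strict (`ratio > 25`), as is the window mask
  (`< 0.001` in both groups).
* All randomness (simulation, planting, spacing filter, permutations)
  flows through per-stage seeds derived from one master seed in the
  pipeline runners; reruns are checksum-identical.
* Problem sizes in the shipped tests: unit tests run on 0.8-Mb genomes
  (~12k sites); the acceptance-style checks run the default 8-Mb
  desk-scale conditions with 10–20 replicate seeds and 200 permutations.

## Known limitations

* STRUCTURE-style admixture proportions are not implemented; group
  separation is validated through the tree and PCA only.
* The Fisher-versus-chi-square duality of the bias test (above) means
  users comparing against published cotton numbers should use the
  default chi-square route.
* The f3 implementation uses allele-frequency blocks on the genotype
  matrix; it does not read TreeMix input formats.
* Indel effect annotation classifies by length and CDS overlap only; it
  does not recompute the downstream protein.
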