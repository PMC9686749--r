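---
title: "Conservation genomics of small herds: models and methods in herdgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation genomics of small herds: models and methods in herdgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdgen)
```

## The problem

A conservation herd of an endangered livestock breed — a few dozen animals,
a handful of breeding males — is genotyped on a medium-density SNP array.
The management questions are concrete: which samples are accidental
duplicates, how much diversity is left, how inbred is each animal, who is
related to whom, and how should the herd be split into sire families so
that within-family matings can be avoided. `herdgen` implements that
analysis chain for biallelic autosomal SNP-array data in the cattle
convention (autosomes 1–29, plus X, Y and "0" for unplaced markers),
together with a pedigree-structured simulator that generates cohorts with
known truth, so that every stage of the chain can be validated
quantitatively rather than by inspection.

## Genotype model

Genotypes live in a samples × markers integer matrix of alternate-allele
dosages (0, 1, 2, `NA` for a missing call), with per-marker metadata
(chromosome, physical position, alleles, indel flag). Dosage counts copies
of `allele_b`, defined as the *second allele observed* scanning samples in
order — not the minor allele, whose identity can change when samples are
filtered. The constructor normalises coding to observation order, which
makes writing to PLINK text PED/MAP and reading back an exact identity;
`subset_genotypes()` deliberately does *not* re-normalise, so filtering
never silently flips the coding of surviving markers. All downstream
statistics are invariant to coding flips (this is property-tested).

Positions are 1-based; segment lengths are computed as `end − start`.

## Quality control

QC follows standard chip practice in a fixed order:

1. **Duplicate samples.** Pairwise DST similarity,
   `DST = (N_IBS2 + 0.5 N_IBS1) / N_valid` over markers called in both
   samples; pairs at DST ≥ 0.99 are the same animal. Within each connected
   group of mutual duplicates the member with the highest call rate is
   kept (ties: lexicographically smaller id, so reruns are deterministic).
2. **Sample call rate** < 0.90 removes the sample. This runs before marker
   statistics so that failing samples cannot distort them.
3. **Marker filters**, each evaluated independently on the post-sample-QC
   set: MAF < 0.01 (strict; a marker at exactly 0.01 survives),
   Hardy–Weinberg exact p < 1e-6, call rate < 0.90, non-autosomal
   chromosome (X, Y, unplaced), insertion/deletion.

The report gives *marginal* per-rule counts plus the joint survivor count.
Published chip-QC tables have the same shape, and their per-rule counts
generally do not sum to the number removed because rules overlap; the
report makes that explicit instead of pretending additivity.

The Hardy–Weinberg test is the conditional exact test: given the observed
allele counts, the heterozygote count h has probability
∝ N! / (n_a! h! n_b!) · 2^h over feasible h of the correct parity, and the
p-value sums all outcomes no more likely than the observed one (no mid-p
correction). It is computed in log space with a 1e-9 relative guard on the
"no more likely" comparison so that exact probability ties are not split
by floating-point rounding. The test suite checks it against a full
multinomial enumeration for every genotype triple with N ≤ 50 at 1e-12.

Whether a real study would test HWE before or after duplicate removal is
rarely stated; here HWE (like all marker statistics) uses the
post-duplicate-removal samples, since duplicate genomes would count
evidence twice.

## Diversity statistics

Per marker, with `p` the allele-b frequency over non-missing calls:
observed heterozygosity `Ho = n_het / n_valid`, expected heterozygosity
`He = 2p(1−p)`, Botstein's polymorphism information content in its
biallelic form `PIC = 1 − (p² + q²) − 2p²q²` (maximum 0.375 at p = 0.5),
and the effective number of alleles as reciprocal expected homozygosity
`Ae = 1/(p² + q²)` (range 1–2 for biallelic markers). The proportion of
polymorphic markers (PN) uses the post-sample-QC, *pre*-marker-QC set:
after the MAF filter every survivor is polymorphic by construction and PN
would be identically 1, which is not the quantity herd reports actually
tabulate.

**Effective population size.** LD-based, via Sved's relation
`E[r²] ≈ 1/(1 + 4 Ne c)`. r² is the squared Pearson correlation of dosage
vectors (composite/genotypic LD — chip data are unphased, and no EM
haplotyping is attempted). Marker pairs are formed within chromosomes,
physical distance is converted at a constant map rate (default 1 cM/Mb),
pairs are binned by genetic distance (default: 10 log-spaced bins over
0.5–10 cM), and per bin
`Ne = (1/(mean r² − 1/(2n)) − 1) / (4 c̄)` with `c̄` the bin midpoint and
`1/(2n)` the finite-sample correction. Markers below MAF 0.05 are excluded
from pairing, the usual practice for LD-based Ne since rare alleles make
r² estimates noisy. No extrapolation to Ne trajectories over past
generations is attempted — the estimate is reported per distance bin.

The estimator is validated against forward Wright–Fisher simulations
(`sim_wright_fisher`): a closed diploid population of true size N = 100
drifts for 200 generations on a 1-Morgan chromosome with 2000 markers;
50 sampled diploids per replicate. Over 10 replicates the mean estimate
at c̄ = 0.01 M must land within ±50% of the true N (it lands within ~10%
in practice). Drift-generated LD is exactly the signal Sved's relation
describes, which the pedigree simulator (linkage-equilibrium founders)
cannot produce — hence the separate simulator.

## Runs of homozygosity and F_ROH

The ROH caller is the PLINK-style scanning-window algorithm, with all
parameters exposed and defaulting to the PLINK 1.9 `--homozyg` defaults
(window of 50 SNPs with ≤ 1 heterozygote and ≤ 5 missing calls, 5% hit
fraction, segments of ≥ 100 SNPs and ≥ 1000 kb, split at > 1000 kb gaps,
≤ 50 kb/SNP density). A marker is "in run" when the fraction of
window placements covering it that are homozygous exceeds the hit
fraction; maximal in-run stretches are trimmed to homozygous non-missing
endpoints, split at gaps (each piece re-trimmed), then filtered. Sex
chromosomes and unplaced markers are never scanned. The implementation is
vectorised with cumulative sums but is checked segment-for-segment against
a naive loop-over-everything oracle on hundreds of random instances.

`F_ROH` is an individual's total ROH length divided by the autosomal
genome length; by default the denominator is the mapped extent
(Σ per autosome of max − min position), with an explicit override for a
published genome-length constant. The calibration target is classical:
offspring of full-sib matings have pedigree F = 0.25, and the simulator's
offspring recover mean F_ROH ≈ 0.25 (acceptance band 0.18–0.32 over 100
offspring), while outbred founders stay below 0.02.

## Relationship matrices, PCA, clustering, families

* **IBS distance** `1 − DST`, pairwise-complete markers.
* **G matrix**: VanRaden method 1, `G = ZZ' / (2Σp(1−p))` with
  `Z = M − 2p` and missing dosages imputed to the marker mean `2p`.
  In-sample frequencies by default (G is then column-centred); explicit
  frequencies are accepted — the simulator records its founder
  frequencies, and on that base-population scale simulated
  parent–offspring pairs sit at G ≈ 0.5 and half sibs at ≈ 0.25. Method 1
  was chosen over per-marker-scaled variants because its
  parent–offspring ≈ 0.5 scale is what the family threshold below
  presumes.
* **PCA** is the eigendecomposition of G (equivalent to PCA of centred
  genotypes up to scaling — one code path, one centering convention),
  with a deterministic sign convention (largest-magnitude loading
  positive).
* **Neighbor joining** on the IBS matrix, implemented directly
  (Q-criterion; ties broken by smallest id pair; negative branch-length
  estimates clamped to zero with the deficit moved to the sibling branch,
  the standard remedy). NJ is exact on additive distances, and the suite
  verifies exact topology and branch-length recovery on random additive
  trees, using an independent tree simulator as oracle. Trees serialise
  to Newick with reserved-character quoting; a bulls-only tree is emitted
  separately since sire relationships drive herd decisions.
* **Families**: bulls are connected when their genomic kinship
  (off-diagonal G entry) is ≥ 0.1; connected components form the
  families. Components are the weakest rule consistent with "pairwise
  kinship ≥ 0.1 means same family" — any stricter rule (e.g. cliques)
  would need a tie-handling policy the data cannot justify. Each cow
  joins the family of her maximum-kinship bull if that kinship reaches
  the threshold, otherwise she is assigned to an "other" category
  (breedable with any bull); argmax assignment is deterministic, with
  ties going to the smaller bull id. The kinship coefficient is read as
  the G entry itself, not G/2: on the G scale 0.1 corresponds to roughly
  third-degree relatives, which matches how such herd rules are used;
  halving it would sweep nearly every cow into a family.

## The simulator

`simulate_cohort()` generates founders in linkage equilibrium (allele
frequencies uniform on [0.05, 0.5] by default) and descends a declared
pedigree by meiosis with Poisson crossovers (no interference) at a
constant 1 cM/Mb. Marker spacing is uniform — array spacing is
manufacturer-specific and nothing in the target setting constrains it.
QC decoys are injected with known labels: rare markers (MAF drawn below
0.01), heterozygote-deficit markers (het probability × 0.1 — the
direction genotyping artifacts and inbreeding actually push),
forced-low-call-rate markers, X/Y/unplaced and indel decoys, exact
duplicate samples, and i.i.d. missingness applied last (after
duplication, so duplicate pairs differ only in missing patterns). The
truth tables record per-sample pedigree F (by the tabular relationship
method), family labels, duplicate pairs, per-marker class and generating
allele frequency.

`sim_config_study_like()` bundles the demonstration conditions: 46
genotyped animals (9 bulls, 37 cows) in three paternal half-sib families
of deliberately unequal size plus 14 unrelated cows, two sire–daughter
backcross offspring carrying long autozygous tracts, two duplicate
samples, 2% missingness, and a ~101k-marker panel whose artifact counts
mirror a published cattle-chip QC table (3157 rare, 66 HWE-violating,
1010 low-call, 3785 X, 330 Y, 6267 unplaced, 174 indel).

What the simulator does *not* emulate: background LD in founders (LD
arises only from pedigree recombination and drift), selection, mutation,
real sex-chromosome inheritance (X/Y decoys are autosomal-like noise with
sex-chromosome labels), and realistic cattle map heterogeneity. Passing
tests therefore demonstrate correctness of the *algorithms* under known
structure, not calibration against any particular real herd.

## Numerical choices and degenerate inputs

* Missing calls are `NA`; every statistic states its own missing policy
  (pairwise-complete for DST/IBS and r², mean imputation for G,
  complete-genotypes for HWE).
* Sample pairs sharing no called marker get `NA` similarity; monomorphic
  markers get PIC = He = Ho = 0, Ae = 1, and p-value 1; bins with
  non-positive adjusted r² give `NA` Ne rather than a negative size.
* QC that removes every marker returns an empty matrix with a warning,
  not an error, so batch runs fail soft.
* Exact-test ties are handled with a 1e-9 relative guard (see above).
* Chromosomes with fewer markers than one scanning window are skipped
  with a message.
* All randomness flows from a single mandatory seed per simulation
  config; the analysis pipeline itself is fully deterministic, and two
  runs on the same input produce byte-identical reports (checksummed in
  the tests).

## Problem sizes used in validation

The test suite exercises: the full HWE enumeration sweep to N = 50;
200 random 500-marker ROH instances against the brute-force oracle;
100 random 8-leaf additive trees; 20 × 500 relationship oracles;
100 full-sib-mating offspring on a 5 × 100 Mb genome at 25 kb spacing for
F_ROH recovery; 10 replicates each of the half-sib family recovery
(3 families × 10 cows, 5000 markers) and the Wright–Fisher Ne recovery
(N = 100, 200 generations, 2000 markers, 50 sampled). The demonstration
cohort runs at the full ~101k-marker scale. These sizes were chosen so
each property is measured with comfortable Monte-Carlo margin while the
whole suite stays quick enough to run on every change.

## Known limitations

* LD-based Ne from a few dozen animals is noisy and sensitive to binning
  and the map-rate constant; the per-bin estimates are reference values,
  not a demographic reconstruction.
* The family rule depends on the G scale; if explicit allele frequencies
  from a different base population are supplied, the 0.1 threshold
  changes meaning.
* PN, MAF histograms and similar cohort summaries are computed on
  whatever marker set survives sample QC; comparing them across panels
  with different ascertainment is not meaningful.
* VCF import is a convenience reader for plain-text, biallelic, GT-only
  files; PED/MAP is the canonical interchange dialect.
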