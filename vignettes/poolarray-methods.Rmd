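---
title: "Models and methods behind poolarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poolarray` implements the computational lifecycle of a multi-species SNP
genotyping array on which DNA from two distantly related species — one
plant and one fish — is pooled into a single reaction. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## 1. The design cascade

Candidate SNPs for each species flow through a fixed sequence of filters.
Every filter marks failing rows `removed:<reason>` instead of dropping
them, so the removal log is an exact partition of the input and each stage
is monotone (its survivors are a subset of its input) and idempotent.

* **Variant filter** (`filter_variants`): biallelic SNPs only; per-site
  missingness at most `max_missing` (default 0.20); mean depth at most
  `max_depth` (default 100 reads, guarding against collapsed repeats);
  minor allele frequency at least `min_maf` (default 0.05); A/T and C/G
  SNPs excluded because their alleles are identical on the reverse
  complement and therefore strand-ambiguous on a probe. Because those two
  SNP classes are gone, all probes can be designed on the reference plus
  strand with unambiguous allele identity.
* **Proximity thinning** (`thin_by_proximity`): polymorphism under a probe
  distorts hybridization, so SNPs close to another variant are removed.
  `exclusive` mode (default) keeps a SNP only if *no* other SNP lies
  within the window, dropping both members of a close pair; `keep_first`
  is the scanning variant used with a 30 bp window in the fish presets.
* **LD pruning** (`prune_ld`): greedy left-to-right within a sliding
  window of `ld_window` SNPs (default 50); the later SNP of any pair with
  squared dosage correlation above `ld_r2_max` (default 0.2) is dropped.
  The pair correlation uses pairwise-complete samples; a monomorphic
  column has no defined correlation and is treated as r² = 0 and kept,
  with a count of such pairs reported. Sensible pruning strengths differ between panels, so both are
  configuration with these defaults.
* **Flank extraction** (`extract_flanks`): 60 bases on each side of the
  variant (1-based, inclusive), the 121-mer probe window having the
  variant at index 61. Sites closer than `edge_min_bp` (default 60) to a
  scaffold end, or whose reference base disagrees with the declared REF
  allele, are removed.
* **Cross-hybridization screen** (`screen_cross_hybridization`): because a
  pooled reaction contains both plant and fish DNA, any plant probe
  resembling fish sequence (and vice versa) must go. The 121-mer is
  searched against every other-taxon genome on both strands with a seeded
  local alignment (exact 11-mer seeds, Smith–Waterman extension, match +1
  / mismatch −2, gap open 5 / extend 2); a hit removes the candidate when
  its Karlin–Altschul E-value is at most `1e-5` *and* its identity over
  the aligned span is at least 0.8. E-values use fixed ungapped
  nucleotide parameters (λ = 1.33, K = 0.621) with database length equal
  to the total other-taxon genome length. The contract is engine-agnostic:
  an external aligner honoring the same thresholds may replace the
  built-in search, and the test suite checks the built-in search against
  exhaustive Smith–Waterman on small genomes.
* **Secondary-genome check** (`check_secondary_genome`): markers designed
  on one reference but deployed on material closer to a second genome are
  kept only if the probe window maps to exactly one best location there
  with at most `max_mismatch` (default 1) mismatches over its full length.
* **Probe score proxy** (`score_probe_proxy`): vendor convertibility
  scores are proprietary, so the package substitutes a documented
  deterministic proxy that only supplements the two hard design rules —
  no IUPAC ambiguity code in a flank, and no other known variant inside
  the 121-base window. The proxy starts at 1 and subtracts
  `2·max(0, |GC − 0.5| − 0.2)` (no penalty for GC in [0.3, 0.7]) and
  `0.1·max(0, run − 6)` for the longest homopolymer run, clamped to
  [0, 1]; a candidate needs a score above 0.6.
* **Gene-pool MAF classes** (`classify_by_pool_maf`): provenance class schemes are study-specific, so
  class definitions are user configuration — an ordered list of predicates
  over per-pool MAFs, first match wins.
* **Even random selection** (`select_even_random`): fixed-width genome
  bins filled round-robin (one candidate per non-empty bin per round,
  within-bin order randomized once under the stated seed) until the target
  count is reached. This caps dense regions, reduces to one-per-bin under
  uniform density, and is bit-identical across runs for a given seed.
* **DQC probes** (`design_dqc_probes`): sample-quality probes are drawn
  from non-polymorphic genome windows — 121-mers overlapping no known
  variant and containing no non-ACGT base, non-overlapping, sampled
  exhaustively and seeded. The per-species count is a free parameter defaulting to 200.

## 2. The intensity simulator

The generator exists so that the caller and every validation analysis can
be exercised end-to-end without proprietary array data. It emulates the
*geometry* of two-channel array data, not its physics.

**Genotypes.** Pool allele frequencies follow the Balding–Nichols model:
with ancestral frequency $p$ and differentiation target $F$, each pool
draws its frequency from $\mathrm{Beta}\!\big(p\tfrac{1-F}{F},
(1-p)\tfrac{1-F}{F}\big)$, and individuals are Hardy–Weinberg samples
within pools. Ancestral minor allele frequencies are uniform on
`ancestral_maf_range` (default 0.02–0.5: the rare-allele tail means a
realistic fraction of loci is monomorphic in any finite screened set, as
on a real array whose content was ascertained in other panels).
Pedigrees transmit one allele per parent per locus; a per-call error
replaces the call with a uniformly chosen different genotype.

**Signals.** For a sample of quality $q \in (0,1]$ and a probe of its
species, the contrast axis value is
$N(\mu_{g},\, \sigma_c / q)$ with diploid cluster means
$\mu = (+1.5, 0, -1.5)$ for genotypes AA/AB/BB and $\sigma_c = 0.15$
(five means $(\pm1.5, \pm0.75, 0)$ in tetraploid mode), and the strength
axis value is $N(10\,q,\, 0.25)$ in log2 units. Channels are
reconstructed as $A = 2^{s + c/2}$, $B = 2^{s - c/2}$, the exact inverse
of the caller's transform. These defaults put a clean sample in the
"clear and well-separated clusters" regime; degradation is modeled only
through $q$, which simultaneously shrinks strength and inflates contrast
noise.

A seeded fraction `otv_fraction` (default 5%) of each species' SNPs
segregates a null allele at frequency `null_allele_freq` (default 0.2);
carrier samples see only background signal there — the mechanism behind
off-target variants. Probes of a species absent from a reaction sit at
crosstalk background (default 2% of full strength, justified by the
design cascade's cross-hybridization screen: pooling in equal quantities
is modeled as adding no interference beyond that constant). A related
species can be mapped onto another species' probes with a per-sample
`divergence` fraction of probes nulled, reproducing the
congener-on-array behavior (elevated off-target rates, lower call rates).

**What it does not emulate** — and hence what passing tests do not show
about real data: optical/physical hybridization effects, plate and batch
spatial structure, probe-sequence-specific affinity differences, linkage
between loci (loci are independent given pool frequencies), and any
biological difference between plant and fish DNA beyond the quality
scalar. In particular, the simulator makes "pooling per se is neutral,
quality differences carry the effect" a *model assumption*; the package
can therefore test that the QC machinery detects quality differences, not
whether pooling harms real chemistry.

## 3. The caller

The proprietary array-calling algorithm is replaced by a documented
stand-in with the same category semantics. Per SNP, the contrast values
are fitted with constrained Gaussian mixtures: one model for every subset
of the prior cluster positions (7 diploid models, up to 31 tetraploid),
each fitted by EM with component means boxed to `prior ± 0.75` (which
also fixes the mean ordering and each component's genotype identity),
standard deviations floored at 0.05 and capped at 1.0, at most 100
iterations, relative tolerance 1e-6. Initialization is deterministic
(means at the priors, uniform weights), so calling is reproducible
without seeds. The model is selected by BIC; each sample takes its
maximum-posterior component's dosage if that posterior reaches
`confidence_min` (default 0.85), else missing. SNPs with fewer than 20
samples are left uncalled. As a speed measure, only subsets of clusters
that have at least one sample within the mean box are enumerated; this
cannot change the selected model because a component without nearby data
collapses during EM.

**Off-target recall.** A SNP is flagged OTV when its strength values
split into two clusters (optimal 1-D 2-partition) with a BIC improvement
over one cluster, at least 2 log2 units between the cluster means (low
cluster below one quarter of full signal) and at least 2 samples in the
low cluster; low-cluster samples are re-coded with the OTV sentinel.

**Classification.** First match of: call rate below 97% (the SNP-level
convention, deliberately distinct from the sample-level 95%); OTV;
no fitted model (Other); one component (MonoHighResolution); polymorphic
with ≥ 2 minor-homozygote calls and adjacent-cluster separation
$|\Delta\mu|/\bar\sigma \ge 3$ (PolyHighResolution); polymorphic with
< 2 minor homozygotes at that separation (NoMinorHom); otherwise Other.
OTV-recoded samples count as called, since they are genotyped — they
carry a null allele. Whether "NoMinorHom" should require a visible heterozygote cluster is
ambiguous in common usage; the package implements the literal reading
(no minor-homozygote cluster).

**Sample QC** is two-stage. DQC is the fraction of the sample's species
DQC probes behaving as clean homozygous A-signal: contrast at least 0.75
(half the nominal homozygous contrast) with strength at least 5.5 log2
units (the 2% crosstalk background of a nominal strength-10 signal plus
one log2 unit of margin). Stage 1 passes samples with DQC ≥ 0.82 and a
QC call rate (over a seeded random 10% probe subset) ≥ 95, both
inclusive. Stage 2 computes the allele deviation mean — the average over
called SNPs of `min(1, |contrast − μ_assigned| / (3 σ_assigned))`, larger
meaning worse — and removes samples above 0.85. The vendor metric's exact formula is proprietary; this definition is the
package's stand-in, with direction chosen so that the conventional 0.85
threshold acts as an upper bound. Call rate is reported for
final samples only, mirroring the reporting convention that call rate
exists only for successfully genotyped samples.

## 4. Validation analytics

* **PCA** (`pca_genotypes`): per-SNP mean imputation, column centering,
  SVD; variance percentages from squared singular values.
* **DAPC-lite** (`dapc_lite`): PCA → k-means (10 restarts, seeded) for
  each candidate k → linear discriminant projection onto ≤ k−1 axes. The
  cluster number minimizes the BIC of the k-means partition under a
  spherical Gaussian mixture with cluster-specific variances
  (classification likelihood with `k·d` means, `k` variances, `k−1`
  weights). The simpler `n log(WSS/n) + k log n` form systematically
  over-splits multi-dimensional PC scores because retained noise
  dimensions keep absorbing within-cluster variance; the
  cluster-specific-variance form recovers the simulated pool number
  across 2–6 pool scenarios and is the package default.
* **FST** (`fst_wc`): Weir–Cockerham (1984) variance components,
  multi-locus ratio-of-sums over loci polymorphic in the compared groups;
  missing genotypes reduce per-locus sample sizes; negative estimates are
  reported as-is.
* **IBS** (`ibs_matrix`): mean over shared non-missing loci of
  `1 − |g_i − g_j|/2`, computed with indicator-matrix products;
  duplicates flagged above 0.97. OTV codes count as missing.
* **Parentage** (`assign_trios`): pair-level Mendelian exclusion rather
  than likelihood assignment. A pair's mismatch rate is the fraction of
  loci typed in all three members where no allele combination of the
  parents yields the offspring genotype; the unique minimizing pair is
  assigned when its rate is at most `eps` (default 0.01, covering genotyping error).
  A per-parent opposing-homozygote screen shortlists candidates — valid
  because a pair's mismatch rate can never be below either parent's
  opposing-homozygote rate — and ties leave the offspring unassigned.
* **Quality comparison** (`welch_t_test`, `compare_pooling`): Welch
  statistic and Satterthwaite degrees of freedom implemented directly so
  the zero-variance degenerate case is defined (equal means: t = 0,
  p = 1); two-sided p-values, significance reported at 0.05. Accounting
  tables (`sample_accounting`) are exact integer partitions and error on
  inconsistent inputs.

## 5. Problem sizes used by the test suite

The package's checks run at deliberately scaled-down sizes chosen to keep
the statistical properties they probe intact: the round-trip fidelity
check uses 200 samples × 1,000 SNPs at the default signal model; FST
recovery uses 4 pools × 50 samples × 5,000 loci over 10 seeds; the
parentage check uses 60 candidate parents, 3 families × 30 offspring and
a 10,000-SNP panel (the order of magnitude of the high-quality marker
sets such arrays yield for parentage work; at a few
thousand loci the binomial spread of a 1%-error mismatch rate would
straddle the 0.01 exclusion tolerance, which is a property of small
panels, not of the method); alignment-screen oracles run on genomes of
20–100 kb against exhaustive Smith–Waterman and Hamming scans.

## 6. Known limitations

Cluster priors are fixed rather than learned across SNPs, so systematic
contrast shifts (dye bias) would need recalibration of the prior
positions. The OTV caller models a single low-strength cluster and will
not resolve several distinct null haplotypes. The cross-hybridization
E-value uses ungapped Karlin–Altschul parameters with gapped alignments,
a standard approximation that is conservative at these thresholds. The
tetraploid caller assigns dosages against fixed five-cluster priors and
does not model allelic ratio distortion. None of the analytics model
linkage; FST and parentage treat loci as independent.
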