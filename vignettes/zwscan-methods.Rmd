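---
title: "Finding a female-specific genomic region from pooled sequencing: methods and design"
author: "zwscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding a female-specific genomic region from pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In many dioecious plants sex is controlled by a small sex-determining
region (SDR) on one member of a homomorphic chromosome pair. Under female
heterogamety (the ZW system) females are WZ (or, where viable, WW) and
males ZZ, and the female-determining sequence exists only on the W. Such a
region can be found without any pedigree by bulked segregant analysis
(BSA): pool DNA from many females and many males, sequence both pools
deeply, and look for sequence that is covered by female-pool reads but
receives no male-pool reads at all. `zwscan` implements that scan and the
analyses around it — copy-number-aware tests of pooled SNP allele ratios,
linkage-map anchoring of scaffolds into pseudochromosomes, haploblock
recombination mapping, in-silico PCR validation of sex markers, and 4DTv
divergence statistics — together with a fully synthetic ZW data generator
so every stage is testable with known truth.

## The depth scan

Both pools are mapped to the candidate carrier assembly and reduced to
per-base depth tracks. A base *qualifies* when the target pool's depth is
strictly greater than `min_target_depth` (default 10) while the other
pool's depth is at most `max_other_depth` (default 0 — exact absence).
Maximal runs of qualifying bases strictly longer than `min_run_bp`
(default 100) are retained; both inequalities are deliberately strict, so
a run qualifies at 101 bp and a base at depth 11. Runs separated by at
most `merge_gap_bp` (default 0, i.e. no merging) are merged, and a merged
region becomes a candidate when its mean target depth reaches
`min_depth_fraction` (default 0.5) of the target pool's genome-wide mean.
The 50% rule is interpreted as a *depth fraction* — mean region depth over
the pool's genome mean — rather than a fraction of qualifying bases: a
heterogametic region present in one copy per diploid in half the pool's
chromosomes runs at ~50% of the genome-wide depth, and a detected region
at, say, 66% of a 106-fold pool passes comfortably. Residual contrasts
below `noise_fraction_ceiling` (default 0.4) are treated as background
when calling the system.

Running the scan in both directions — female pool against the female
assembly, male pool against the male assembly — yields the system call:
female-specific candidates without male-specific ones mean ZW, the mirror
means XY, both is ambiguous, neither gives no call.

## Copy-model tests of pooled SNPs

A W-linked SNP shows a characteristic allele-dosage signature in the
female pool. With one W copy and a duplicated paralog contributing two
co-mapping copies of the other allele, the W allele is expected at 1/3 of
reads (a 1:2 ratio); with a single Z-derived alternative it is expected at
1/2. `copy_model()` encodes these dosages; `test_site()` checks the female
pool's W-allele count against the model expectation with a two-sided exact
binomial test (consistency means p > α, default α = 0.05) and requires the
male pool's W-allele fraction to stay at or below `max_male_error`
(default 0.05 — male pools are rarely perfectly homogeneous; sequencing
error, pool contamination and residual cross-mapping are subsumed here).
Sites whose depth exceeds ~1.5x the single-locus expectation are flagged
as multi-copy *ghost* loci: paralogous regions with small divergence to
the reference attract co-mapping reads and fake variants. Candidates can
be confirmed in individually sequenced, sexed samples
(`confirm_in_individuals()`): every female must be consistent with the
model at a per-individual α of 0.01 and every male must be W-free up to
`max_male_error`; a single discordant individual fails the site. The
genome-wide scan keeps each site's best-fitting model (largest female-pool
p) and can apply Benjamini–Hochberg correction across sites, off by
default because single-region workflows report one dominant signal.

## Scaffold anchoring

Mapped markers (marker, linkage group, cM, scaffold, position) drive
pseudochromosome construction:

* **Assignment and chimeras.** A scaffold joins the linkage group of its
  markers. Markers are ordered along the scaffold and collapsed into
  contiguous same-group blocks; blocks with fewer than
  `min_split_support` (default 2) markers are dismissed as noise. Two or
  more retained blocks on different groups flag a chimeric misjoin, which
  is cut at the midpoint of the gap between the flanking conflicting
  markers — marker evidence says only that a breakpoint lies somewhere
  in that gap, so the midpoint is the least-informative choice. Interleaved
  blocks (a group recurring in non-adjacent blocks) are not separable and
  raise an error instead of guessing.
* **Ordering** is by median marker cM (robust to one mis-mapped marker),
  with ties broken by marker count then scaffold id, so output order is
  deterministic.
* **Orientation** is a majority vote over all marker pairs: a pair votes
  `+` when scaffold order agrees with map order, `-` when reversed, and
  abstains on cM ties. Scaffolds with fewer than three markers, or tied
  votes, are placed unoriented (`?`) rather than guessed.
* **Emission.** Each chromosome concatenates its oriented scaffolds with
  exactly 1000 `N` between adjacent components; unplaced scaffolds are
  concatenated in seeded-random order onto chromosome 0, so "random" is
  reproducible from the run seed. The AGP v2.1 table round-trips to the
  emitted FASTA exactly, which the tests assert byte for byte.

## Haploblocks, recombination and centromeres

The mapping design is an outbred F1 treated as a double pseudo-testcross:
markers segregate as maternal testcross (`lm x ll`), paternal testcross
(`nn x np`) or both-heterozygous (`hk x hk`). Before aggregation a
graphical-genotyping curation step sets apparent double recombinants
(a genotype flipping and flipping back within 1 cM) to missing, since
these are nearly always genotyping errors. Markers of one segregation
type and genetic bin whose vectors agree on all co-observed progeny merge
into a haploblock; agreement is assessed up to linkage phase (a marker in
repulsion is the exact code-complement of one in coupling and is flipped
into the block's phase), and the consensus is the per-progeny majority
with unresolved ties set to missing.

Recombination fractions between blocks are direct counts over
co-informative meioses, with phase chosen to minimise the estimate
(`min(r, 1-r)`, capped at 0.5) and entries suppressed below 20
co-informative progeny. Pairs without a shared informative parent — any
`hk x hk` involvement — have no direct-count estimate and are left absent:
a proper estimator there requires EM over phase, which is out of scope.
The full matrix in map order is the recombination heatmap.

Centromeres are called as recombination-suppressed windows: consecutive
block pairs are scored by physical span over genetic span, the genetic
span floored at 0.5 cM to avoid division blowup, and the peak pair is
extended while neighbouring pairs stay above half the peak. The windowing
rule is this package's own construction — the observable it targets is a
single ~2 cM region of marker pile-up per chromosome. Peaks below twice
the chromosome-average Mb/cM are flagged low-confidence, which is what a
uniformly recombining chromosome produces.

## Sex markers in silico

PCR assays are evaluated computationally: a primer pair amplifies wherever
the forward primer matches one strand and the reverse primer's reverse
complement matches strictly downstream within the product cap, on either
strand of the template. Mismatches up to a configurable count are allowed
per primer but the 3' terminal base must match exactly (no extension from
a mismatched 3' end); the default is zero mismatches. Dominant assays
score band presence (W carrier); co-dominant assays pair the W-specific
amplicon with a control amplicon from the paralogous locus present in both
sexes — two bands call female, control-only calls male, and a missing
control *fails* the assay rather than silently scoring absence, exactly
the role an internal positive control plays on a gel. Expected F1 ratios
come from exact gamete enumeration (WZ x WZ with a dominant W marker gives
3:1), and observed segregation is tested with a Pearson chi-square without
continuity correction. WW is treated as a viable, female-scoring genotype
throughout.

## The 4DTv statistic

For a codon-aligned gene pair, fourfold-degenerate third-codon sites are
those where both codons are gap-free, share their first two bases and
belong to a fourfold family of the standard code (a permissive flag
requires only that each codon be fourfold on its own). The raw statistic
is the fraction of those sites differing by a transversion. "Revised by
HKY" is interpreted as the transversion-distance component shared by the
HKY85/TN93 model family,

d = -2 πR πY ln(1 − tv / (2 πR πY)),

with πR and πY the purine/pyrimidine frequencies estimated from the
fourfold third positions of the pair itself (not genome-wide). The
correction is undefined (saturated) once tv reaches 2 πR πY and the result
is flagged rather than extrapolated; raw values are always reported
alongside. On its domain the correction is monotone, convex, and tangent
to the raw value at 0, which the tests verify, and simulated pairs at
known transversion distances 0.05–0.5 recover the truth within sampling
error.

## The synthetic generator: what it does and does not emulate

`sim_config()` defaults describe the calibration conditions: eight
chromosomes, a 59-kb female-specific region near the distal end of
chromosome 8 carrying seven genes copied at 10% divergence from donor
paralogs on the same chromosome and interleaved with repeat-like filler
(40% of the region, a placeholder proportion — the true gene/TE split of
such regions varies), female and male pools at 106x and 127x, a
95-progeny WZ x WZ F1, and a 133-female / 128-male validation panel.
Chromosomes are shrunk to 200 kb desk scale while the FSR keeps its full
59 kb, preserving the detection geometry (region length, depth contrast)
at a fraction of the compute. Genetic maps are normalised to 66.4 cM per
chromosome — a 531 cM genome over eight groups — with a tenfold
recombination suppression over the central fifth of each chromosome as
the planted centromere.

Pool depth is Poisson per base at `pool_depth x copies / 2`; pileups are
multinomial in copy dosage with a uniform substitution error. Crossovers
follow the Haldane model (Poisson, no interference — the simplest standard
choice where nothing is known about interference). The FSR has zero
genetic width on the map, so no simulated crossover can fall inside it,
matching the observed non-recombining behaviour of such regions. Marker
linkage phase is drawn once per genetic bin, so co-located markers
co-segregate exactly; the aggregator nevertheless handles repulsion-phase
markers, which real data contain. Cross-mapping of paralogous reads is a
toggle with a 5% divergence cutoff: below it, FSR genes and their donors
exchange reads, producing ghost depth (~1.5x) and ghost variants; at the
default 10% divergence mapping is clean.

What the generator does **not** model bounds what green tests mean for
real data: there is no read-level simulation (no mapping-quality
artefacts, indels, GC bias or coverage waves), no structural variation
beyond the single insertion and its paralog copies, no segregation
distortion, and sequencing error is uniform. A scanner that is exact here
can still need parameter tuning (`max_other_depth`, `merge_gap_bp`,
`noise_fraction_ceiling`) on noisy real alignments.

## Numerical and design choices

* Coordinates are 0-based half-open internally and in BED; AGP and marker
  tables are 1-based inclusive, matching each format's convention.
* Strict `>` for run length and depth thresholds follows the wording of
  the rule they implement; both are configurable.
* The pipeline (`run_zw_pipeline()`) writes every stage's outputs to disk
  for inspection but reruns stages deterministically in memory rather than
  resuming from partial files: at desk scale regeneration is cheaper and
  removes a class of stale-intermediate bugs. Identical config and seed
  give byte-identical outputs, which the tests assert.
* Degenerate inputs are first-class: a zero-length FSR yields identical
  haplotypes, a "none" system call and an empty region set; zero-depth
  pools yield diagnostic unassociated calls; chromosomes with fewer than
  four anchored blocks yield no centromere call, with a warning.
* Test problem sizes are chosen for a laptop-class run: module tests use a
  4 x 30 kb genome with a 6-kb FSR, the acceptance suite runs the full
  default configuration (1.6 Mb genome, 59-kb FSR, 20 scanner seeds,
  10^4-site calibration), and the whole suite completes in well under a
  minute.

## Known limitations

Recombination-fraction estimation for both-heterozygous marker pairs,
LOD-based map construction, homology-based ordering of short scaffolds
between two assemblies, and any alignment- or read-level processing are
deliberately out of scope; maps, depth tracks and allele counts are
inputs. The HKY-style 4DTv correction is one defensible reading of a
terse method statement; raw values are always emitted so any other
correction can be applied downstream.
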