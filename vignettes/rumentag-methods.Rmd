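---
title: "Methods: short 16S tag taxonomy and T-RFLP community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: short 16S tag taxonomy and T-RFLP community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumentag)
```

# The problem

Rumen bacterial communities are profiled here by two complementary
16S rRNA strategies: short sequence tags from the V1 hypervariable region
(~50–60 nt, obtained by serial concatemer cloning) or longer V1–V2
pyrosequencing reads (~250 nt, barcoded), plus terminal restriction
fragment length polymorphism (T-RFLP) fingerprints of the same samples.
The scientific question the pipeline serves is twofold: do dietary
treatments (here, probiotic yeast doses `L0 < L1 < L2` in a 3×3 Latin
square over cows and periods) shift the community, and can a tag as short
as the V1 region carry genus-level information comparable to a longer
read?

`rumentag` implements every computational stage of that analysis, together
with a synthetic-data module that generates references, communities,
reads, concatemers and electropherograms with known ground truth, so the
whole pipeline is testable end to end without any external download.

# Taxonomy assignment by filtered nearest-neighbour transfer

Queries (tags or quality-filtered reads, plus-oriented) are classified
against a reference database of full-length 16S sequences with six-rank
lineages (domain…genus):

1. **Region extraction.** Reference records must match both the 27F and
   357R primer sites (each with a bounded mismatch count, found exactly
   once, in the correct orientation); the inter-primer region — the same
   region the sequencer reads — is what queries are compared against.
   Records failing this are dropped with a reason count.
2. **Dereplication.** Identical regions collapse to one representative
   whose lineage is the set's deepest common classified prefix; two genera
   with indistinguishable regions are honestly represented at the family
   level.
3. **Candidate search.** References are ranked by the number of distinct
   7-mers shared with the query (ties by reference id) and the top 50 are
   kept. This is a recall device only — the neighbour choice never relies
   on the word ranking.
4. **Identity screen.** Each candidate is aligned semi-globally
   (match +1, mismatch −1, gap open 5, gap extend 2, free end gaps).
   A candidate passes if identity (matches over alignment columns,
   overhangs excluded) is ≥ 95% *and* the aligned span is within ±5 nt of
   the query length. The span rule is what catches chimeras: a two-parent
   chimera aligns well over only part of its length against either parent,
   so its best span is short and the read is discarded as
   `filtered_identity` rather than mis-assigned.
5. **Nearest neighbour.** Among screened candidates the one with the
   smallest Jukes–Cantor distance `d = -(3/4) ln(1 - 4p/3)` wins, where
   `p` is the mismatch proportion over gap-free columns (gapped columns
   are excluded because the one-parameter model describes substitutions
   only). Distance ties go to the candidate classified to the deepest
   rank, then to the smallest reference id so runs are reproducible. The
   query inherits the neighbour's lineage verbatim, at the neighbour's
   depth.

Choices worth stating: identity is computed over alignment columns and the
span over the non-overhang aligned region — one consistent reading of
"95% identity over ±5 bp query length"; `p` excludes N-containing columns
(Ns in reads are capped at two by the quality filter anyway).

# Quality control of barcoded reads

Reads arrive tag-first in sequencing orientation (4-nt barcode, 357R
primer, insert). Demultiplexing allows one barcode mismatch (a read within
tolerance of two barcodes is `ambiguous` and unassigned) and two primer
mismatches; the insert is then reverse-complemented into 27F→357R
orientation. The quality filter passes a read iff it has at most 2 Ns,
mean Phred quality ≥ 20, trimmed length in [200, 400] and no single-base
run longer than 6. Rules are evaluated in a fixed order (ns, quality,
length, homopolymer) so rejection-reason counts are reproducible. The
homopolymer rule is deliberately read as "no run longer than six bases" —
the standard pyrosequencing artefact filter; the alternative reading
(more than six runs) would reject nearly every 250-nt read and is not
biologically sensible. Length is measured on the trimmed insert, whose
bounds bracket the ~250-nt V1–V2 amplicon.

# Tag deconcatenation

Serial-tag clone inserts are split at every non-overlapping occurrence of
the 8-nt head-tail border `ACGGGTCG` or its reverse complement
`CGACCCGT`, scanning left to right — ligation orientation is random, so
both forms are searched simultaneously. Fragments outside the [40, 70] nt
window (tags are nominally 50–60 nt; ±10 tolerates indel errors without
admitting junk) are discarded and counted. Terminal borders, if a
protocol produces them, yield empty terminal fragments that the window
silently removes, so both layouts parse identically.

One limitation is inherent to the format: a tag ending in `ACGGGT`
immediately before a `CGACCCGT` border (or starting with `ACCCGT` after
an `ACGGGTCG` border) creates a spurious border spanning the junction,
and no splitter can tell the two readings apart. Enumerating all overlap
cases of the border pair shows these are the only two hazard classes;
the synthetic concatemer round-trip therefore defines "border-free" tags
as excluding those termini as well as full border forms.

# OTU clustering and the threshold scan

Greedy clustering follows the CD-HIT convention: sequences sorted
longest-first (ties by id), each joining the first OTU whose
representative it matches at or above the threshold, with identity
defined as alignment matches over the *shorter* sequence length and a
5-mer shared-word prefilter. Multi-step mode cascades through 100%,
99%, … 90% and then the final threshold, re-clustering representatives
and merging members — one cascade pass serves every requested threshold.

Each OTU receives a consensus classification: walking from genus upward,
the first rank at which ≥ 80% of members share one full lineage prefix
labels the OTU at that depth (prefix-wise agreement, so two genera of one
family disagree at genus but agree at family). The threshold scan then
compares, rank by rank, the member-weighted consensus composition with
the unclustered composition by Spearman rank correlation over the union
of classified taxa (absent taxa count as zero; a rank with fewer than
three taxa is undefined). At 100% the clustering is exactly a
dereplication, so the correlation is exactly 1 — a structural check the
tests assert. Composition is member-weighted rather than OTU-weighted
because the quantity of interest is relative abundance, not cluster
count. On the synthetic community (genus divergence 0.08) the genus-rank
correlation stays at 1 down to 93% identity and collapses below 92%,
which is the calibration logic that motivates clustering at 93% for
genus-level work.

# Diversity

Samples are depth-matched by uniform subsampling without replacement
(multivariate hypergeometric) to the smallest sample before estimating:
bias-corrected Chao1 `S_obs + F1(F1−1)/(2(F2+1))` (the corrected form is
defined even when no doubletons exist), Good's coverage `1 − F1/N`, and
Shannon entropy with natural logarithms (the index base is a convention;
natural log is stated here once and used everywhere). The core-microbiota
summary reports the OTUs present in every animal, their share of the OTU
union and of total abundance, and optionally a family breakdown.

# Community statistics

Two dissimilarities are provided: Bray–Curtis `Σ|x−y| / Σ(x+y)` for the
T-RFLP matrices, and Morisita–Horn (as 1 − similarity) for sequence-based
genus tables — the latter is invariant to uniform rescaling of either
vector, which is why it suits libraries of unequal size. UPGMA clustering
places each merge node at half the merge distance, uses size-weighted
average linkage, and breaks distance ties lexicographically on the merged
leaf sets so trees are deterministic; the newick writer emits branch
lengths as parent height minus child height and refuses non-ultrametric
input.

PERMANOVA uses Anderson's pseudo-F from sums of squared distances
(`SS_total = Σ d²/N`, within-group terms analogously), with the null
built by permuting labels **within strata** — by default within animal,
which respects the Latin-square layout where treatments vary within each
cow. When the restricted permutation group is small (e.g. `(3!)³ = 216`
for 3 animals × 3 periods) it is enumerated exhaustively and the p-value
is exact; otherwise permutations are sampled and the `(1+b)/(1+B)`
estimator is used. The pseudo-F agrees with `vegan::adonis2` to machine
precision in the test suite, and the type-I error rate is 5% on 200 null
simulations.

Per-taxon differential abundance uses a Welch t statistic on per-sample
proportions with a permutation null pooled across taxa and computed
leave-own-taxon-out: with three samples per group only 20 relabellings
exist, so a per-taxon null bottoms out at p = 0.1 and pooling that
includes a taxon's own statistic (always re-entering via the identity
relabelling) pins the smallest attainable BH q at exactly 0.1; excluding
the taxon's own permuted statistics from its null removes that floor
while keeping the null honest. Taxa with fewer than 10 pooled reads are
too sparse for proportion t statistics and route to Fisher's exact test
on the pooled taxon-versus-rest table. Benjamini–Hochberg q-values are
reported over all tested taxa; the calibration suite checks ≥80% power
for a 3-fold enriched genus at 20% abundance (n = 3 vs 3) and a ~10%
any-discovery rate on all-null tables at q < 0.1. A one-way ANOVA on
Firmicutes/Bacteroidetes ratios (samples with zero Bacteroidetes are
excluded with a warning) completes the treatment summaries.

# T-RFLP processing

Peak lists (fragment size, area) per sample × enzyme are processed
per enzyme:

1. **True-peak detection.** Iteratively, the noise standard deviation is
   `sqrt(Σ area² / n)` over peaks currently labelled noise — a zero-mean
   noise model; peaks above 3σ are promoted to true and the iteration
   runs to a fixed point. The zero-mean form matters: a mean-offset
   variant cannot detect a single outlier, because the outlier drags the
   mean with it. The procedure is idempotent and promotion is monotone
   (removing a peak from the noise pool only shrinks σ).
2. **Binning.** Sizes are rounded to integers; bins are seeded greedily
   by descending total area (so binning does not depend on sample
   order), each bin centre being the area-weighted mean size, fixed after
   seeding; every peak joins the first bin within ±1 bp.
3. **Transform and concatenation.** Per-sample relative abundances (in
   percent, over true peaks) are transformed as `ln(1 + r)` — zeros stay
   zero and the transform is strictly monotone — and the four enzyme
   matrices are concatenated column-wise with enzyme-qualified labels.
   Binning is per-enzyme; fragments from different digests are never
   co-binned.

In-silico digestion uses the canonical recognition sites and cut offsets
HaeIII `GG^CC`, MspI `C^CGG`, HhaI `GCG^C`, RsaI `GT^AC`; the terminal
fragment runs from the dye-labelled 27F end of the amplicon to the first
cut (0-based site position + offset). A sequence without a site
contributes its full amplicon length, flagged as uncut.

# The synthetic-data module

The generators define the study conditions under which the pipeline is
validated:

* **Reference database.** A random root sequence (≥1200 nt) carries
  intact 27F/357R sites at fixed coordinates (masked from mutation), and
  its homopolymer runs are capped at 5 nt — long runs are rare in real
  16S genes, and an uncapped random root would hand whole genera reads
  that the homopolymer quality filter rightly rejects. Taxon
  substitutions are drawn to differ from both neighbouring bases, so
  they never extend or bridge a run; only the read error model can
  create new homopolymers, as on a real instrument.
  Taxa evolve down the six-rank taxonomy: a node at rank r substitutes a
  fixed proportion (half the rank-r divergence) of its parent's sites, so
  siblings differ at about the stated proportion. Substitution positions
  are placed by stratified jittered sampling rather than independent
  per-site draws, so the realized divergence matches the nominal value in
  any sub-region of the molecule (in particular inside the sequenced
  V1–V2 window) instead of fluctuating with binomial variance — a
  controlled-benchmark choice, not a model of rRNA evolution, whose
  hypervariable/conserved structure is deliberately not emulated.
  Defaults: phylum 0.20, class 0.12, order 0.10, family 0.08, genus 0.08,
  within-genus 0.005 — a divergence scale on which congeneric references
  are nearly identical and confamilial genera differ by ~8%, the regime
  in which the 93% clustering threshold is meaningful.
* **Community.** Ten rumen genera across five phyla with Prevotella
  dominance; treatment effects are multiplicative folds on expected
  occurrence (renormalised), including a 3.1-fold Megasphaera and
  2.7-fold Ruminococcus increase and a 1.2-fold Prevotella decrease at
  the high yeast dose — the lactate-utiliser/fibrolytic signature of
  yeast supplementation.
* **Reads.** V1–V2 reads are emitted in sequencing orientation (barcode,
  357R, reverse-complemented insert) with truncated-normal Phred
  qualities (mean 32, sd 4, bounds 2–40 — enough signal for the mean-20
  filter to act on); V1 tags are bare 55-nt plus-strand fragments. The
  error model has per-base substitution and indel rates, an indel
  multiplier inside homopolymer runs ≥3 (the dominant pyrosequencing
  artefact), and a per-read two-parent chimera rate with a uniform
  breakpoint. Defaults are zero: the validation conditions are
  error-free, and error rates are free parameters, not calibrated to any
  instrument.
* **Concatemers.** Tags joined by the head-tail border in random
  orientation per junction; terminal borders optional (off by default,
  matching the junction-only description of the chemistry).
* **Electropherograms.** Signal areas proportional to genus counts
  (split equally over a genus's references); 200 baseline noise peaks per
  enzyme at uniform random sizes with areas uniform on (0, scale), as
  capillary traces list hundreds of sub-threshold peaks. Both choices
  are deliberate properties: the 3-SD detector's premise is
  bounded-amplitude baseline noise (an unbounded tail would make perfect
  separation impossible at any finite signal/noise ratio), and its
  bootstrap requires noise peaks to dominate the peak count — with as
  many signal as noise peaks, the initial σ is signal-inflated and
  nothing ever clears 3σ.

Everything is seed-deterministic: same seed, byte-identical output, with
the caller's RNG state restored afterwards.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: flowgram-level 454 noise, PCR amplification
bias and primer mismatch to divergent templates, true chimera formation
mechanisms (breakpoints at homologous motifs), rank-incomplete reference
annotations, and capillary size-calling error in T-RFLP beyond the ±1 bp
binning. Recovery rates on synthetic error-free reads are upper bounds.

# Problem sizes and numerics

The validation suite uses 5,000 reads per sample for the recovery and
threshold-scan checks, nine samples (3 cows × 3 periods) for the sequence
arm, 54 profiles (× 4 enzymes) for the T-RFLP arm, 200 replicates for
each statistical calibration, and 1,000 clones for the concatemer
round-trip — sizes at which every property being asserted is already
stable. Floating-point ties in the nearest-neighbour and clustering
paths are broken with a 1e-12 tolerance before the deterministic
tie-breaks; identity thresholds are compared with a 1e-9 slack so that
exact-boundary cases (e.g. identity exactly 0.90 at threshold 0.90) join
rather than split. Internally all coordinates are 1-based inclusive — the
R and Biostrings convention; off-by-one safety is enforced by tests on
primer and cut positions rather than by a coordinate convention.

# Known limitations

* Genus recovery depends on the reference database containing the true
  genus: the method transfers labels, it cannot discover new lineages
  (de novo tree building is out of scope).
* The identity screen can let a chimera pass when its minority segment is
  short (<~2% of the read) or its parents are congeneric; such reads are
  assigned to the majority parent, which is the correct genus in the
  congeneric case.
* With very short tags, distinct genera occasionally share an identical
  V1 sequence; dereplication then classifies at the family level, and
  tag-level recovery is bounded by that ambiguity (the 1-percentage-point
  tolerance in the V1 recovery check absorbs it).
* The Latin-square PERMANOVA restricts permutations within animal; other
  restriction schemes (within period, or doubly restricted) are possible
  and would give slightly different exact p-values. The factor interface
  is generic, so a caller can pass any stratum vector.
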