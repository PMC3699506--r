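# rumentag

Profiling rumen bacterial communities from short 16S rRNA amplicons and
T-RFLP fingerprints.

`rumentag` is for microbial ecologists who work with short hypervariable
16S tags — serial V1 sequence tags of ~50–60 nt, or barcoded V1–V2
pyrosequencing reads of ~250 nt — and who want genus-level community
composition, defensible clustering thresholds, diversity estimates and
treatment statistics from them, alongside the parallel analysis of
multi-enzyme T-RFLP electropherograms of the same samples. Everything is
validated end to end on a built-in synthetic-data module that generates
reference databases, communities, reads, tag concatemers and peak tables
with known ground truth.

## What it computes

**Taxonomy by filtered nearest-neighbour transfer.** Each query is
compared to reference regions extracted between the 27F/357R primer
sites: candidates found by shared 7-mers (top 50), screened by
semi-global alignment (identity ≥ 95% over a span within ±5 nt of the
query length — the span rule rejects chimeras), and classified by its
closest screened neighbour under the Jukes–Cantor distance

> d = −(3/4) · ln(1 − 4p/3),

with p the mismatch proportion over gap-free columns; distance ties go to
the neighbour classified to the deepest rank.

**OTUs and the threshold scan.** Greedy CD-HIT-style clustering
(longest-first, identity = matches / shorter length, word prefilter,
multi-step cascade 100%…90% + 85%), rank-wise consensus classification at
80% agreement, and a Spearman-correlation scan of clustered versus
unclustered composition that shows how far the clustering threshold can
drop (to 93%) before genus-level composition degrades.

**Diversity.** Depth-matched subsampling, bias-corrected Chao1
`S_obs + F1(F1−1)/(2(F2+1))`, Good's coverage `1 − F1/N`, Shannon
entropy, and shared-OTU (core microbiota) summaries.

**Community statistics.** Bray–Curtis and Morisita–Horn dissimilarities,
deterministic UPGMA dendrograms, PERMANOVA (Anderson's pseudo-F) with
permutations restricted within strata (exact p by enumeration for small
Latin-square designs), per-taxon differential abundance (permutation
t-tests with a pooled null, Fisher's exact for sparse taxa, BH q-values)
and a Firmicutes/Bacteroidetes ratio ANOVA.

**T-RFLP.** Iterative 3-standard-deviation true-peak detection under a
zero-mean noise model, ±1 bp cross-sample binning, `ln(1 + %)` transform,
and column-wise concatenation of the four enzyme matrices (HaeIII, MspI,
HhaI, RsaI) for the distance analyses.

## Worked example

Simulate a high-yeast-dose sample, push it through QC and taxonomy
assignment, and summarise:

```r
library(rumentag)

ref <- make_reference(rumen_taxon_specs(), seed = 1)
db  <- prepare_reference_db(ref)
cnt <- simulate_community(rumen_community_spec(), "L2", 2000, seed = 2)
rd  <- sample_reads(cnt, ref, region = "V1V2", barcode = "ACAC", seed = 3)
qc  <- run_qc(rd$records, demux_rule(c(cow1 = "ACAC")))
kept <- qc$reads[qc$reads$status == "assigned", ]
asg <- assign_taxonomy(data.frame(id = kept$read_id, seq = kept$insert), db)

head(asg[, c("query_id", "status", "neighbour_id", "jc_distance", "genus")], 3)
#>     query_id   status neighbour_id jc_distance      genus
#> 1 read_00001 assigned Prevotella_1           0 Prevotella
#> 2 read_00002 assigned Prevotella_2           0 Prevotella
#> 3 read_00003 assigned Prevotella_3           0 Prevotella

round(100 * sort(table(asg$genus), decreasing = TRUE) / nrow(asg), 1)
#>      Prevotella    Ruminococcus     Fibrobacter     Megasphaera    Butyrivibrio
#>            23.6            17.1            16.5            14.7             9.8
#>   Succinivibrio     Selenomonas Bifidobacterium Syntrophococcus     Mitsuokella
#>             6.9             6.7             3.0             1.2             0.6
```

Error-free reads sit at Jukes–Cantor distance 0 from their source
reference, and the recovered composition is the multinomial draw itself:
the yeast-responsive genera (Megasphaera, Ruminococcus, Fibrobacter) are
enriched relative to the control proportions and Prevotella reduced,
which is the treatment signature the simulation encodes. Shannon
diversity of this sample is 2.00 nats; with all ten genera observed and
no singletons, Chao1 equals the observed richness (10) and Good's
coverage is 1.

Full-pipeline drivers reproduce the complete analysis shapes in one
call: `run_sequence_arm()` (9 samples in a 3×3 Latin square → genus
table, threshold scan, diversity, Morisita–Horn UPGMA tree, restricted
PERMANOVA, differential abundance) and `run_trflp_arm()` (54 profiles ×
4 enzymes → labelled peaks, binned matrices, Bray–Curtis distances,
treatment×fraction UPGMA, PERMANOVAs).

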