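# surfprot

Quantitative cell-surface proteomics for TMT-multiplexed monocyte subsets.

Blood monocytes comprise classical (CD14++CD16−), intermediate
(CD14++CD16+) and non-classical (CD14+CD16++) subsets whose surface
proteomes differ far beyond the markers used to sort them. In plasma
membrane profiling, surface glycoproteins are selectively biotinylated,
enriched, trypsin-digested and labelled with tandem mass tags (TMT), so
that a 3-plex (classical monocytes × 3 donors) and a 9-plex (3 subsets ×
3 donors) can each be quantified in a single MS3 run through reporter-ion
signal-to-noise (S:N). `surfprot` implements the complete post-search
pipeline for such experiments, plus a fully specified synthetic-experiment
generator so every stage is testable without raw mass-spectrometry data.

The chain, in the package's terms:

1. **Reporter extraction** — max-intensity peak within ±0.003 Th of each
   theoretical reporter m/z; S:N = intensity / scan noise.
2. **PSM quality filters** — combined S:N ≥ 15 per channel (135 for the
   9-plex, 45 for the 3-plex), missing-channel and isolation-specificity
   (≥ 0.70) rules, with every disposition tallied.
3. **Target–decoy FDR** — best score per peptide, then per protein, each
   thresholded at 1%: the smallest score t with #decoys(≥t)/#targets(≥t)
   ≤ level.
4. **Parsimony inference** — merge indistinguishable proteins, select
   anchor proteins (unique peptide evidence), then greedy set cover.
5. **Protein signal** — per-channel S:N summed over a group's PSMs;
   loading factors checked against (0.33, 3.0); **fractional signal**
   = channel S:N / row maximum, so every protein peaks at exactly 1.
6. **iBAQ-style abundance** — summed MS1 max precursor intensity over
   distinct peptides ÷ theoretically observable tryptic peptides
   (cleave after K/R except before P, lengths 7–30); contributions as
   percentages, MHC class I/II poolable; inter-donor %CV on
   loading-normalized S:N.
7. **Surfaceome filter** — GO cellular-compartment terms 'plasma
   membrane', 'cell surface', 'extracellular', or a short 4–5-part
   'integral to membrane' term with no other compartment.
8. **Subset comparison** — PCA over samples; k-means scan k = 1…20 with
   log-log tail elbow detection; pooled-variance t-tests per subset pair
   with per-family Benjamini–Hochberg correction; cluster-gated marker
   calls; centroid-linkage hierarchical clustering (Euclidean or
   uncentered correlation) with Newick export; cross-platform
   co-clustering.

## Worked example

```r
library(surfprot)

cfg      <- sim_config(seed = 42L)                 # study-condition defaults
proteome <- generate_proteome(cfg)                 # FASTA + GO + ground truth
design   <- make_study_design("subsets_9plex")     # 126 -> classical d1, ...
psms     <- simulate_experiment(cfg, proteome, design)

quant <- quantify_proteins(psms, pipeline_config(plex_size = 9L), design)
quant$filter_report
#>                  kept drop_missing_channels           drop_low_sn
#>                  7019                     0                   687
#>  drop_low_specificity           drop_no_ms3
#>                   341                     0

surf <- filter_surfaceome(quant$proteins$accession, proteome$annot)
pq   <- quant$proteins[quant$proteins$accession %in% surf$surface, ]
m    <- profile_matrix(pq, design)                 # 255 x 9, row max = 1

scan <- kmeans_scan(m, kmax = 20L, restarts = 50L, seed = 42L)
detect_elbow(scan)
#> [1] 8

cl <- kmeans_cluster(m, 8L, design, restarts = 50L, seed = 42L)
mk <- rank_markers(cl, pairwise_tests(m, design), m, design)
head(mk[mk$direction == "enriched", ], 3)
#>   accession       subset direction cluster  worst_q effect
#> 2    SP0095    classical  enriched       4 0.000412  0.609
#> 7    SP0125    classical  enriched       4 0.000574  0.542
#> 8    SP0016 nonclassical  enriched       8 0.000676  0.591
```

Of 8047 simulated PSMs, 7019 pass the MS3 quality rules (687 fall below
the combined S:N floor of 135, 341 below 0.70 isolation specificity) and
3706 target PSMs survive the two-level 1% FDR filter; 296 protein groups
are quantified, 255 of them surface-annotated. The class-number scan finds
its elbow at k = 8 — the number of profile classes the generator planted —
and the top marker calls are classical- and nonclassical-enriched proteins
with both pairwise comparisons at q < 0.001 and mean fractional-signal
differences of 0.5–0.6.

The abundance side of the same experiment:

```r
ib      <- ibaq_table(quant$psms, quant$inference, proteome$fasta)
contrib <- relative_contributions(ib[ib$estimable &
                                     ib$accession %in% surf$surface, ])
head(contrib$display, 3)
#>    label     ibaq contribution_pct
#> 1 SP0079 1.38e+09            39.12
#> 2 SP0117 4.45e+08            12.63
#> 3 SP0002 3.29e+08             9.33
```

With lognormal copy numbers spanning ~5 orders of magnitude, a handful of
proteins dominates the simulated surface proteome — the concentration the
iBAQ contributions are designed to expose.

A thin CLI wraps the same functions
(`Rscript inst/cli/surfprot.R {run|quant|abundance|surface|subsets|simulate} ...`);
`run` executes all stages and writes per-stage TSVs plus a run log.

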