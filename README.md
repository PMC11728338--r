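# HiCdci

Condition-paired Hi-C analysis: TAD calling, differential chromatin
interactions, and proximity statistics for activated retroviral loci.

## The problem

When human naive iPSCs differentiate into primordial germ cell-like cells
(PGCLCs), specific loci of the hominoid endogenous retrovirus family HML-2
(HERV-K) become strongly transcribed, and the chromatin contact landscape
changes on the megabase scale of topologically associating domains (TADs).
The analytical question is whether *newly formed* chromatin contacts in
PGCLCs lie unusually close to the activated HML-2 loci — closer than random
placement would predict, and increasingly so for more strongly expressed
loci.

HiCdci implements that analysis as a tested, deterministic pipeline for
anyone working with binned, condition-paired Hi-C matrices (Hi-C Pro
sparse-triplet format) plus a table of expressed loci:

1. **ICE balancing** of each contact matrix (iterative correction with
   square-root damping and low-coverage masking).
2. **TAD calling** by k-means clustering of decay-corrected (observed /
   expected) per-bin contact profiles; the partition quality
   `mean(OE intra) − mean(OE inter)` selects the number of clusters.
3. **Differential chromatin interactions (DCIs)**: per-bin paired t-like
   score on depth-matched counts,
   `score(i) = mean(d) / (sd(d)/sqrt(n))` with
   `d = log1p B − log1p A` over a ±5-bin window; runs of bins beyond the
   threshold become directional regions.
4. **Replicate consensus**: per-base intersection of DCI regions across
   replicate pairs, then matching to TAD boundaries of the comparison
   condition.
5. **Proximity statistics**: gap distance from each locus to its nearest
   consensus region; Spearman rank association between expression and
   distance, with the two-sided p from
   `t = rho * sqrt((n−2)/(1−rho²))` on n−2 df; and a genome-randomization
   permutation test of the mean nearest distance,
   `p = (1 + #{null ≤ observed}) / (n_perm + 1)` over 2000 placements
   (lengths preserved, chromosome by length, start uniform), computed per
   expression-rank subset with a shared null.
6. **TAD size statistics**: per-chromosome Mann–Whitney U tests of domain
   sizes between conditions and per-size-class frequency tests
   ([0.2–1), [1–1.5), [1.5–2), [2–2.5) Mb and overflow).

A synthetic-data module generates complete condition-paired studies with
planted TADs, planted differential windows and expressed loci whose
expression is (optionally) inversely related to distance from the planted
windows, so every stage is testable end to end without external data.

## Worked example

```r
library(HiCdci)

## reproduce the published desk number: two-sided t-approximation p-value
## of a Spearman coefficient of -0.5953 with n = 19 loci
round(spearmanPvalue(-0.5953, 19), 4)
#> [1] 0.0072

## 1) simulate a condition-paired study: 2 chromosomes x 300 bins at
##    100 kb, 3 replicate pairs, 4 planted differential windows anchored at
##    planted TAD boundaries, 19 expressed loci with an inverse
##    expression-distance effect
bundle <- simulateBundle(simulationConfig(), "bundle", replicates = 3,
                         seed = 42)

## 2) run the full analysis (ICE -> TADs -> DCI -> consensus -> proximity
##    -> TAD size statistics), with file-based handoffs under bundle/results
cfg <- readPipelineConfig(bundle$configPath)
manifest <- runPipeline(cfg)

## 3) association between locus expression and distance to the nearest
##    boundary-matched consensus DCI
jsonlite::read_json(file.path(cfg$outDir, "association_ranks1_4.json"))
```

On this simulated bundle the run prints, per stage, and ends with:

```
all loci      : n = 19, rho = -0.9526, p_spearman = 0.0000, p_perm = 0.0045
ranks 1-2 only: n = 9, observed mean distance = 64252 bp, p_perm = 0.0015
```

Reading: across all 19 simulated loci, expression and distance to the
nearest consensus DCI are strongly anticorrelated (the planted effect), and
the strongly expressed half of the loci (expression ranks 1–2) lies
significantly closer to the consensus regions than 2000 random placements
of those regions (permutation p ≈ 0.0015). `manifest` records the
configuration, seeds and MD5 checksums of every input and output; rerunning
the same configuration reproduces every file bitwise.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/hicdci-pipeline.R simulate --out bundle --seed 42
Rscript inst/scripts/hicdci-pipeline.R run-all --config bundle/config.yaml
```

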