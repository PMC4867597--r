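# riboclip

Analysis toolkit for studies that pair **CLIP-seq** mapping of an
RNA-binding protein's transcriptome-wide targets with **ribosome
profiling** of the translational consequences of expressing a mutant
allele — the design used to show that the helicase DDX3X binds 5'-UTRs
near start codons and that cancer-associated mutants shift ribosomes from
coding sequences into 5'-UTRs without slowing elongation. The package is
written for computational biologists who need the full statistical chain
reusable and testable: peak calling with control subtraction,
region-normalized metagene profiles, occupancy-shift testing, half-transit
regression, and expression-stability comparison, all exercisable on a
bundled seeded synthetic-data generator.

## The statistics at the core

**Peak calling.** Reads are anchored at their 5' ends on spliced
transcript coordinates. For a sliding window (50 nt, step 25) with IP
count *k*, the null is Poisson:

> p = P(X ≥ k),  X ~ Poisson(λ),
> λ = max(control count × N_IP/N_ctrl, gene rate × window, 1)

with Benjamini–Hochberg correction over all tested windows; touching
significant windows merge, and the summit (maximal per-base coverage,
5'-most on ties) anchors each peak. A gene with ≥1 peak at q ≤ 0.05 is a
*target*.

**Metagene profiles.** Each 5'-UTR/CDS/3'-UTR is rescaled to *n* bins by
`bin = min(floor(offset·n/L), n−1)`; densities are features per kb of
aggregate bin extent (50 bins for CLIP, 20 for condition comparisons, the
latter sum-normalized to 1 across the three regions).

**Occupancy shifts.** Two-sample Kolmogorov–Smirnov on per-anchor
within-region positions (P-site = read 5' end + 12 nt), per gene class
(target / non-target), plus the 5'-UTR/CDS density ratio per condition.

**Half-transit time.** With PMS (total) and PRS (released) labeling series
fitted by least squares, ½τ = t₀(PRS) − t₀(PMS) where t₀ = −intercept/slope;
bootstrap over time points gives the interval and condition comparisons.

**Expression stability.** MA transform `M = log2((y+1)/(x+1))`,
`A = ½·log2((x+1)(y+1))`; flags need |M| > 1 and moderated-t q ≤ 0.05, and a
KS test on M asks whether targets shift as a class.

## Worked example

```r
library(riboclip)

cfg  <- simConfig(seed = 42, nGenes = 200)
anno <- simulateAnnotation(cfg)
anno
#> TranscriptAnnotation with 220 transcripts ( 220 genes )
#>   gene types: ncRNA=10, protein_coding=200, pseudogene=10

clip <- simulateClip(cfg, anno)
pc   <- callPeaks(poolReadSets(clip$ip[[1]], clip$ip[[2]]), clip$control, anno)
pc
#> PeakCall: 22 merged peaks ( 13103 windows tested )
#>   window=50 step=25 pseudocount=1 fdr=0.05 minCount=5

targets <- defineTargets(pc)                       # 22 genes
mean(clip$targets %in% targets)                    # sensitivity vs truth: 1
replicateCorrelation(clip$ip[[1]], clip$ip[[2]], anno)
#> [1] 0.9910054
```

The 22 recovered genes include all 20 truly bound ones; the replicate
correlation of 0.99 reflects the shared per-gene abundance structure the
generator builds in. Comparing ribosome occupancy between wild-type and
mutant conditions:

```r
wt  <- simulateRibo(cfg, anno, "WT")
mut <- simulateRibo(cfg, anno, "G325E")
cc  <- compareConditions(list(WT = wt, G325E = mut), anno, targets)
cc$tests[cc$tests$region == "cds", c("geneClass", "D", "p")]
#>    geneClass          D             p
#> 1     target 0.06319872 2.225074e-308
#> 3 non-target 0.07140980 2.225074e-308
cc$ratios[, c("condition", "geneClass", "utr5_cds_ratio")]
#>   condition  geneClass utr5_cds_ratio
#> 1        WT     target      0.3902078
#> 2        WT non-target      0.3750072
#> 3     G325E     target      1.7407950
#> 4     G325E non-target      1.7593940
```

The mutant's CDS occupancy distribution differs decisively for targets and
non-targets alike, and its 5'-UTR/CDS density ratio rises ~4.5-fold in
both classes — ribosomes accumulate in the 5'-UTR at the expense of the
CDS. Elongation, read out as the half-transit time, is unchanged:

```r
set.seed(1)
ests <- fitHalfTransitTable(simulateTransit(cfg), nBoot = 1000)
ests$WT
#> HalfTransitEstimate [WT]: 1/2 tau = 1.513 min (95% CI 1.393-1.633)
#>   slopes PMS=508 PRS=497; R2 PMS=0.999 PRS=0.999
compareHalfTransit(ests)
#>   conditionA conditionB  difference         p
#> 1     vector         WT  0.02480261 0.8094371
#> 2     vector      G325E -0.06470860 0.5752954
#> 3         WT      G325E -0.08951120 0.3545730
```

A command-line wrapper for the shell-facing steps lives at
`inst/scripts/riboclip` (`simulate`, `callpeaks`, `metagene`, `transit`,
`compare`).

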