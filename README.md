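# hubdiff

Differential intra- and inter-chromosomal Hi-C contact analysis with
multi-omic hub association.

## The problem

Environmental or experimental stimulation can reorganize the 3D genome.
Beyond the well-studied intra-chromosomal structures (loops, TADs), pairs of
chromosomes can gain coordinated *inter*-chromosomal contacts — "hubs" — and
those hubs tend to co-locate with differential epigenomic, transcriptomic and
proteomic changes. Detecting such hubs from a two-condition Hi-C experiment
(e.g. environmentally enriched **EE** vs control **CTL** animals, two
biological replicates each) and quantifying their association with other
differential data sets requires a chain of steps that is usually assembled ad
hoc. `hubdiff` packages that chain as tested, reusable components:

1. **Contact binning** — HiC-Pro-style valid pairs are binned at 100 kb
   (intra) and 1 Mb (inter); sex chromosomes and self-interacting bins are
   removed.
2. **Differential testing** — bin-pair counts are TMM-normalized and tested
   with a negative-binomial GLM (log link, likelihood-ratio test of the
   condition coefficient; Cox–Reid adjusted profile-likelihood dispersions
   with shrinkage). Unwanted variation is removed with RUV-style factors:
   residual-based (RUVr) for intra, control-gene-based (RUVg) for inter, with
   a select-and-intersect strategy (FDR 0.1) across RUV variants for
   mark/expression count tables. Calls use Benjamini–Hochberg FDR < 0.05.
3. **Hub association** — a from-scratch permutation test at 1 Mb: the bins
   carrying differential inter-chromosomal contacts are compared against any
   differential region set by resampling bins from the genome universe
   (default 100,000 iterations), with exact hypergeometric z-scores and
   add-one empirical p-values.
4. **Compartments** — ICE balancing and A/B compartment eigenvectors
   (leading eigenvector of the O/E Pearson correlation matrix).
5. **Proteomics** — the two-contrast iTRAQ consistency statistic
   δ = φ/β (φ = EE1/CTL1, β = EE2/CTL2); proteins with |δ − 1| ≤ 0.1 are
   replicate-consistent.
6. **Small RNA** — the batch-robust strategy: drop miRNAs with < 50 mean
   counts, rpm-normalize, compute EE/CTL fold changes batch-wise, keep only
   features with a reproducible direction of change in every batch, and rank
   by per-batch z-scores.
7. **Linking correlation** — enhancer/promoter RPKM fold changes are
   averaged per linked target gene (average-then-fold-change) and correlated
   with transcriptomic (Pearson) or proteomic (Spearman) fold changes.

A synthetic-data module generates every input with planted ground truth
(hub bin-pairs, batch factors, consistent proteins, reproducible miRNAs, a
known link correlation), so each stage is verifiable at desk scale.

## Worked example

Simulate a 6-chromosome genome with a fold-2 hub of 15 inter-chromosomal
bin-pairs planted between `chr7s` and `chr17s` (2 EE + 2 CTL samples, batch
effect on), recover it, and test whether a hub-clustered mark region set
associates with the recovered bins:

```r
library(hubdiff)

cfg <- sim_config(chroms = c(paste0("chr", 1:4, "s"), "chr7s", "chr17s"),
                  chrom_length = 10e6, n_hub_pairs = 15)
sim <- simulate_hic_counts(cfg, seed = 1, classes = "inter")
flt <- filter_contacts(sim$inter, sim$bins_inter)
da  <- diff_contact_analysis(flt, k = 1, fdr = 0.05)

nrow(da$increased)                     # 14
head(da$increased[, c("id", "log2FC", "p", "q")], 3)
#>        id    log2FC            p            q
#> 1:  40_50 0.9076805 4.518438e-07 0.0001129610
#> 2:  40_56 0.8741857 4.566884e-06 0.0006850326
#> 3:  42_50 0.7138042 3.165804e-04 0.0339193302
```

14 of the 15 planted pairs are recovered at q < 0.05 with log2
fold-changes near the planted log2(2) = 1. Associating the called hub bins
with a clustered and an unclustered mark set (100,000 permutations):

```r
bins  <- sim$bins_inter
hub   <- bins_to_regions(bins, sort(unique(c(da$increased$bin1,
                                             da$increased$bin2))))
query <- region_set(hub$chrom, hub$start, hub$end, label = "diff_inter_bins")
marks <- simulate_mark_regions(sim$truth$hub_bins, bins, n_regions = 30,
                               p_in_hub = 0.8, seed = 2, label = "H3K79me2_up")
ctrl  <- simulate_mark_regions(sim$truth$hub_bins, bins, n_regions = 30,
                               p_in_hub = 0,   seed = 3, label = "H3K27ac_up")
associate_all(query, list(marks, ctrl), bins, n_perm = 1e5, seed = 4)$table
#>          label observed null_mean  null_sd         z       p_emp  stars
#> 1: H3K79me2_up       11       4.2 1.514002  4.491406 2.99997e-05     **
#> 2:  H3K27ac_up        0       5.6 1.618537 -3.459915 1.00000e+00
```

The hub-clustered set overlaps 11 of the 14 differential bins against a
null expectation of 4.2 (z = 4.5, empirical p ≈ 3e-5); the background set
shows no association. `run_all(config)` chains every stage (contacts →
mark bins → association → δ → miRNA → link correlation) on a config
produced by `simulate_dataset()` or written by hand, and emits TSV outputs
plus a JSON run summary with per-output checksums.

A command-line front end with `simulate`, `run-all`, `assoc`, `delta` and
`mirna` subcommands is installed at `inst/cli/hubdiff.R`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
models, the synthetic-data generators and their defaults, numerical choices,
and known limitations (including one deliberately red acceptance clause).
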