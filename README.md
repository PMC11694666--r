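# reefnet

Abundance-resolved virus–bacteria interaction networks for marine
microbial communities.

## What it does, and for whom

Environmental virology can now ask not just *how many* viruses a water
sample holds, but *who infects whom and how actively*. reefnet is an R
package for analysts working with that study design in oligotrophic
seawater (coral reef boundary layers and similar systems). It takes three
streams of virus–host link evidence — proximity-ligation (Hi-C) contact
tables, prophage BLAST alignments, and CRISPR spacer matches — together
with size-fractionated metagenome read counts and epifluorescence
microscopy counts, and produces a species-level bipartite infection
network in which every virus and host carries an absolute abundance
(genomes per ml).

The core quantities:

* **Link inference.** Prophage alignments are kept at ≥ 95 % identity and
  ≥ 99 % coverage of the viral contig; spacer matches at ≤ 2
  mismatches+gaps, 100 % coverage, ≥ 20 nt; Hi-C links by a transparent
  contact-count/score filter. Genomes are dereplicated by single-linkage
  clustering (viruses: 95 % ANI + 80 % shared genes; hosts: 95 % ANI) and
  evidence is collapsed to unique virus-population × host-species pairs.
* **Microscopy-scaled abundance.** Length-normalized relative abundances
  (reads/genome length, renormalized per sample) are multiplied by direct
  VLP and cell counts to genomes/ml. Per linked pair, the virus-to-host
  ratio VHR = virus genomes/ml ÷ host genomes/ml is computed in the free
  (< 0.45 µm) and cell-associated (> 0.22 µm) fractions; the
  cell-associated VHR proxies ongoing viral production. Quartiles of the
  per-pair median VHRs classify pairs into four production categories
  (high/low × free/cell-associated) plus a middle class.
* **Network structure.** For the hosts × viruses incidence matrix *A*
  with virus degrees *d*, host degrees *k* and *m* links, the package
  computes NODF nestedness, Atmar–Patterson-style matrix temperature, and
  Barber bipartite modularity

  &nbsp;&nbsp;&nbsp;&nbsp;Q<sub>B</sub> = (1/m) Σ<sub>ij</sub> (A<sub>ij</sub> − k<sub>i</sub>d<sub>j</sub>/m) δ(g<sub>i</sub>, g<sub>j</sub>),

  maximized by seeded label propagation with agglomerative refinement and
  normalized by the Q of the idealized fully-within-module matrix with
  the same marginals. Significance uses a conserved size-and-fill null
  model (positions of the 1s shuffled uniformly).
* **Proteomic trees.** Dice distances over summed protein homology
  bitscores, D<sub>AB</sub> = 1 − 2·AB/(AA + BB), feed a neighbor-joining
  tree written as Newick.

A seeded synthetic community generator (`simulateCommunity()`,
`simulateEvidence()`) reproduces the full study design — log-normal host
community with a dominant linkless lineage, planted modular-and-nested
infection structure, temperate/lytic lifestyles, multinomial read
sampling, noisy microscopy totals — so the entire pipeline is testable
against known ground truth without any downloads.

## Worked example

```r
library(reefnet)

truth <- simulateCommunity(seed = 1)   # study-scale synthetic community
truth
#> CommunityTruth: 51 hosts, 88 viruses, 6 samples
#>   planted links: 114 | modules: 29 | temperate viruses: 44 | prophage carriers: 44
#>   seed: 1

res <- runDemo(dir = tempfile(), seed = 1)   # evidence tables + full pipeline
m <- res$bundle$network$metrics
cat(sprintf("unique pairs: %d (%d viruses x %d hosts)\n", m$n_links, m$n_viruses, m$n_hosts))
#> unique pairs: 114 (88 viruses x 47 hosts)
cat(sprintf("normalized modularity Q = %.3f with %d modules\n", m$q_normalized, m$n_modules))
#> normalized modularity Q = 0.991 with 27 modules
cat(sprintf("specialist viruses: %.1f%%\n", m$specialist_percent))
#> specialist viruses: 73.9%
median(res$bundle$abundance$microscopy$cells_per_ml)
#> [1] 956646.8
table(res$bundle$vhr$categories$category)
#>      1      2      3      4 middle
#>     11      6      8      5     84
```

Reading these numbers: the pipeline recovered 114 unique virus–host
pairs, all of them planted links (the four dominant hosts carry no links
by construction, hence 47 of 51 hosts appear). The network is almost
perfectly modular (Q ≈ 0.99; the planted structure is block-diagonal),
the median bacterial density lands near 9.6×10^5 cells/ml as configured,
and the VHR quartiles split the pairs into the four production categories
with most pairs in the middle class. Pipeline outputs (links.tsv,
abundance.tsv, vhr.tsv, vhr_categories.tsv, network_metrics.json,
modules.tsv, tree.nwk, run manifest) land in `<dir>/results/`.

For real data, point a YAML config at your own tables and run
`runPipeline(readRunConfig("run.yaml"))`, or use the thin CLI wrapper in
`inst/scripts/reefnet.R` (`Rscript reefnet.R all --config run.yaml`).

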