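# guideBalancer

Selection of single guide RNAs (sgRNAs) for engineering **balancer
chromosomes** with CRISPR/Cas9.

Balancer chromosomes carry multiple inversions that suppress meiotic
crossovers, which is what lets fly geneticists maintain recessive lethal
mutations in stable stocks. Cas9 double-strand breaks at several positions
along one chromosome can seed such inversions — but the guide doing it has
unusual requirements: it must cut its **own** chromosome at multiple,
well-spaced sites, and essentially nowhere else in the genome.
`guideBalancer` scans a genome for exactly such guides and ranks them.

## The method in brief

For every chromosome, the pipeline:

1. **Scans** both strands for 23-bp target sites (20-nt protospacer +
   5'-NGG-3' PAM), recording the blunt-cut coordinate 3 bp 5' of the PAM.
2. **Bins** sites by their 18-bp PAM-proximal seed and merges each bin's
   cut positions; a guide whose seed occurs *exactly* on another
   chromosome is rejected outright.
3. **Models protection**: each cut suppresses recombination over ±2 Mbp;
   merged, clipped windows give the chromosome *coverage* ∈ [0, 1]. Bins
   exceeding the ideal cut count ⌈L / 4 Mbp⌉ or below the coverage
   threshold (default 0.70) are removed.
4. **Scores on-target** efficiency with a pluggable logistic
   position-weight model (bin average ≥ 0.5 by default).
5. **Scores off-targets** on all other chromosomes with the multiplicative
   CFD mismatch-penalty model (≤ 4 spacer mismatches), and sums
   per-chromosome burdens soCFD_j over hits with CFD ≥ 0.2.
6. **Ranks** by the sgRNA Sequence Value

   SSV = Coverage_i / (1 + Σ_{j≠i} soCFD_j)

   reporting the top 5 guides per chromosome with coverage, cut positions,
   average on-target score and the off-target denominator.

The shipped CFD and on-target tables are deterministic *synthetic*
heuristics (see `inst/extdata/synthetic_default_*.tsv`); supply measured
matrices via `readScoreTables()` for production designs.

## Worked example

```r
library(guideBalancer)

# a 28 kb two-chromosome toy genome with one ideally spaced planted guide
fx <- simulateGenome(
  c(chr1 = 16000L, chr2 = 12000L),
  guides = list(list(chrom = "chr1",
                     protospacer = "TTTAACCCACGGTATACCGC", pam = "TGG",
                     positions = c(1983L, 5983L, 9983L, 13983L))),
  seed = 1)

cfg <- balancerConfig(fx$genome, flank = 2e3)   # scaled geometry: 2 kb flank
run <- runBalancerDesign(cfg, quiet = TRUE)
guideReports(run)[, c("chrom", "sgrna_23mer", "ssv", "n_cuts", "coverage")]
#>   chrom             sgrna_23mer ssv n_cuts coverage
#> 1  chr1 TTTAACCCACGGTATACCGCTGG   1      4        1
```

The planted guide cuts chr1 at 2000, 6000, 10000 and 14000 (0-based) —
the ideal count of 4, evenly spaced — so its protection windows tile the
chromosome: coverage 1.0. It has no off-target burden, so its SSV equals
its coverage, 1.0. The run manifest (`runManifest(run)`) records the full
filtering funnel: sites scanned, bins formed, and how many bins each
filter removed.

A command-line wrapper is included:

```sh
Rscript inst/scripts/design-balancer-guides.R \
  --genome genome.fa --genes genes.bed \
  --out report.tsv --manifest manifest.json
```

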