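---
title: "Designing multi-cut sgRNAs for balancer chromosomes: model and methods"
author: "guideBalancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-cut sgRNAs for balancer chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guideBalancer)
```

## The design problem

Balancer chromosomes suppress meiotic recombination through multiple
inversions, which keeps recessive lethal mutations paired with their
wild-type allele across generations. CRISPR/Cas9 can seed such inversions:
double-strand breaks at several positions along one chromosome can resolve
as inversions during repair. The engineering question is which single guide
RNA (sgRNA) to use. A good guide for this purpose is unusual by ordinary
CRISPR standards: it should cut its *own* chromosome at several, widely
spaced positions, and nowhere else in the genome.

`guideBalancer` searches a genome for such guides and ranks them. One guide
per chromosome suffices in the ideal case, which minimizes rounds of
transformation and the number of generations screened.

## Model

### Target sites and cut coordinates

A candidate site (PTS) is a 20-nt protospacer followed by an NGG PAM, on
either strand. SpCas9 cuts bluntly 3 bp 5' of the PAM, so a plus-strand
site whose protospacer starts at 0-based position $s$ cuts at $s + 17$,
and a minus-strand site whose PAM complement (the plus-strand CCN triplet)
starts at $p$ cuts at $p + 6$. Sites whose 23-mer contains N are excluded
— ambiguity codes in the input are normalized to N first, so uncertain
sequence can never nominate a guide. Overlapping PAMs (e.g. a GGG run) all
count; no deduplication is applied.

### Seed bins and cross-chromosome rejection

Cas9 mismatch tolerance falls toward the PAM, so two sites sharing their
PAM-proximal sequence are treated as cut-equivalent. We bin sites by the
18 nt of the protospacer nearest the PAM (the two PAM-distal bases and the
PAM itself are excluded from the seed; which bases the original concept
included was never spelled out, so this is a documented choice in line
with the position-dependence of mismatch tolerance). A bin merges the cut
positions of all its members on one chromosome; its representative 23-mer
is the most frequent full site among members, ties broken
lexicographically.

A bin is discarded outright if its seed occurs *exactly* on any other
chromosome: such a site would be cut regardless of PAM-distal mismatches,
and no scoring can rescue it. Near matches (one or more seed mismatches)
are not rejected; they are handled quantitatively by CFD scoring below.

### Coverage: the protection model

In *D. melanogaster*, recombination is suppressed within roughly 2 Mbp on
each side of an inversion breakpoint. We adopt that span genome-agnostically
and on physical distance: each cut at position $c$ on a chromosome of
length $L$ protects $[\max(0, c - f), \min(L, c + f))$ with flank
$f = 2\,\mathrm{Mbp}$; overlapping windows merge, windows clip at
chromosome ends (no wraparound), and

$$\mathrm{Coverage} = \frac{\text{protected bp}}{L} \in [0, 1].$$

The *ideal cut count* is $\lceil L / w \rceil$ with $w = 2f = 4$ Mbp: the
fewest cuts that could protect the whole chromosome, achieved exactly by
even spacing. Bins with more cuts than ideal are rejected (strict excess;
extra cuts cannot improve an even layout and only add off-target
exposure); the ceiling rather than rounding is a deliberate choice, as the
ideal count at which full coverage is attainable requires rounding up. No
*minimum* cut count is imposed beyond what the coverage threshold itself
implies. Bins below the coverage threshold (default 0.70, configurable —
chosen to match the reported achievable regime of 70%-plus coverage on
model genomes) are rejected. Equal cut counts can yield very different
coverage: four clustered cuts protect little more than one, which is
exactly the failure mode the filter removes.

The interval-union computation goes through `IRanges::reduce`; an
independent per-basepair mask implementation (`maskCoverage()`) is kept in
the package and used by the test suite to cross-validate the interval
arithmetic to $10^{-9}$, and by the fixture generator to compute coverage
ground truth without touching the interval code.

### On-target scoring

On-target efficiency models are external to this method: the pipeline only
needs *some* score in $[0,1]$ per site and a threshold. The scorer is
therefore pluggable. The default is a logistic position-weight model over
the 30-nt context (4 nt upstream, 23-mer, 3 nt downstream) plus a GC-count
feature over the protospacer; its coefficient table is a replaceable TSV
asset, and the shipped default is a synthetic heuristic (mild positional
weights centered above 0.5), clearly labelled as such. Sites too close to
a chromosome end to have a full context are "unscorable" and receive a
configurable neutral score (default 0.5) rather than a padded sequence. A
bin's score is the arithmetic mean over member sites; bins below the
on-target threshold (default 0.5; survival comparisons throughout the
package are $\ge$-inclusive) are removed.

### Off-target scoring: CFD and soCFD

For each surviving bin, the representative protospacer is compared to
every PTS on every *other* chromosome (the candidate space is NGG sites,
mirroring the PTS-vs-PTS comparison; NAG and other non-NGG off-target
PAMs are not searched, a documented narrowing relative to broader CFD
practice). Sites with at most `maxMismatches` (default 4) spacer
mismatches are scored with Cutting Frequency Determination:

$$\mathrm{CFD} = \prod_{i \in \text{mismatches}} p(i, g_i, t_i) \times p_\mathrm{PAM}(t_{22}t_{23})$$

with positions counted 1-20 from the PAM-distal end. Matched bases score
1, a perfect match with GG PAM scores exactly 1, and all penalties lie in
$[0,1]$. The default penalty matrix is a deterministic synthetic heuristic
(penalties decaying toward the PAM; transitions tolerated more than
transversions), shipped as a labelled-synthetic TSV asset and replaceable
by any user-supplied matrix in the same format. Per off-chromosome $j$,

$$\mathrm{soCFD}_j = \sum_{\text{hits on } j,\ \mathrm{CFD} \ge \tau} \mathrm{CFD},$$

with $\tau = 0.2$ by default (the threshold concept is inherited from the
CFD literature without a published value; 0.2 is surfaced in the
configuration and manifest rather than buried). Same-chromosome near
matches are deliberately ignored — the ranking sum runs over $j \ne i$
only, and extra cuts on the target chromosome are the *goal* of this
design, not a liability.

### Ranking: the sgRNA Sequence Value

$$\mathrm{SSV} = \frac{\mathrm{Coverage}_i}{1 + \sum_{j \ne i} \mathrm{soCFD}_j}$$

SSV equals coverage for a perfectly clean guide and shrinks as off-target
burden accumulates; $0 \le \mathrm{SSV} \le \mathrm{Coverage} \le 1$
always. Users may disable off-target consideration, which forces the
denominator to 1. Reports carry the denominator
$1 + \sum_j \mathrm{soCFD}_j$ explicitly so the arithmetic is auditable.
Within each chromosome, candidates sort by SSV, then coverage, then
average on-target score, then lexicographic sequence — a total order, so
output is independent of input order — and the top 5 (configurable) are
reported.

## Pipeline order and determinism

Stages run in a fixed order: scan, seed-bin, cross-chromosome rejection,
cut-count/coverage filter, on-target filter, off-target CFD, SSV ranking.
The cheap geometric filters run before the quadratic off-target
comparison, which is what makes the comparison affordable. Scanned sites
spill to a documented tab-delimited temporary file past a configurable
in-memory budget. There is no randomness anywhere in the pipeline; the run
manifest records every stage's input/output counts and all effective
parameters, and two runs on identical inputs are byte-identical.

## Coordinates and file formats

Internally, positions are 0-based half-open and the cut coordinate is the
plus-strand position of the base immediately 3' of the blunt cut;
interval-union arithmetic converts explicitly to the 1-based closed
`IRanges` convention at that boundary. All user-facing output is 1-based
inclusive. Genomes are FASTA (plain or gzipped). Gene locations are
accepted as standard BED3+ — a deliberate dialect substitution for the
loosely specified "FASTA-formatted" location lists the original tool
mentions, chosen because BED is the interoperable interval standard.
What to *do* with gene locations was also never specified, so they are
annotation only: each report counts how many cut positions fall inside a
gene, and this never changes scores or ranks.

## The synthetic fixture generator

`simulateGenome()` builds genomes with exactly known content: random
background at a chosen GC (default 0.40, a typical eukaryotic value),
planted 23-mer guide sites at exact positions and strands, planted
off-target sites derived from a guide by explicit base edits, and planted
gene intervals. Background windows that accidentally contain a planted
guide's seed (either orientation) are re-drawn, so seed-level expectations
are exact rather than probabilistic; the scrub is bounded and logged.
Identical seeds give byte-identical genomes.

Fixtures emulate site geometry, seed collisions and mismatch structure.
They do not emulate real genome composition — repeats, segmental
duplications, GC isochores — so passing tests demonstrate algorithmic
correctness, not biological performance on real assemblies; repeat-dense
genomes will reject far more seeds than random backgrounds do. Test
fixtures mostly use a scaled geometry (flank 2 kb, window 4 kb, 10-100 kb
chromosomes): coverage is scale-invariant (scaling positions, length and
flank together leaves it unchanged, a property the suite checks), so the
scaled geometry exercises the same interval mathematics in milliseconds.
The acceptance script runs the full cascade on a 28 kb two-chromosome
fixture with one ideally spaced guide, one clustered decoy and one
off-target-bearing decoy.

## Numerical and degenerate-input choices

* Threshold comparisons are $\ge$-inclusive for survival and summation.
* Chromosomes shorter than 23 bp yield an empty scan with a notice, not an
  error; an empty final report is a success with a warning.
* A cut at position 0 protects only one flank; cuts must satisfy
  $0 \le c < L$ or a named error is raised.
* Ranking ties break deterministically (coverage, on-target,
  lexicographic), and every error condition carries a distinct class
  (`gb_*`) so callers can discriminate failure modes.
* Scanning processes one chromosome at a time; memory scales with the
  largest chromosome plus the site budget, not the genome.

## Known limitations

* The default CFD and on-target tables are synthetic heuristics: rankings
  with defaults are internally consistent but not calibrated to
  experimental cutting data. Supply published matrices as TSV assets for
  production use.
* The 2 Mbp suppression span is a fly-derived estimate applied to all
  genomes on physical distance; organisms with very different
  recombination landscapes will be mis-modelled in absolute terms, though
  relative ranking within a genome is unaffected.
* Off-target search is mismatch-only (no DNA/RNA bulges) and NGG-only.
* Guides are ranked individually; the tool does not co-optimize sets of
  guides across chromosomes.

## A worked example

```{r example, eval = FALSE}
fx <- simulateGenome(
  c(chr1 = 16000L, chr2 = 12000L),
  guides = list(list(chrom = "chr1",
                     protospacer = "TTTAACCCACGGTATACCGC", pam = "TGG",
                     positions = c(1983L, 5983L, 9983L, 13983L))),
  seed = 1)
cfg <- balancerConfig(fx$genome, flank = 2e3)
run <- runBalancerDesign(cfg)
guideReports(run)
runManifest(run)$counts
```

The planted guide cuts at 2000, 6000, 10000 and 14000 (0-based) — the
ideal count of 4 for a 16 kb chromosome at window 4 kb, evenly spaced —
so it is reported at rank 1 with coverage 1.0 and, with no off-target
burden, SSV 1.0.
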