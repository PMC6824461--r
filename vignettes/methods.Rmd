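---
title: "Scaffolding genomes with Hi-C: models and design choices"
author: "hicscaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding genomes with Hi-C: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inference problem

Hi-C measures, genome-wide, how often pairs of loci are cross-linked in
the nucleus. Within a chromosome the contact frequency between two loci
decays with their genomic distance roughly as a power law, while loci on
different chromosomes share only a flat, much weaker background. A contact
matrix binned over a *fragmented* assembly therefore encodes the linear
order of the fragments: bins that are truly adjacent in the genome share
far more contacts than bins one fragment-length apart, which in turn share
far more than inter-chromosomal pairs. `hicscaffold` turns that signal
into chromosome-length scaffolds. Its modelling assumptions are exactly
two: monotone contact decay with distance within chromosomes, and an
approximately flat trans background below the cis signal at the relevant
scales. Nothing else about genome biology is assumed.

## Pipeline stages and their parameters

### Coverage filtering (`mad_filter_bins`)

Per-bin coverage is the row sum of raw counts. Removed are bins with zero
coverage, bins below the `low_count_quantile` of nonzero coverages
(default **0.01**), and bins whose robust z-score
$(c_i - \mathrm{median}(c)) / (1.4826\,\mathrm{MAD}(c))$ exceeds
`mad_z_high` (default **1.6**, one-sided). The high cut targets collapsed
repeats, which appear as implausibly high coverage; the one-sidedness is
deliberate, since *low* coverage is often biologically real. On the low
side we remove only the extreme tail: bins flanking scaffold ends and
chimeric junctions legitimately have reduced coverage because half of
their neighbourhood is missing, and removing them would blind the
misassembly detector exactly where it must look. (An earlier candidate
default of the 5th percentile did precisely that in simulation.)

### Balancing (`ice_correct`)

Multiplicative row/column balancing of the retained submatrix, iterated
until the coefficient of variation of retained row sums drops below `tol`
(default **1e-5**, cap **200** iterations; non-convergence returns the
best iterate with a warning and a `converged = FALSE` attribute). The
balanced matrix is rescaled to conserve the total raw contact mass so
that corrected values stay on the count scale; per-bin factors are stored
and survive a round-trip through the on-disk format. Balancing is scale
invariant by construction.

### Misassembly detection (`separation_score`, `find_split_positions`)

For an internal bin boundary $b$ and window $w$, the score is the mean
balanced contact over pairs $(p, q)$ with $b-w \le p < b \le q < b+w$,
restricted to retained bins of the same scaffold; the raw score averages
over $w$ from `min_depth` to `max_depth` in steps of `step`. Defaults are
derived from the bin size as the equivalents of **15 kb / 50 kb / 2 kb**,
floored at 3 bins — the window range standard for insulation-based domain
calling at these resolutions. Windows truncated by a scaffold end are
skipped, so no score exists within `min_depth` of an end; scaffolds with
fewer than 10 scored boundaries are left unscored because a z-score over
so few values is meaningless. Scores are z-standardized jointly across
all scaffolds (the comparison the detector makes is against the global
signal level, not a per-scaffold one). A split is called at strict local
minima with $z <$ `z_threshold` (default **−1.0**). Splitting renames
parts `<id>/1`, `<id>/2`, … and touches only the bin-to-scaffold binding;
contact entries and total mass are untouched. A boundary erroneously
split (a strong domain boundary, say) is simply rejoined by the assembly
stage later; no special casing is needed.

### Iterative joining (`hic_assemble`)

Scaffolds shorter than `min_scaffold_length` (default **150 kb**) and
ignore-listed scaffolds are set aside first; they carry too few contacts
to be ordered reliably and are reinserted at the end. Each of
`num_iterations` (default **3**) iterations then runs:

1. **Partition** (`make_merge_groups`): each current Hi-C scaffold
   contributes $k = \max(1, \mathrm{round}(L/T))$ contiguous, near-equal
   parts, where $T$ is the length of the smallest current Hi-C scaffold.
   `round` is R's round-half-to-even; at the relevant scales only the
   $L = 2.5T$ boundary case is affected.
2. **Merge + re-balance** (`merge_bins`): part-level matrix entries sum
   each unordered bin pair once; because parts have variable bin counts
   the merged matrix is re-balanced with the same routine and tolerance
   as the full matrix (nothing suggested a looser tolerance would be
   safer, and re-using the routine keeps the code honest).
3. **Cutoff** (`estimate_cutoff`): the median corrected contact between
   parts of the same scaffold at part-distance 2 — i.e. separated by one
   part, one scaffold-length of material. Edges weaker than this level
   are not credible adjacency evidence; in particular the flat trans
   background sits well below it at any realistic depth, which is what
   keeps chromosomes separate without any clustering step.
4. **Graph + maximum spanning forest** (`build_scaffold_graph`,
   `max_spanning_tree`): edges strictly below the cutoff are removed
   (ties at the cutoff survive, matching the "below threshold" wording
   of the rule); Kruskal's algorithm runs on edges sorted by weight
   descending, then smaller endpoint id, then larger endpoint id, so the
   forest is deterministic under ties.
5. **Hub resolution** (`resolve_hubs`): in the first iteration every
   single-node branch hanging off a degree-≥3 node is pruned and queued
   for reinsertion (stray attachments, typically repeat-rich fragments);
   then each hub keeps its two heaviest incident edges until the maximum
   degree is 2 and the forest decomposes into simple chains.
6. **Orientation** (`orient_and_join`): for each chain the original
   high-resolution bins of its members are gathered and each candidate
   orientation assignment is scored with
   $\mathrm{score}(a) = \sum_{i<j} a_{ij}\,|i-j|$ on the rearranged
   submatrix; the minimizing assignment wins. We use the absolute
   distance $|i-j|$ as the weight: off-diagonal mass must *raise* the
   score for minimization to concentrate contacts at the diagonal (a
   signed weight $i-j$ would reward, not punish, distant contacts).
   Chains of up to `max_exhaustive` (default **8**) units are solved by
   full $2^k$ enumeration (256 scoring passes); longer chains solve the
   first pair exhaustively and extend greedily, two candidate flips per
   appended unit. The score is invariant under simultaneous reversal of
   the whole bin order, so each chain's orientation is identifiable only
   up to a global reflection; results are reported with the first unit
   forward. Parts of a divided scaffold re-fuse with their stored
   internal orientations. Edge weights throughout use balanced counts —
   coverage bias would otherwise masquerade as proximity.

**Degenerate partitions.** When no current Hi-C scaffold divides into
three or more parts (all fragments of similar size), the distance-2
stratum is empty and the cutoff is undefined. Proceeding with a cutoff of
0 would be worse than stopping: the spanning forest would happily bridge
chromosomes through the trans background. The driver instead retries the
iteration with part sizes $T/2$ and then $T/4$ — the part size is "about
the size of the smallest scaffold" by construction, not a hard
constraint, and halving it restores a distance-2 stratum while keeping
the cutoff and the graph it thresholds mutually consistent. If even
$T/4$ yields no stratum, the iterative phase stops early rather than make
joins the confidence model cannot vouch for; at convergence (one chain
per chromosome) this is exactly the desired stopping behaviour.

### Reinsertion (`insert_small`)

Set-aside scaffolds and first-iteration prunings are placed back against
the finished chains. A scaffold-level contact graph pins existing
chain-neighbour edges at the maximum weight (so the spanning forest can
never cut a chain) and weights removed-scaffold edges by their summed
balanced contacts, thresholded at the median contact of consecutive
assembled bins (computed genome-wide: the median is a robust global
reference and per-chain strata would be thin). On the forest, removed
scaffolds form branches hanging off chain nodes; tree-shaped branches are
first reduced to paths by the same top-two rule. Each path is oriented by
the same score minimization (anchor fixed as placed) and spliced in next
to its anchor. The side is chosen by
$W(\text{path far end}, v) - W(\text{anchor}, v)$ for each neighbour $v$
of the anchor (absent neighbour scoring 0): the path displaces a
neighbour only when its far end out-contacts the anchor's direct link to
that neighbour, and a path that belongs beyond a chain end is appended
outward. (The naive rule "side of the neighbour with more contacts"
cannot append outward at all.) Branches with no anchor become unplaced
chains or, as singletons, unplaced originals; the multiset of scaffold
ids is conserved exactly.

### Writers

All three writers derive from a single layout table
(`assembly_layout`), which makes FASTA, UCSC chain and AGP v2.1 output
consistent by construction — the property tests parse the three files
independently and cross-check them anyway. Joined scaffolds are separated
by `gap_n` = **2000** Ns; FASTA headers are
`hic_scaffold_<k> <id>:<strand>,...` with Hi-C scaffolds numbered by
decreasing length. Chain records map original scaffold (target) to
assembly (query) coordinates, with minus-strand query coordinates in
reverse-complement space per the chain specification, so lifting any
interval through a chain and back is the identity.

## The synthetic generator

`sim_params()` defines the study conditions: two 5-Mb chromosomes, 10-kb
bins, contigs drawn uniformly from 200–700 kb (about 20–25 contigs over
10 Mb, contig N50 near 500 kb — the scale of hybrid short/long-read
assemblies), $5\times10^6$ total contacts, intra-chromosomal rate
$\lambda \propto (d + d_0)^{-\alpha}$ with $\alpha = 1$ and $d_0$ = one
bin (fractal-globule-like decay), a flat trans rate carrying 5 % of the
mass, independent Poisson counts, and optional chimeric contigs
(`chimera_rate`) concatenating fragments of different chromosomes with
the junction recorded. Contigs are independently strand-flipped and
emitted shuffled. All stages are deterministic given `seed`.

What this emulates: the statistical structure the algorithm actually
uses — decay, flat trans background, shot noise, fragment shuffling,
chimeras. What it deliberately does not emulate: restriction-site
geometry, mappability and GC bias, copy-number variation, repeats and
collapsed repeats, overdispersion beyond Poisson (a gamma-mixing knob
exists in principle but is off by default), or structural features such
as domains and compartments. Passing the end-to-end tests therefore shows
the *algorithm* is correct under its own assumptions at realistic depth;
it does not show robustness to repeat-rich real genomes, which is what
the ignore-list and manual split file exist for.

`evaluate_assembly()` scores an assembly against the truth: adjacency
accuracy (truly adjacent pairs placed adjacently in the correct relative
orientation), orientation accuracy (per chain, under the better global
reflection), grouping purity (co-chained pairs sharing a chromosome), and
chain count. All metrics are invariant to chain order and reversal.

## Problem sizes used by the tests

Unit tests run on matrices of tens of bins with exhaustive oracles
(all spanning trees of graphs of ≤ 7 nodes; direct double-sum scoring;
brute-force insulation diamonds). The end-to-end suite runs ten seeded
simulations at the full study conditions (≈ 1000 bins, ≈ 5 M contacts
each) plus three chimera simulations; the whole suite completes in about
a minute on one core, and `scripts/acceptance.R` in well under a minute.

## Known limitations

* Orientation of a whole chain is unidentifiable from Hi-C; we fix the
  first unit forward and evaluation respects the reflection.
* Very short scaffolds (a handful of bins) orient on little evidence;
  below `min_scaffold_length` they are only placed, and their strand
  should be treated as tentative.
* The misassembly detector needs roughly `min_depth` scored bins on each
  side of a junction; junctions within ~30 kb of a scaffold end are
  invisible to it (the manual split file covers those).
* Chromosome-scale inversions between chromosomes of near-identical
  contact profiles could in principle tie the score; ties are broken
  deterministically but arbitrarily.
* The pipeline assumes the input matrix was built from reads mapped to
  the same scaffold set as the FASTA; it never re-bins or re-maps.
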