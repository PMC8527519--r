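---
title: "Designing and testing MAGIC populations by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and testing MAGIC populations by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magicpop)
```

## The problem

A Multiparental Advanced Generation Inter-Cross (MAGIC) population is built
by crossing n founders through a structured *funnel* — two-way crosses, then
four-way, then eight-way, and so on — followed by several generations of
selfing that produce near-homozygous recombinant inbred lines (RILs).
Constructing such a population takes years, and the crossing scheme fixes
properties that cannot be repaired afterwards: how much recombination the
RILs carry, how evenly it is spread over founder pairs, and how evenly the
founder genomes are represented.  magicpop lets a breeder specify a candidate
design, expands it into the explicit pedigree that field teams would execute,
simulates the resulting RIL population many times, and scores each design so
that alternatives can be compared before any seed is sown.

## Funnels and their combinatorics

A funnel is a complete crossing tree over the founders, written as its leaf
order: `1234` means `((1x2)x(3x4))`.  Cross direction is ignored, so leaf
orders that differ only by swapping the two parents of any cross are the same
funnel; every equivalence class for a power-of-two n has `2^(n-1)` members,
giving `n!/2^(n-1)` distinct funnels — 3 for four founders, 315 for eight.
`canonical_funnel()` maps any leaf order to its class representative (the
subtree containing the smaller founder first at every node), and
`enumerate_full_funnels()` lists all classes.

For founder numbers that are not powers of two, we fix the crossing-tree
shape: at every generation consecutive lineages are paired and an unpaired
lineage advances unchanged.  Under that shape each class has `2^s` members,
where `s` counts the internal nodes whose two child subtrees have the same
shape, so the count `n!/2^s` is closed-form for every n; the tests verify it
against brute-force enumeration for n = 3–8.

Design types follow the field's taxonomy: *full* (all funnels), *partial
balanced*, *partial unbalanced* (funnels drawn at random), and *basic* (one
funnel).  A design is *balanced* when every founder appears equally often and
every founder pair is brought together equally often at each crossing
generation.  For eight founders the minimal balanced set has seven funnels:
the seven two-way levels must partition all 28 founder pairs (a
1-factorization of the complete graph K8) and every pair must occur exactly
twice at the four-way level — each pair then occurs four times at the
eight-way level automatically, because every pair meets exactly once per
funnel.  `enumerate_balanced_sets(8)` runs an exact-cover backtracking over
these constraints and finds exactly 720 minimal sets; minimal sets that share
no funnel can be concatenated into larger balanced designs.  For other
founder numbers (5–16, excluding the enumerable 4 and 8) no exhaustive search
is practical, and classical balanced-design constructions (nested
incomplete block designs) specify the property rather than an algorithm; we therefore search by seeded simulated annealing over funnel
replacements and within-funnel founder swaps, minimizing the summed squared
deviation of the pair-count profile, and accept **only** an exactly balanced
result — an unbalanced near-miss raises an error rather than being returned
silently.  `balanced_set_size()` exposes the divisibility condition (pairs
per funnel per generation must divide the pair count evenly) that determines
the minimal set size: 3, 7 and 15 funnels for 4, 8 and 16 founders.

## From design to pedigree

`build_scheme()` expands a design into explicit cross and self rows.  Three
rules matter:

* **Deduplication.** Funnels share lower-generation crosses: the 315 funnels
  of a full eight-founder design reuse the same 28 two-way crosses and 210
  four-way crosses.  One cross appears once per generation regardless of how
  many funnels contain it.
* **Replicates.** `replicates[g]` is the number of seeds retained per cross
  at generation g.  Each seed is an independent meiosis (replicated two-way
  seeds are genetically identical only because their parents are inbred).
  Seeds are paired index-wise for the next generation's crosses, so r
  four-way replicates yield r eight-way crosses per funnel — e.g. one
  balanced funnel set with replicates (1, 9, 15) gives 28, 14, 63 crosses
  and 63 × 15 = 945 RILs.
* **Selfing.** `selfing[g]` chained single-seed-descent rows follow every
  seed of generation g; the terminal of the chain is what gets crossed next
  (or becomes the RIL).

The optional additional crossing generation randomly intercrosses the
progeny of the final funnel crosses.  The number of extra crosses is
`round(n_ril / final replicates)`; pairs are drawn as distinct parent pairs
through shuffled pairing rounds (balancing how often each individual is
used), avoiding pairs of seeds from the same cross.  There is no canonical
pairing rule for this generation; ours keeps per-individual usage balanced
and yields, for the basic-plus-extra-cross benchmark design, the cross
counts 4, 2, 4, 64 and a 960-RIL population.
Pedigrees read and write as plain TSV/CSV and any externally supplied
pedigree that lists all crosses from founders to RILs can be simulated
directly.

## Meiosis model

Founder genomes are tracked as segment lists in cM (0-based, half-open),
which is exact — equivalent to fully informative markers at every position.
Per chromosome of length L cM, a gamete receives a Poisson(L/100) number of
crossovers placed independently and uniformly, with a fair-coin starting
homolog that alternates at each crossover: no interference and no obligate
chiasma, the process implied by the Haldane map function.  We chose this
model because the surrounding analysis pipeline (founder-probability
calling with Haldane distances) assumes it and because no interference
model is stated for the populations being emulated; the tests check the
implied closed forms (two-locus recombinant fractions, exponential
inter-crossover spacings, the Haldane–Waddington limit of ~2 junctions per
Morgan in selfed biparental RILs).  Founders are fully inbred; heterozygous
founders are out of scope.  One master seed drives everything;
per-iteration substream seeds are derived from it, so iterations can be
computed in any order (or concurrently) with results identical to serial
execution.

## Metrics

All metrics are evaluated on evenly spaced markers (`marker_spacing`, cM)
and a recombinant-haplotype interval `d` (cM, an exact multiple of the
spacing — anything else errors rather than rounding silently):

* **Total recombinant-haplotype proportion** — the fraction of consecutive
  d-spaced marker pairs whose founder labels differ, averaged over both
  homologs, all RILs and all chromosomes.  Residual heterozygosity after
  finite selfing is handled by averaging the homologs, which is unbiased
  for proportions.
* **Unique recombinant haplotypes** — with n founders there are n²−n
  ordered flanking pairs (56 for eight).  We count the distinct ordered
  pairs observed *within each evaluation interval* across the population
  and average over intervals.  This per-locus definition is the
  discriminating one: at realistic population sizes every pair occurs
  *somewhere* in the genome under any design, but a single-funnel design
  feeds each locus from a handful of ancestors (16 eight-way individuals
  give at most 32 ordered pairs at a locus), which is exactly the
  deficiency the statistic should expose.  The population-wide count is
  also reported (`pairs_observed`).
* **Per-pair mean counts** — mean events per RIL for each ordered pair;
  in a basic design the eight two-way pairs run about twice as frequent as
  the rest, the known signature of that design.
* **Founder proportions** — exact genome-length-weighted fractions from the
  segment representation (not marker-binned); their founder-mean is exactly
  1/n.
* **Founder tracts** — distinct founders per RIL chromosome, homologs
  unioned.
* **Segment lengths** — mean maximal single-founder segment per RIL
  chromosome.
* **Unique/identical binning and PRHR** — events of the same ordered pair
  falling in the same nonoverlapping bin (anchored at position 0; width
  typically 1 or 10 cM) are *identical*, otherwise unique; the proportion
  of recombinant haplotypes recovered (PRHR) is observed count / true
  count.  Both also apply to imported founder-call matrices
  (`read_founder_calls()` / `calls_to_events()`).

## The demonstration study

The packaged comparison (used by the acceptance script and the test suite)
uses a five-design benchmark on a fictitious genome of five
chromosomes of 1.0, 1.5, 2.0, 2.5 and 3.0 Morgans, markers every 5 cM,
d = 5 cM, 100 iterations per design, populations of ~945–960 RILs: the full
design (replicates 1, 1, 3; selfing 0, 0, 4), one balanced funnel set
(1, 9, 15; 0, 0, 4) and the basic design with an additional crossing
generation (1, 4, 4, 15; 0, 0, 0, 4; 960 RILs).  These problem sizes run in
a few minutes on one CPU; they are the package defaults for the worked
examples, with every design sized to a comparable RIL total (~1000 lines
per design) so that the comparison is fair.  What these simulations emulate — and what they
do not — should be kept in mind: evenly spaced markers, a uniform
recombination rate along each chromosome (no hot or cold spots), fully
informative founder labels (no genotyping error or missingness, no
founder-similarity masking), and no selection or phenotypes.  Passing tests
therefore validate the design comparison machinery, not the error properties
of any empirical founder-calling pipeline.

## Numerical and design choices

* Coordinates are cM, 0-based, half-open; a marker sitting exactly on a
  breakpoint takes the right-hand segment; a marker at the chromosome end
  takes the last segment.
* Canonical funnel order breaks ties by the smaller minimum founder index;
  funnel sets are unordered collections of canonical funnels *without*
  quotienting by founder relabeling, which is how the exhaustive count of
  720 minimal eight-founder sets is defined.  (Under the stricter convention the answer is 1: all 720 sets
  are founder relabelings of a single combinatorial structure, whose
  symmetry group has order 40320/720 = 56.)
* The annealing search for balanced sets is seeded and geometric-cooled
  (default 40,000 iterations); it verifies feasibility by divisibility
  first and reports failure explicitly when exact balance is not reached.
* Degenerate inputs error early: non-permutation funnels, replicate or
  selfing schedules of the wrong length, founder counts outside 3–128,
  intervals that do not divide evenly, pedigree rows whose parents are
  undefined or out of order.
* `run_comparison()` validates every design before simulating any of them,
  and its aggregate table is recomputable from the persisted per-iteration
  CSV — there is no hidden state.

## Known limitations

* Balanced designs are limited to 16 or fewer founders, and for founder
  numbers without an exhaustive enumeration the annealing search may fail
  on feasible instances (it is exact-or-error, never silently unbalanced);
  16-founder balanced sets in particular can take many restarts.
* The recombination model has no interference; simulators that use a gamma
  (chi-square) interference model will show slightly different fine-scale
  statistics at the same map length.
* The additional-crossing pairing rule is our own (see above).
* Unstructured designs are supported only through user-supplied pedigrees.
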