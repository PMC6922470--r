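---
title: "Simulating miRNA-mRNA competition in a discrete molecule pool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating miRNA-mRNA competition in a discrete molecule pool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comics)
library(dplyr)
```

## The model

The package simulates the post-transcriptional tug-of-war between
microRNAs and mRNAs in a single cell under transcription arrest: no new
transcripts are made, and the only modelled route to transcript loss is
miRNA-mediated degradation. Both species are discrete molecule pools of
fixed size — by default 25,000 transcripts and 50,000 miRNAs, a 2:1
stoichiometry in line with molecule-per-cell estimates for cultured human
cell lines. Working with integer molecules rather than concentrations is
deliberate: competition effects (a strongly expressed target soaking up a
shared miRNA) and the stochasticity of lowly expressed genes both emerge
naturally from sampling discrete pools.

One iteration of the engine does the following:

1. Draw a miRNA family from the free pool, with probability proportional
   to its free molecule count.
2. Draw a target among that family's predicted target genes, with
   probability proportional to each gene's live (not yet degraded)
   molecule count, then a molecule uniformly within the gene. Occupied
   molecules remain eligible — a transcript can carry several miRNAs at
   once on different sites.
3. Bind with the pair's binding probability at a site chosen uniformly
   among the record's sites that do not fall within 50 nt of an already
   occupied site on that molecule. If no site is eligible, or the
   probability draw fails, the iteration ends and nothing is consumed.
4. A molecule's first successful binding starts its removal clock: the
   molecule is deleted `removal_delay` iterations later (default 1,000),
   and its bound miRNAs return to the free pool for further rounds of
   regulation.

Iterations are pseudo-time. An iteration is one loop pass whether or not
binding succeeds, and the removal delay is denominated in the same units;
there is no mapping to wall-clock hours beyond the empirical observation
that a standard run (100,000 iterations) produces decay of the same order
as a day-long transcription arrest.

Binding probabilities come from TargetScan-style cumulative weighted
context++ scores (CWCS, one score per gene-family pair, more negative =
stronger predicted repression) via

$$p = 1 - 2^{\mathrm{CWCS}},$$

so a score of 0 never binds and a score of -1 binds on half of the
encounters. The CWCS is cumulative over a gene's sites, which is why the
probability applies at the gene-family level; individual site positions
are used only for occupancy bookkeeping and the 50-nt exclusion rule.
Scores above 0 are invalid input and clamp to probability 0 with a
warning. Genes with no interaction record at all cannot lose molecules
and are excluded from the simulated pool (they are reported in the run's
exclusion log rather than silently carried along).

## Normalization and thresholds

Expression tables (FPKM for mRNA, TPM or counts for miRNA) are converted
to molecule counts by proportional scaling onto the fixed pool, using
largest-remainder rounding so the pool total is exact — pool conservation
is an engine invariant, so the rounding must be bit-exact, not
approximately right. Remainder ties break by identifier so the
apportionment is deterministic. Entities falling below `min_molecules`
(default 1) are dropped and the pool re-apportioned once over the
survivors. Mature miRNAs are collapsed to families before normalization,
and a family inherits the strongest (most negative) score among its
members in the interaction table.

Two separate thresholds are easy to conflate:

* the *simulation* set — every gene with at least one molecule and one
  interaction record takes part in the dynamics;
* the *reporting* set (`reported_genes()`) — retention summaries are
  restricted to genes holding at least 0.02% of the transcript pool
  (5 of 25,000 molecules), because percentage retention of a 2-molecule
  gene is mostly noise.

## Perturbation: overexpression at a fixed pool

In-silico overexpression multiplies one family's count by a factor and
renormalizes the whole distribution back to the fixed pool total, so a
baseline fraction $f_0$ becomes $F f_0 / (1 + (F-1) f_0)$. A family that
is undetected in the native cell is first floored at 0.01% of the pool
(5 of 50,000 molecules) and the floor is applied *before* the factor.
Factor 1 is the identity; factor 0.5 is a knockdown through the same
renormalization path. `run_screen()` runs one independent simulation per
family; each column's seed is derived from the master seed and the family
name (not its position), so a screen is reproducible column-by-column and
the column order is irrelevant.

## Cross-miRNA classification

From a screen's retention matrix (genes x overexpressed families, percent
at the final checkpoint), `classify_genes()` labels a gene *stable* when
retention exceeds 85% in at least 90% of the columns and *sensitive* when
retention falls below 50% in at least 90% of the columns. The retention
comparisons are strict (>85, <50) and the coverage comparison is
inclusive (>=90%), matching the definitions the thresholds come from.
Everything else is *other*. Raising the stable threshold can only shrink
the stable set; coverage 1 is the intersection over columns and coverage
near 0 approaches the union — both boundary behaviours are exercised in
the tests.

## What the synthetic generator emulates

`make_fixture()` builds a complete synthetic cell: family abundances
decay geometrically (ratio 0.75 over 20 families puts ~25% of the miRNA
pool on the top family, the dominance regime observed in real small-RNA
profiles), gene abundances are uniform, and background gene-family
records appear with density 0.1 carrying scores uniform on [-2, 0].
Planted structure mirrors the two phenotypes the classifier is meant to
find:

* *sensitive-like* genes carry strong records (score -6, binding
  probability ~0.98) for the four most abundant families — the real
  signature of sensitive genes, which are targetable by nearly every
  dominant miRNA;
* *stable-like* genes carry records only for two bottom-quartile
  families — MBS only for miRNAs that are hardly ever drawn;
* background genes are guaranteed a few records with abundant families,
  because a real "other" gene is almost always under the reach of at
  least some expressed miRNAs; without that guarantee a background gene
  with no meaningful regulator would be *correctly* called stable and
  dilute the planted contrast.

The validated-pair list emulates CLASH-style evidence: a random subset of
genes (default 10%, 40% in the wiring-control analyses) each contribute
their strongest-probability record. This matters for the randomization
control: a truth list made only of the globally strongest records sits on
high-degree rows and columns, and a degree-preserving null keeps exactly
that structure, so the control would stay "significant" for reasons that
have nothing to do with wiring.

What the fixtures do **not** emulate: real 3'-UTR coordinates, shared
sites between families, transcript isoforms, miRNA-independent decay, or
expression correlations between miRNAs and their targets. Passing the
planted-recovery tests therefore shows the pipeline recovers structure of
this designed kind, not that any particular real gene list is correct.

## Choice of the classification factor in reduced screens

The package's tests and acceptance analyses use fixtures with 20 families
rather than the ~250 of a genome-scale table. Overexpression shares
renormalize against the whole pool, so factor and family count interact:
x300 applied to a median family in a 250-family cell moves it to roughly
10-20% of the pool, while x300 applied to a median family among 20
(baseline share ~2%) hands it ~90% of the pool and erases the native
competition that the classification is about. The scaled-down analog of
"x300 in a large cell" is therefore a moderate factor: x9 applied to a
median fixture family yields a ~15% share. Reduced screens still sweep
the full factor ladder (x0.5 through x1000), and classification is read
from the x9 matrix.

## Numerical choices and degenerate inputs

* Largest-remainder ties break lexicographically by identifier;
  randomization and screens derive all randomness from explicit seeds, so
  every result is bit-reproducible.
* The removal clock is fixed by the *first* successful binding by default
  (`removal_clock = "first"`); the alternative reading, where later
  bindings restart the clock, is one configuration switch away.
* A failed attempt (probability miss or no eligible site) consumes no
  molecules and still counts as an iteration.
* Degree-preserving randomization uses checkerboard swaps (10x the record
  count by default) plus within-gene score shuffling: row score totals
  are preserved exactly, column totals only through the degree sequence.
  A matrix with no swappable quadruple is returned unchanged with a
  warning.
* Zero-probability matrices, empty profiles, pool mismatches and
  all-zero abundance vectors raise errors or return exact identities, as
  exercised in the test suite.
* An exact upper-tail hypergeometric probability of observing *at least*
  the actual overlap is 1 when the overlap is 0 — a zero overlap can
  never be evidence of enrichment.

## Problem sizes used by the tests

The test and acceptance analyses run on sizes chosen to make the
stochastic assertions sharp while keeping a full suite run comfortable on
a laptop: conservation and monotonicity on twenty fixtures of 120-500
genes at the full 50k/25k pools and 100k iterations; engine-vs-oracle
agreement on five random tiny systems (at most 3 genes, 2 families, a few
hundred molecules) with 200 replicate seeds on both routes, compared at
three combined standard errors; reduced screens of 20 families across the
seven-factor ladder at 20k iterations; and the wiring control over 20
seeds at 10k iterations. The brute-force oracle shares no code with the
engine — it re-implements the iteration rules over explicit per-molecule
lists in plain R, slow on purpose and readable in one sitting.

## Known limitations

The engine models degradation-mediated regulation only: no translational
repression, no transcript synthesis, no explicit AGO/RISC kinetics (the
protein is assumed non-limiting), no cooperative binding beyond site
competition on a molecule, and no miRNA decay. Retention is relative to
the simulation's own time axis; comparisons with experimental
time-courses should therefore be made through rank statistics
(`rank_correlation()`) rather than absolute retention at a matched time.
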