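---
title: "Gene-neighborhood analysis of CARF/WYL families: models and methods"
author: "casNeighbors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-neighborhood analysis of CARF/WYL families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

Many prokaryotic defense-associated protein families — the CARF
(CRISPR-associated Rossmann fold) ligand-binding domains and the WYL
sensor domains among them — are characterized less by their sequences
than by their *genomic context*: where their genes sit relative to
CRISPR-Cas loci, which families recur in their neighborhoods, and which
CRISPR-Cas system types they travel with.  `casNeighbors` implements
that comparative-genomics workflow as a reusable, testable pipeline:

1. parse genome annotations (GenBank flat files or NCBI PTT tables with
   protein FASTA) into ordered per-replicon gene tables;
2. discard incomplete protein records (partial, pseudo, or missing a
   translation);
3. extract the window of $k$ genes on either side of each query gene;
4. pool the neighbor proteins and cluster them by single linkage under
   joint length-coverage and score-density thresholds (the BLASTCLUST
   criterion);
5. annotate clusters from a supplied domain-hit table and count, per
   family, the query windows containing that family (the co-occurrence
   histogram), plus the reverse direction: how many of a family's own
   windows contain *cas* genes;
6. call *cas* loci, assign CRISPR-Cas types from signature genes, and
   tabulate per-family and per-genome type associations;
7. classify CARF architectures as effector-bearing vs regulatory, and
   reduce the collection to one representative genome per genus for
   genome-level statistics.

Every stage is exercised end-to-end on synthetic genome collections
with planted ground truth (see below), because the historical database
snapshot behind the original numbers cannot be reproduced at desk
scale.

# Alignment and scoring model

Pairwise similarity is optimal local alignment (Smith–Waterman) under
affine gaps: BLOSUM62, gap open 11, gap extend 1, so a gap of length
$L$ costs $11 + L$.  Raw scores are converted to bits with the
Karlin–Altschul transform

$$S' = \frac{\lambda S - \ln K}{\ln 2},
\qquad \lambda = 0.267,\; K = 0.041,$$

the standard parameters for gapped BLOSUM62/(11,1) scoring.  Both are
configurable through `scoringParams()`, and the matrix can be loaded
from an NCBI-format text file.

Two derived quantities drive clustering:

* **length coverage** — the aligned span on a sequence divided by its
  full length, computed for *each* sequence (span = last − first
  aligned residue + 1; internal gap columns do not shrink the span);
* **score density** ("score coverage") — bit score divided by the
  alignment length in columns, *including* gap columns.  That is the
  literal reading of "bit score divided by alignment length", and with
  substitution-only synthetic families the two readings coincide.

The alignment kernel is implemented in C++ (`src/align.cpp`): a
score-only Gotoh pass, and a full pass that propagates each cell's
alignment start and column count so spans come out without a traceback
matrix.  An exhaustive enumeration oracle over chains of aligned
columns (independent of the Gotoh recurrence) pins the scores down on
short sequences, and scores are cross-checked against
`Biostrings::pairwiseAlignment` on longer random pairs.

When no residue pair scores positively the alignment is empty: raw
score 0, zero-length spans, coverage 0 — such a pair is never linked.

# Clustering

Two proteins are **linked** when both coverages reach the
`lengthCoverage` threshold (default 0.8) *and* the score density
reaches `scoreDensity` (default 0.8 bits/column).  Clusters are the
connected components of the linked relation — single linkage, the
BLASTCLUST partition semantics — and each cluster's representative is
its longest member (ties: lexicographically smallest id).  The
partition is invariant under input order, and `dereplicate()` returns
one representative per cluster (the non-redundant-set construction).

Requiring coverage on **both** sequences is the stricter of the two
readings of a length-coverage filter; `symmetricCoverage = FALSE`
switches to the shorter-sequence-only reading for users who want
nested-domain matches to link.

Two necessary-condition shortcuts keep all-pairs clustering exact but
fast.  First, a pair is skipped outright when even a perfect alignment
could not satisfy both thresholds (the raw score needed grows linearly
in the longer sequence's length; the best achievable score is bounded
by 11 per column over the shorter).  Second, an **ungapped pre-screen**
computes the best ungapped segment score (a fully vectorizable
diagonal scan, several times faster than the gapped recurrence) and
classifies a pair as unlinked when that segment stays below
`ungappedScreen` (default 60).  The margin is wide on both sides: a
linked pair of $\geq 100$-residue proteins needs a gapped raw score
above $\approx 1.66 \cdot \max(\ell_a,\ell_b) - 12 \geq 150$, which for
near-gapless alignments implies an ungapped segment far above 60,
whereas the best segment between unrelated random proteins of a few
hundred residues concentrates around 25–35.  The screen only applies
to sequences of at least `screenMinLen` (100) residues, so
short-sequence comparisons — where low-scoring linked pairs are
possible — always take the exact path; tests verify that decisions are
identical with the screen on and off, and the transitive-closure
oracle comparison runs against the complete clustering stack.  Setting
`ungappedScreen = 0` disables it.  A configurable `maxPairs` cap makes
the quadratic cost explicit: exceeding it is an error, not a silent
truncation.

# Neighborhood windows and co-occurrence

A window is the genes with index in $[q-k, q+k]$ on the query's
replicon, truncated at linear ends, wrapped without duplication on
circular replicons, never spanning replicons.  The default $k = 10$ is
the upper end of the 5–10 range conventionally used for initial
screening; because the published analyses leave the final value
per-analysis, every report echoes the $k$ used.  Pseudo genes count as
window positions by default (`includePseudoPositions`), though their
proteins never enter the clustering pool.

The pooled set is the union of window members with all query proteins
excluded — a query should not count as its own neighbor, and a CARF
gene fused near another CARF's window would otherwise self-count.
Co-occurrence is **window-level presence**: for each family label, the
number of query windows containing at least one member of a cluster
with that label, not a per-gene tally.  Reverse *cas*-linkage counts,
for the windows around one family's genes, how many contain at least
one gene annotated with any *cas* family (query excluded), reported in
the `total (linked)` convention.

Cluster labels come from the supplied domain-hit table (e-value
$\leq 0.01$ by default): majority family among member hits, ties to
the family holding the best e-value, `"unknown"` without hits.

# CRISPR-Cas loci and typing

Locus calling is deliberately simple, since locus boundaries are never
formally defined in this literature: maximal runs of *cas*-family
genes, merged across at most `locusMaxGap` (default 2) intervening
non-*cas* genes.  Typing uses signature families, externalized in a
two-column table so alternative schemes drop in: cas3 ⇒ type I, cas9 ⇒
type II, cas10 ⇒ type III with csm2/cmr5 resolving III-A/III-B and
plain cas10 left III-unspecified; conflicting signatures report all
matching types and flag the locus composite; no signature ⇒ unknown.
cas1/cas2/cas4 are adaptation-module genes — they anchor loci but
carry no type signal.

"Vicinity of *cas* genes" is operationalized uniformly as
window-overlap: a query gene is `near_cas` when its $k$-window
overlaps a called locus span, and it is attributed to the type of the
*nearest* overlapping locus (gene-index distance; ties count toward
all tied loci, composites toward each of their types).  Genome-level
summaries partition genomes into type III co-occurring with I/II, III
sole, I only, II only, I and II, or none, cross-tabulated with whether
the genome carries an effector-bearing query protein; the presence
summary counts genomes with the query family and, among them, genomes
possessing neither cas1 nor cas10, the two signature protein families
whose joint absence indicates no CRISPR-Cas system at all.

# Domain architectures

Raw hits for a protein are resolved greedily by ascending e-value
(ties: higher score, then smaller start); a hit survives if it
overlaps every kept hit by at most 30% of the shorter interval — a
standard tolerant-greedy rule standing in for manual curation, with
both the cutoff and the tolerance configurable.  A protein is
`effector_bearing` when an effector-family domain (HEPN, PIN, RelE,
REase, HD, Ada, HNH, Csx15 by default) lies strictly downstream of a
CARF interval — the C-terminal fusion geometry — and
`regulatory_only` when CARF is present without one.  Degraded domain
remnants count only if the hit table labels them; the classifier never
infers a family that the input does not assert.  The seven-residue
linear signature `[DN]X[ST]XXX[RK]` associated with the CARF
ligand-binding pocket is scanned positionally with overlapping matches
reported.

# Representative genomes

One genome per genus: the largest total genome size wins, with ties
broken by lexicographically smallest genome id (the sources are silent
on ties; determinism matters more than the choice).  Named overrides
pin model organisms — by convention *Bacillus subtilis* 168 and
*E. coli* K12 MG1655 for their genera — and an override naming an
absent genome is an error rather than a fallback.  Each genome record
is treated independently; multi-strain species are not collapsed.

# The synthetic-genome generator

`generateCollection()` emulates the shape of a multi-genome survey
while keeping every downstream quantity exactly checkable:

* **genus structure** — `nGenera` genera with 1–3 genomes each;
* **background genes** — unique uniform-random proteins of 100–400
  residues (the realistic bacterial length range), so planted-cluster
  recovery is exact: backgrounds can only be singletons;
* **families** — each planted family grows from an independent random
  seed sequence; members substitute
  $\mathrm{round}((1-p)\,L)$ uniformly chosen positions (replacement
  uniform over the other 19 residues), giving identity to seed exactly
  $p$ (default 0.75) and expected pairwise member identity
  $\approx p^2 + (1-p^2)/19 \approx 0.58$ — comfortably above the
  linkage threshold while inter-family identity stays at the ~5–10%
  background.  Substitution-only evolution (an indel rate is available
  for stress tests, default 0) keeps coverage and density predictable;
* **CRISPR-Cas loci** — instantiated contiguously from type templates
  (I, II, III-A, III-B), placed at least $2k+2$ gene slots apart so no
  window can straddle two loci and gap-merging never joins independent
  plantings — which is what makes 100% typing recovery the correct
  expectation rather than an approximation;
* **associations** — one CARF gene per genome, within a locus window
  with probability `carfNearCasProb` (0.75 by default: the strong but
  not total linkage typical of these families), and one WYL gene
  within the CARF window with probability `wylNearCarfProb` (0.8, the
  dominant-associate regime).  These are Bernoulli draws recorded per
  event, so binomial checks apply; counts that must match exactly —
  partial-flagged genes and cas-free genomes — are planted as
  deterministic `round(p·n)` counts instead;
* **completeness flags** — partial (5%) and pseudo (2%) flags land on
  background genes only, so planted-family counts survive the
  completeness filter untouched while the filter itself is still
  exactly testable.

The generator writes GenBank and PTT+FASTA side by side (the PTT
dialect adds optional `Partial`/`Pseudo` columns, which the canonical
format cannot carry), a hit table for every planted protein, a taxa
table, and ground-truth TSVs; with a fixed seed the whole file tree is
byte-identical across runs.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: indel-rich divergence, paralogs
and promiscuous domain sharing among backgrounds, operonic strand
structure, composite or degraded loci, horizontal transfer, and
annotation noise in the hit tables.  The validation demonstrates that
the machinery is correct under controlled conditions, not that the
biological conclusions of any particular survey re-derive.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (the PTT convention);
  gene indices are 0-based ranks in start order.  Origin-spanning
  genes on circular replicons (end < start) are legal and flagged, not
  errors.
* Protein alphabet is the 20 standard residues plus X; anything else
  is an error, catching format drift early.
* Alignment tie-breaks prefer diagonal over gap moves and the first
  maximal cell in row-major order; cluster ids are assigned in
  representative-id order, making every output deterministic.
* Empty inputs degrade gracefully: an empty query family yields a
  successful run with empty tables; a protein with no hits is
  `unknown`; an empty locus table means nothing is `near_cas`.

# Validation problem sizes

The shipped validation (tests and `scripts/acceptance.R`) runs at:
50 random instances of ≤ 25 sequences against a transitive-closure
oracle; 10 planted families × 20 members (identity 0.75, length 200)
for dereplication and ARI; 200 random short pairs against exhaustive
alignment enumeration; 200 single-genome genera (window $k = 5$, the
screening end of the 5–10 range) for association recovery; 40-genome
fixtures for typing, partition and presence checks.  These sizes
exercise every code path at full fidelity while a complete run stays
in the minutes range on one core.

# Known limitations

Quadratic all-pairs clustering is intended for neighborhood pools and
non-redundant-set construction at desk scale, not for clustering
hundreds of thousands of proteins.  Locus typing resolves only
{I, II, III-A, III-B}; repeat-array detection and finer subtyping are
out of scope, as are running the profile searches that produce the
domain-hit tables this package consumes.
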