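---
title: "Gene-family phylogenetics and amyloidogenic-potential profiling with amyphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family phylogenetics and amyloidogenic-potential profiling with amyphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyphylo)
```

## The problem

The amyloid-beta precursor protein (APP) family is an ancient metazoan gene
family: vertebrates carry up to three homologues (APP, APLP1, APLP2),
invertebrates one (APL-1 / APPL-1).  Only vertebrate APP contains the
beta-A4 region whose proteolytic fragment, amyloid-beta, forms the fibrillar
deposits of Alzheimer disease.  Two questions drive the analyses this
package supports:

1. **Where is the family conserved, and where does it change?**  Answered by
   calling *unambiguous synapomorphies* -- derived residues shared by the
   members of a clade -- at every node of a maximum-parsimony tree and
   profiling their frequency per alignment column, per conserved domain
   (NTS, E1, E2, E3, beta-A4) and per major branch of the family.
2. **When did the amyloid-forming property arise?**  Answered by scoring the
   beta-A4-homologous region of every taxon with a beta-pairing energy model
   and a consensus aggregation predictor, classifying each taxon
   high / low / none, and projecting the classes onto the tree.

The package implements every stage as a tested, reusable function:
homolog collection by similarity closure, parsimony machinery, frequency
profiling, aggregation modelling, and a synthetic-data generator that makes
the whole pipeline verifiable against planted truth without any downloads.

## Parsimony machinery

**Scoring.**  Characters are unordered amino-acid states.  Binary nodes use
Fitch set intersection/union; polytomies use Hartigan's count-based
generalization (cost $k - m$ at a node with $k$ children whose state sets
contain the most frequent state $m$ times), which is exact for unordered
characters on multifurcating trees.  Gaps, `X` and `?` are *missing data*:
they can take any state and never force a change.  Treating gaps as a 21st
state was rejected because indel placement is an alignment artefact at the
divergences involved, and common practice profiles substitutions only.

**Unambiguous synapomorphies.**  A (node, column) pair qualifies iff *every*
most-parsimonious reconstruction (MPR) of that column places a state change
on the branch entering that node *and* the derived state is identical across
all MPRs.  Synapomorphy lists in this field traditionally come from TNT,
whose exact operational definition (its relation to ACCTRAN/DELTRAN) is not
published in reimplementable detail; the all-MPRs definition above is
adopted and documented, and is not silently changeable.  One entry is recorded per
(node, column).  Implementation: per column, a unit-cost Sankoff inside
(`down`) and outside (`up`) dynamic programme gives, exactly and without
enumeration, (a) whether some MPR leaves the branch unchanged and (b) the
set of states the node takes across MPRs.  `enumerate_mprs()` provides the
explicit enumeration (guarded to 20 tips) and the test-suite cross-checks
both paths against brute-force labeling enumeration.  Autapomorphies (tip
branches) are excluded from the node table, since the domain profiles
describe clade-defining change.  The ancestral state is reported as the
parent's MPR state; if the parent is ambiguous the alphabetically smallest
optimal parent state is recorded (tie-break; the derived state can never be
among them, so `ancestral != derived` always holds).

**Search.**  The published trees came from TNT's `xmult`/tree-drifting and
symmetric resampling; none of that machinery is specified reimplementably,
so the package substitutes the standard combination of multi-start random
stepwise addition plus SPR hill-climbing, retaining all distinct topologies
at the best score, with ordinary nonparametric column bootstrap for
supports.  Support values are therefore comparable in *kind*, not in
number, to the published ones.  Consensus trees use strict or majority rule
(`cutoff = 0.5` keeps clades in more than half of the trees).  Rooting is by
user-designated outgroup: the true outgroup in simulations, the
earliest-diverging (cnidarian-analogue) lineage in a real analysis.

## Synapomorphy profiling

Column percentages are $100 \cdot c_j / \sum_j c_j$; histograms are binned
over half-open 5-column windows anchored at column 0 (final partial bin
allowed), and bin values are sums of member-column percentages, so mass is
conserved exactly.  Domain membership is by alignment column through the
reference-sequence projection of the domain map; the beta-A4/E3 overlap is
kept explicitly and a column counts once per domain containing it, so the
two rows are reported independently.  Columns outside every domain fall in
an implicit `inter-domain` row so totals reconcile.

Two denominator conventions coexist in the published tables and are both
implemented, selected by `scope`:

* `whole` -- every value is a percentage of *all* synapomorphies on the
  tree (branch columns therefore sum, over a full partition, to 100);
* `branch` -- values are percentages of the synapomorphies *within* each
  branch.

The captions of the original tables do not state their denominators; the
convention above was inferred from worked numbers in the text (the same
region contributing 1.7% "to that branch" and 0.3% "for the whole tree")
and is recorded here rather than guessed silently per table.

## Aggregation modelling

**Pairing energy.**  A *pairing* is two equal-length, ungapped,
non-overlapping windows of one chain (length at least `min_strand_len`,
default 4) laid against each other in parallel or antiparallel orientation;
its energy is the sum of tabulated residue-pair energies over paired
positions.  Each residue's profile value is the minimum energy over all
pairings covering it; residues no admissible pairing covers carry `NA`.
Windows must be disjoint because two strands of one chain cannot share
residues -- this also gives the documented invariant that sequences shorter
than `2 * min_strand_len` have an all-sentinel profile.  Profile values are
pairing-total energies (not per-residue averages); the published plots are
compatible with either convention and the total-energy reading is adopted
and flagged as an interpretation.

**Thresholds** follow the published convention: energy $< -4$ marks ordered
beta-fibril formers, $-4$ to $-3$ marginal, and a sequence is considered
non-amyloidogenic once its best pairing rises above $-2$ (the stopping rule
of the C-terminal truncation scan, `truncation_scan()`).

**The packaged energy table is a synthetic surrogate.**  The original PASTA
pairing tables are not redistributable here, so
`pairing_energy_table()` builds $E(a,b) = \gamma - \alpha\,p(a)\,p(b)$ from
the Chou-Fasman beta-sheet propensity scale $p$ normalized by its maximum,
with a mild multiplicative penalty (0.9) on the stabilizing term of parallel
pairings.  The constants $\alpha = 2.2$, $\gamma = 0.44$ are fixed once by
two calibration anchors: the human Abeta42 C-terminal window
(`GAIIGLMVGGVVIA`) must score below $-4$ and a poly-serine 20-mer must stay
above $-2$ ($\gamma = 0.2\alpha$ keeps the serine-serine pair weakly
destabilizing, making the second anchor robust to sequence length).  The
table's provenance field says `synthetic-surrogate`; numeric energies are
*not* PASTA values, only the threshold semantics carry over.  Users with a
licensed table can load it with `read_energy_table()`.

**Consensus predictor.**  The published consensus tool combines five
proprietary component methods under an agreement-of-2 rule.  The five
components are replaced by three documented window scorers -- Kyte-Doolittle
hydropathy (window 5, mean >= 1.6, the classic membrane-interaction cutoff),
Chou-Fasman beta propensity (window 5, mean >= 1.05, net beta-former), and
an amyloid-prone hexapeptide stretch scorer -- keeping the k-of-n rule
itself (`k = 2` of 3 by default).  Predictions are antitone in `k` and in
every scorer threshold, and the test suite asserts this.

**Segments and the two-region rule.**  Maximal runs with energy $< -4$ and
consensus become `high` segments, runs in $[-4, -3]$ with consensus `low`;
runs shorter than `min_run = 3` are dropped (suppresses single-residue
threshold noise).  A stable amyloid beta-fold needs two separate
aggregation-prone regions, so a taxon is `high`/`low` only when *both* its
N-terminal and C-terminal beta-A4 windows contain a qualifying segment (the
class is the best N-terminal segment's class), and `none` otherwise -- a
lone C-terminal transmembrane-like segment never suffices.

**Region extraction.**  Per taxon, beta-A4 boundaries come from (1) its own
cleavage annotation, else (2) the nearest annotated taxon on the tree
(patristic distance; unit branch lengths when the tree has none), else
(3) projection of the reference (human Abeta42) columns, with provenance
recorded.  The region splits into N- and C-terminal windows at the
alpha-secretase-site column.  The nearest-annotated-neighbor rule is a
reconstruction of the original "boundaries chosen based on similar
species", not its exact choices.

## Homolog collection

The classic harvest strategy for a gene family runs stringent (effectively
zero E-value) BLAST searches iteratively until no new sequence appears.
Live database queries are out of scope; `iterative_closure()` computes the same least fixed point
over a local `seq_database()` behind a pluggable backend.  The built-in
backend is exact Smith-Waterman (Biostrings) with Karlin-Altschul E-values
$E = K m n e^{-\lambda S}$; a literal floating zero is
representation-dependent, so stringency is expressed as $E \le \varepsilon$
(default $10^{-180}$).  A subject joins when *any* current member's hit
passes -- union semantics reproduce the fixed point regardless of seed
order, and the closure is idempotent and monotone in both seeds and
threshold (asserted in tests).  Deduplication keeps the single longest
record per (taxon, gene label) -- the human AbetaPP770-over-695/751 rule --
with ties broken to the smallest id; records labelled `other` group by
taxon alone with a warning.  The original "Unknown"/"synthetic construct"
organism filter is metadata-dependent and is left to a user-supplied taxon
blacklist rather than guessed.

## The synthetic world

`evolve_family()` evolves sites independently down a tree under a
uniform-exchange 20-state model: along a branch of length $t$ a site with
rate multiplier $r$ substitutes with probability $1 - e^{-rt}$, uniformly
to one of the other 19 states.  This is deliberately the simplest
reproducible model: the downstream analyses consume character matrices, not
model parameters.  Chosen defaults, fixed once:

* mean root-to-tip path 0.2 expected substitutions per unit-rate site --
  the low-homoplasy regime (<= 0.3) where parsimony is consistent;
* the example family (`example_family_config()`) grafts five simulated
  clade subtrees onto a ladder backbone with an outgroup tip, guaranteeing
  five disjoint monophyletic "major branches" (random Yule trees often lack
  them, and their occasional near-zero internal edges make topologies
  genuinely unidentifiable -- a property of the data, not the search);
* domain-rate analogues NTS 1.5, E1 1.0, E2 5.0, E3 0.2, beta-A4 0.3,
  mirroring the fast-E2 / slow-E3 contrast of the real family;
* planted clade-diagnostic substitutions are applied on the clade's stem
  branch and their columns frozen elsewhere, so the truth stays assertable;
* planted amyloid motifs are sampled heavy in I/V/F/L/A (weights
  0.3/0.3/0.2/0.15/0.05) over a polar background (S,G,N,D,E,K,P,R), the
  contrast the classifier is meant to detect; one motif is shared by all
  tips of a planted clade, as a clade-wide trait would be.

A green test on this world establishes that the machinery recovers planted
truth under low homoplasy and clean region boundaries; it does not
establish robustness to alignment error, heterotachy, indel-rich regions or
database incompleteness, none of which the generator emulates.

## Numerical and interface conventions

Coordinates are 0-based half-open internally and 1-based inclusive in every
file written for humans (TSV reports, FASTA/Newick stay standard).  Gaps
are `-` (`.` normalized on read); `*` stop codons are stripped; FASTA
headers use the `id|taxon|gene_label` dialect because the real records
carry this metadata in database fields.  Newick annotations
(`[&support=..]`, `[&class=..]`) ride as comment tags and round-trip
losslessly.  The center-star fallback aligner exists so toy runs need no
external tool; it is explicitly not for production -- configure
`align_adapter(records, external_cmd = "mafft --auto")` or supply an
alignment.

## Known limitations

* Bayesian inference, Bremer/decay supports and TNT's specific heuristics
  are out of scope; bootstrap percentages are not comparable in number to
  symmetric-resampling supports.
* The surrogate energy table preserves threshold semantics, not published
  PASTA energies; per-species PASTA energies reported elsewhere are not
  reproducible with it, and a full-family analysis additionally depends on
  a GenBank harvest whose content is database-version dependent.
* The per-taxon classification depends on the alpha-site column; where no
  cleavage annotation exists anywhere, region extraction refuses rather
  than guessing.
* `enumerate_mprs()` is exponential in the worst case and guarded; the
  synapomorphy caller itself is polynomial and handles full-size columns.
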