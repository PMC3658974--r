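---
title: "Classifying type-3 copper proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying type-3 copper proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuproclass)
```

# The problem

Type-3 copper proteins (tyrosinases, tyrosinase-related proteins,
catechol oxidases, hemocyanins) share a binuclear active site: two
copper atoms, Cu(A) and Cu(B), each held by three conserved histidines.
Sequence surveys of this family face three recurring tasks: finding the
paired histidine triads in unannotated proteins, separating the family
into its architectural subclasses, and reading the resulting
per-species repertoires as a history of gene duplication and loss.
`cuproclass` implements that pipeline end to end with deterministic,
testable components.

# Motif grammar

The scanner treats each copper site as a spacing grammar over histidine
positions.  Cu(A) follows `H1(n)-H2(8)-H3` and Cu(B) follows
`H1(3)-H2(n)-H3`, where a parenthesised number counts residues
*strictly between* two histidines (the PROSITE convention; a spacing of
8 means an index difference of 9).  Defaults in `scan_params()`:

* variable spacings `n` are accepted in 2–40.  The family's own
  variation does not constrain these bounds tightly; 40 is generous
  enough to keep the scan exhaustive without admitting cross-domain
  artefacts.
* the cytosolic subclass displaces the second Cu(A) histidine; this is
  modelled as a Cu(A) H2–H3 spacing of 6–12 other than the canonical 8
  (`shifted_h2`).
* the gap between the Cu(A) H3 and the Cu(B) H1 must be 10–400
  residues: the two sites belong to one globular domain, so both very
  short and very long separations indicate spurious pairings.
* conserved diagnostics: Phe at offset −4 from H3 in both sites, Asp at
  offset +4 from the Cu(B) H3.  "Four residues away" is read as index
  offset 4, not four intervening residues; the offsets are
  configurable because the opposite reading is defensible.

Candidate pairs are scored `2 − shifted_h2 + phe_A + phe_B + asp_B`,
an integer in 0–5, and ties are broken by the leftmost Cu(A) H1, then
the leftmost Cu(B) H1.  Scoring favours canonical spacing and intact
diagnostics; it is deliberately coarse — the score ranks alternative
pairings inside one protein and is not a cross-protein quality measure.
Unknown residues (X) never satisfy any motif or diagnostic probe.

Two further active-site features are read off as sequence-level
proxies.  A Cys within ±2 of the Cu(A) H2 marks a candidate Cys-His
thioether bond.  The disulfide-bridge candidate count is
`floor(c / 2)`, with `c` the number of Cys in the site ±20 residues
(bond Cys excluded).  Both are proxies: no 3D structure is modelled, so
a "bridge" is a Cys pair in the region, not an assigned bond.

The placeholder (gatekeeper) residue that roofs the Cu(A) substrate
pocket is located structurally in the folded protein, not by a fixed
sequence index.  The package uses a configurable anchor convention —
default: six residues upstream of the Cu(B) H1
(`placeholder_convention("cuB_h1", -6)`) — and the synthetic generator
plants the residue at the same position, so the convention is
internally consistent while remaining an explicit stand-in for a
structural assignment.

# Architecture heuristics

Dedicated signal-peptide and transmembrane predictors are
server-bound; the package instead uses transparent hydropathy
heuristics (`architecture_params()`), all on the Kyte-Doolittle scale
(X contributes 0):

* **signal peptide** — an 8-residue window with mean hydropathy ≥ 1.6
  starting at index ≤ 12 within the first 35 residues.  The reported
  span runs from the N-terminus to three residues past the core window;
  only presence/absence feeds classification, so no cleavage-site
  model is attempted.
* **transmembrane segment** — runs of positions with 19-window mean
  hydropathy ≥ 1.6, at least 19 long after merging runs separated by
  fewer than 5 positions, excluding the signal-peptide span.  The
  exclusion matters: a signal-peptide core is itself a hydrophobic
  stretch and would otherwise be double-reported.
* **Cys-rich region** — ≥ 6 Cys in a 30-residue window, overlapping
  windows merged.  No published density threshold exists for this
  family; 6/30 separates the planted regions cleanly from background.

# Subclass assignment

The subclass definition is architectural: secreted (α) = signal
peptide without a membrane segment; cytosolic (β) = no signal peptide;
membrane-bound (γ) = signal peptide plus a transmembrane segment.
Active-site evidence — shifted Cu(A) H2 and placeholder Phe (β-like),
placeholder Val and a Cys-rich region (γ-like) — adjusts an integer
confidence (count of concordant minus discordant items, floored at 1)
but never overrides the architecture.  Two reasons: the subclasses are
*defined* by architecture while the site features are diagnostic
correlates, and the heuristic Cys-rich detector is the least reliable
feature, so it must not be able to flip a call.  A protein with no
detected binuclear site is `unclassified` rather than forced into a
subclass.

Functional compatibility is a *set*, not a single call.  The packaged
feature table (placeholder residues, Cys-His bond, bridge count per
subclass × lineage group) does not always separate functions — e.g.
arthropod tyrosinases and arthropod hemocyanins share F/no-bond/2
bridges — and returning every consistent label is more honest than
inventing a tie-break.

# Phylogenetics

Full-length progressive alignment is unnecessary for this family's
conserved core: the six histidine anchors define a motif-anchored
alignment in which inter-anchor blocks are left-justified and
gap-padded to the block maximum.  This is deterministic, needs no
external aligner, and confines columns to the region where positional
homology is defensible.  Distances are p-distances (default) or
Poisson-corrected `-ln(1 - p)`, with pairwise deletion of gap/X columns
(complete deletion available); p = 1 under the Poisson model is an
error rather than an infinity.

Trees are built by the canonical neighbor-joining agglomeration on the
Q criterion, written by the package itself so its determinism is under
control: ties in Q are broken by the lexicographically smallest pair of
cluster representatives, and negative branch-length estimates are
clamped to zero with a message.  On additive matrices the
implementation reproduces path lengths to within 1e-9 and matches an
exhaustive OLS minimum-evolution search (tested at n ≤ 6).  Bootstrap
support resamples alignment columns with replacement and counts
bipartition recovery over replicates (percentage; seeded and exactly
reproducible).  Midpoint rooting delegates to `phangorn::midpoint()`
with a closed-form special case for two-tip trees.  Monophyly of a tip
set means some bipartition of the unrooted tree separates exactly that
set; singletons and the full set are monophyletic by convention.

# Genome context

Tandem clusters are found by single-linkage chaining of genes sorted
by start along each scaffold: consecutive same-subclass genes join one
cluster when the intergenic gap is ≤ 50 kb (inclusive), and singletons
are discarded.  Single linkage makes membership independent of input
order; 50 kb is a configurable default chosen to span the
kilobase-scale intergenic distances typical of tandem arrays while
excluding same-chromosome coincidences.  Strand is reported but
ignored for membership — tandem duplication produces both parallel and
inverted copies.  All coordinates are 0-based half-open internally;
GFF3 (1-based inclusive) and BED are converted at the I/O boundary
only, which keeps off-by-one errors out of the analysis code.

# Character evolution

Subclass history is reconstructed under a Dollo model: each subclass
arises exactly once — α at the root, β on the unikont stem, γ on the
metazoan stem (`default_origin_map()`) — and can only be lost.  The
minimal loss set explaining the absent tips is the set of maximal
all-absent subtrees inside the origin clade, computed bottom-up; an
exhaustive search over loss sets confirms minimality on small trees.
A species marked present *outside* its subclass's origin clade is a
data/hypothesis conflict and raises an error instead of being silently
accommodated: under a single-origin model such a pattern is
impossible, and hiding it would corrupt every downstream count.
Lineage-specific expansions are flagged at ≥ 4 genes per species and
subclass — the smallest repertoire the census treats as an expansion —
with the threshold configurable.

# The synthetic census

The generator is the constructive inverse of the classifier.  Each
subclass template carries its planted architecture (α: 20-residue
signal peptide; β: hydrophilic N-terminus; γ: signal peptide, Cys-rich
region, C-terminal transmembrane segment), the planted binuclear site
with subclass spacings (β with the shifted H2), the Phe/Phe/Asp
diagnostics, and a species-specific feature profile from the packaged
table.  Background design keeps the planted signal identifiable:
within the active-site region ±20, backgrounds exclude H, C, F and D
so the planted motif, diagnostics and Cys counts stay unique; elsewhere
the background is uniform over non-His residues with 2% His allowed,
so spurious-triad handling is still exercised.

All three active-region consensi descend from one ancestral draw: α
diverges ~15% from it (a shared α/γ stem plus its own branch), γ ~30%,
and β ~50% on top of its shifted geometry.  This yields three
well-separated clades whose cytosolic branch is the most divergent —
the family's own phylogenetic signature — without saturating β's
distances into noise.  Per-record variation is substitution noise
(default 5% per site) outside protected positions.  The protected set
covers every planted feature *plus* the positions where a noise
histidine could complete a triad tying the planted site's score and
stealing the leftmost tie-break; outside it, noise is free, which is
what the robustness sweeps (0–20%) exercise.

The packaged census spec pins the aggregate structure: 179 proteins in
35 metazoan and 17 non-metazoan species; the named expansions (18, 18,
12, 9, 6, 5, 5, 4 genes); exactly one species with all three
subclasses; four surveyed genomes with none.  Counts for unnamed
filler species are 1–3 and are editable artifact choices constrained
only by the totals.  The cluster plan lays the four tandem-expansion
species' genes out as clusters of sizes 2–7 (10 kb gaps) plus
singletons; the species tree encodes the survey's groups with named
internal nodes and polytomies where resolution is not needed.

What the generator does *not* emulate: insertions and deletions,
realistic amino-acid substitution matrices, compositional biases,
multi-domain proteins, split or mispredicted gene models, and the
third (copper-free) tyrosinase state.  Passing the round-trip tests
therefore demonstrates internal consistency of scanner, classifier and
generator under substitution noise — not performance on real,
indel-rich proteomes, where the anchored alignment and the fixed
placeholder convention are the components most likely to need care.

# Problem sizes and determinism

The shipped analyses are sized for a desk run: the census fixture holds
179 proteins of ~200–260 residues; phylogenetic property checks use
24-taxon panels with 100 bootstrap replicates; oracle comparisons use
exhaustive searches at n ≤ 6 taxa (minimum evolution, 105 topologies)
and ≤ 8 tips (Dollo).  Every stochastic step takes an explicit seed,
callers' RNG state is restored by the generator utilities, and a fixed
configuration plus seed reproduces every output byte for byte
(`run_subcommand("all", ...)` is tested for this).

# Known limitations

* Signal-peptide and transmembrane calls are hydropathy heuristics,
  tuned to be exact on the generator's templates; on real proteomes
  they will underperform dedicated predictors, and chloroplast transit
  peptides and GPI anchors are not modelled at all.
* The placeholder position is a sequence convention standing in for a
  structural assignment.
* NJ on anchored p-distances is a fast, deterministic tree method, not
  a substitute for model-based inference when alignments are long and
  rate heterogeneity matters.
* The Dollo model excludes re-gain by construction; true convergent
  origins (a real possibility for hemocyanin function) surface as
  consistency errors, which is intended but worth knowing.
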