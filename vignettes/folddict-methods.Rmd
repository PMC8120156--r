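---
title: "Dictionary compression of folding-pattern tableaux: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary compression of folding-pattern tableaux: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(folddict)
```

## The tableau representation

A tableau describes a protein folding pattern by (a) the order of helices
(`H`) and strands (`E`) along the chain, (b) which pairs of SSEs are in
physical contact, and (c) the relative orientation of each pair, as the
dihedral angle between the two least-squares SSE axes about their mutual
perpendicular. Axes are total-least-squares fits to the Cα coordinates of a
segment, oriented N→C; two SSEs are in contact when some heavy-atom pair
(one atom per residue, one residue per SSE) is closer than the sum of the
Bondi van der Waals radii plus a 1 Å slack. The representation is invariant
under rigid motions of the coordinates, and reversing a segment's chain
direction shifts its pairwise angles by 180° — both properties are enforced
by tests.

Degenerate geometry needs conventions: parallel axes get angle 0 (the
coplanar limit) and antiparallel axes 180, both flagged; exactly
intersecting axes keep a well-defined dihedral through the direction (not
the zero length) of the mutual perpendicular. Secondary-structure
assignment is pluggable: the `external_file` adapter accepts any
`chain type start end` table (e.g. from a dedicated assignment program),
while the built-in `ca_geometry` assigner uses Cα-only criteria (helix:
d(i, i+3) ∈ [4.7, 5.7] Å over ≥ 4 consecutive windows; strand: d(i, i+2) ∈
[6.0, 7.2] Å over ≥ 3; minimum lengths 4/3 residues; helices win overlaps).
It is deliberately an approximation that keeps the tool self-contained —
kinked helices and irregular strands will be segmented differently than a
dedicated assigner would.

## The two-part message

The best dictionary is the one minimizing
I(C & T) = I(C) + I(T | C) in bits, accepted only when shorter than the
null statement I_null(T). The codec is fully explicit, so the objective is
a real, decodable code length:

* **Integers** (SSE counts, concept counts) use the Elias gamma code,
  2⌊log₂ n⌋ + 1 bits for n ≥ 1.
* **Binary sequences** (the H/E string; the row-major upper-triangle
  contact cells) use the Krichevsky–Trofimov adaptive code: symbol
  probability (c + ½)/(t + 1) given c prior occurrences in t symbols.
* **Angles** are quantized to ε = 1° bins. Outside concept regions an angle
  costs log₂(360/ε) bits (uniform); inside a region, the deviation δ from
  the archetype angle costs −log₂(f(δ; κ) · ε_rad) bits under the von Mises
  density with the concept's κ, floored at 0 because density × bin width
  can exceed 1 at large κ.
* **κ** is coded by its index in a fixed public grid (0 plus 64
  geometrically spaced values in [0.1, 1000]), costing log₂ 65 bits. This
  is simpler and exactly decodable compared with optimal-precision
  parameter coding; the grid is part of `code_spec` and serialized with
  every dictionary.
* **Contact cells inside a concept region** are coded against the archetype
  by a Bernoulli flip model (p = 0.05): −log₂(1 − p) per matching cell,
  −log₂ p per extra contact. A region is valid only if its SSE string
  equals the archetype's and every archetype contact is present, so
  topological conservation is a hard gate and flips only add contacts.
* **Dictionary statement**: Elias gamma of |C| + 1, then each archetype
  under the null tableau code plus its κ index.

Only angles of *contacting* pairs are transmitted; non-contact angles are
derived data, recomputable from coordinates, which keeps the message
focused on the geometry of interactions.

One design decision makes the whole objective decomposable: the adaptive KT
models condition on **all** previously transmitted *or concept-implied*
symbols, in a fixed global order, rather than on the subsequence a
particular segmentation happens to route through them. Each SSE position
and each contact cell therefore has a null cost that is a constant of the
tableau, regions contribute additively, and the dynamic program below is
exact. The stream stays decodable because the decoder always knows every
earlier symbol, however it was coded.

`encode_tableau()`/`decode_tableau()` realize this code with a 32-bit
arithmetic coder. Conditional distributions are quantized to integer
frequencies summing to 2²⁰ identically on both sides, so losslessness is
unaffected and the emitted length stays within the coder's ~2-bit
termination overhead of the analytic total; the round trip recovers the SSE
string and contacts exactly and every coded angle to within ε/2.

## Optimal dissection by dynamic programming

A dissection tiles the n SSEs with consecutive regions: null regions of one
SSE, concept regions of the archetype's size. Each region start pays a
uniform label over the |C| + 1 options. With per-position null costs
constant (above), the Bellman recursion over region ends,

```
best[j] = min( best[j-1] + label + sse_cost[j],
               min over concepts c valid at [j-n_c+1, j] of
                   best[j-n_c] + label + match_cost(c) - base_cells(span) )
```

attains the global minimum exactly; `brute_force_dissect()` enumerates all
segmentations independently and the suite asserts bit-for-bit agreement on
hundreds of random instances. Ties are broken deterministically: fewer
regions, then the earlier concept id (null first). Cross-region cells are
always coded under the null model, which is what makes the objective
segmentation-independent outside regions. Concept usages must be strictly
consecutive in SSE order — allowing gapped matches would explode the search
space — and regions never overlap.

The recursion is implemented in C++ (Rcpp) because the annealing search
dissects the whole collection for every proposal; the exported R cost
functions (`match_cost()`, `null_tableau_len()`, ...) are the reference
implementation, and tests pin the two paths together, which doubles as a
dual-implementation oracle.

## Searching dictionary space

`anneal()` starts from the empty dictionary and explores with five
primitives, chosen uniformly among the applicable ones: add a random
connected subtableau from the collection; remove a concept; grow/shrink a
concept by one SSE with reference to its source tableau; step its κ on the
grid (±1 or ±2 indices); or swap a concept with one of the regions its
current dissections explain. Invalid draws (disconnected candidates,
no-ops) are redrawn up to 50 times before an Add is forced. Acceptance is
Metropolis in base 2 — message lengths are bits — with Δ the change in the
full two-part total, recomputed per proposal (no incremental shortcuts to
go wrong; a test checks the fast path against the plain accounting).

The schedule is geometric: t₀ = 1000 bits, α = 0.95, 200 proposals per
level, floor t_min = 0.1, early stop after 20 levels without an acceptance.
These values are the package's own choices — the cooling schedule, proposal
mixture and stopping rule are free parameters of any annealing search — set
once to comfortably reach equilibrium on desk-scale collections (tens of
tableaux, ≲ 10 SSEs each). The *best-seen* state is returned, then
subjected to the MML null test: if it does not beat I_null(T), the empty
dictionary is returned. Consequently a returned non-empty dictionary always
has positive compression gain.

## Meta-concepts and the concept hierarchy

To relate concepts, the archetype subtableaux themselves become the source
collection and the identical inference runs again (`infer_meta()`),
yielding meta-concepts. Each concept is then a count vector over
meta-concept usages in its archetype's dissection (a bag-of-words view),
pairwise similarities are cosines of these raw count vectors, and `upgma()`
agglomerates 1 − similarity with size-weighted averaging, heights d/2,
lowest-index tie-breaks. Conventions: two all-zero vectors score similarity
1 (concepts with no meta-structure are indistinguishable), a zero against a
non-zero scores 0; raw counts rather than normalized frequencies keep the
bag-of-words reading. The tree is ultrametric by construction and exported
as Newick via ape.

## The synthetic benchmark

`make_benchmark()` generates what the model assumes real collections look
like, with known ground truth: SSE counts uniform on [5, 10]; H/E types
i.i.d. with p = 0.5; contacts independent with probability 0.9 for
adjacent pairs and 0.15 for distant pairs (real tableaux are dominated by
near-diagonal contacts, and this keeps random subtableaux realistically
connectable); angles uniform, quantized to ε. The planted motif is a
four-SSE `EHHE` unit with a contact ring and packing-like angles, written
into half of 60 tableaux at a random position, its contact-pair angles
perturbed by von Mises noise at κ_true = 50 (circular sd ≈ 8°) via a
Best–Fisher sampler. These defaults are the reference study conditions used
by the tests and the acceptance script.

What passing these benchmarks shows — and does not show: recovery of a
planted motif under the generator's own assumptions demonstrates the
inference machinery (search, codec, null test) is sound, not that the
built-in SSE assigner or the contact model match any particular
experimental dataset; real collections are redundant, their angle noise is
not von Mises, and their contacts are correlated. Conversely, the
pure-noise rejection study shows the MML null test resists over-fitting
even though every candidate concept trivially explains its own source
region.

## Numerical choices and edge cases

* Angle wrap-around is always to (−180, 180]; bin b covers
  (−180 + (b−1)ε, −180 + bε] and decodes to its center.
* ε must divide 360; 1° is well below tableau comparison noise.
* The von Mises normalizer uses the exponentially scaled Bessel I₀ so
  κ = 1000 stays finite; κ = 0 reproduces the uniform code *exactly*.
* Empty tableaux are valid (1 bit: the gamma code of n + 1 = 1); empty
  dictionaries are valid inferences (gain −1 bit, the statement overhead).
* All-identical Cα points refuse an axis fit; collinear points are fine.
* Annealing, simulation and clustering are bitwise reproducible from their
  integer seeds; every `cmd_*` output carries a manifest with the tool
  version and effective configuration (the tableau text format's header is
  fixed, so manifests are sidecar files).
* Problem sizes in the tests and acceptance script (hundreds of random DP
  instances at n ≤ 8, 30 annealing runs on 50–60 tableaux) were chosen as
  the smallest scales at which every claimed property is exercised
  meaningfully.

## Known limitations

* The absolute bit totals depend on this package's codec conventions
  (Elias gamma, KT, gridded κ, the flip model); other codecs for the same
  model family would report different absolute numbers while ranking
  dictionaries similarly. Published figures from other implementations are
  therefore not comparable bit-for-bit.
* The built-in Cα-geometry SSE assigner is a convenience, not a substitute
  for a dedicated assignment program; use the external-file adapter for
  serious structural work.
* Dictionaries are flat; hierarchical (nested) dictionaries are out of
  scope — the meta-concept clustering is an exploratory device, not an
  inferred hierarchy.
* Single-chain tableaux only; no quaternary contacts, no β-sheet topology
  labels, no gapped concept usages.
* The annealer is single-threaded; collections of thousands of tableaux
  need more aggressive schedules or parallel dissection than provided
  here.
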