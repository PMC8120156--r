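# folddict

Unsupervised discovery of recurrent protein substructures by lossless
compression of folding-pattern *tableaux*.

## The problem

A protein's folding pattern can be summarized by a **tableau**: the string of
secondary structural elements (SSEs; helices `H`, strands `E`) in chain
order, a symmetric contact matrix over SSE pairs, and a symmetric matrix of
interaxial dihedral angles, where only angles of contacting pairs carry
structural information. Recurring sub-patterns of tableaux — helix hairpins,
β-α-β units, Greek keys, larger super-secondary assemblies — are the
vocabulary in which protein architecture is written. folddict infers such a
vocabulary from any collection of structures, with no supervision and no
fixed motif library, by treating the problem as model selection under the
**minimum message length** (MML) criterion:

- A **concept** is a subtableau over ≥ 2 *consecutive* SSEs whose contact
  graph is connected, together with a von Mises concentration κ that governs
  how tightly usage angles cluster around the archetype's
  (f(δ; κ) = e^{κ cos δ} / (2π I₀(κ))).
- A **dictionary** C is a set of concepts plus the implicit null concept
  `c_0000`. Its quality on a collection T is the length of the two-part
  message I(C & T) = I(C) + I(T | C): first state the dictionary, then every
  tableau *given* the dictionary, losslessly.
- Each tableau is stated through its optimal **dissection**: a partition of
  its SSEs into consecutive regions, each assigned to a concept or to null,
  found exactly by dynamic programming.
- A dictionary is accepted only if I(C & T) is *shorter* than the null
  encoding I_null(T) of the data alone; the compression gain
  I_null(T) − I(C & T) measures how much real structure was found. The
  search over dictionaries is simulated annealing over five perturbation
  primitives (add / remove / resize / re-weight / swap-with-usage).
- Concepts are then related hierarchically by rerunning the same inference
  on the concept archetypes themselves ("meta-concepts"), representing each
  concept as a bag-of-meta-concepts count vector, and clustering by cosine
  similarity with UPGMA.

Everything is backed by a working bit-level codec (Elias gamma integers,
Krichevsky–Trofimov adaptive codes, quantized von Mises angle codes, an
arithmetic coder), so "message length" is not a metaphor: every tableau can
actually be transmitted in the reported number of bits and recovered
exactly.

The package is for structural bioinformaticians who want to mine
substructural vocabularies from structure collections, and for
methods-minded readers who want an executable, testable MML pipeline:
coordinates → tableau → dictionary → dissection → concept hierarchy.

## Worked example

Generate the reference synthetic benchmark (60 tableaux of 5–10 SSEs; a
four-SSE `EHHE` motif planted in half of them with von Mises angle noise at
κ = 50), infer a dictionary, and score the recovery:

```r
library(folddict)
spec  <- code_spec()                      # 1° angle bins, 65-point kappa grid
bench <- make_benchmark(synth_params(seed = 7), spec)
C     <- anneal(bench$collection, anneal_params(seed = 7), spec)
C
#> dictionary of 1 concepts (+ implicit null c_0000)
#>   concept c_0001: [EHHE], kappa = 46.4 (from synth_047 3-6)
attr(C, "null_bits")   # 7197.952  bits to state the collection without a model
attr(C, "best_bits")   # 6836.645  bits for dictionary + dissected collection
attr(C, "gain")        # 361.3066  bits of lossless compression gained

recovery_score(C, bench$truth, collection = bench$collection)
#> $motif_recovered  TRUE
#> $best_concept     "c_0001"
#> $mean_abs_dev_deg 1        # archetype angles within 1° of the planted motif
#> $usage_overlap    1        # every planted span found by the dissections
```

The single inferred concept is the planted motif: the search recovered its
SSE string, contact topology, angles (to 1°) and a κ (46.4) close to the
generating concentration (50). Dissecting one planted tableau shows the
Fig-style markup at the SSE level:

```r
d <- dissect(bench$collection[[2]], C)
d
#> dissection of 'synth_002': 7 regions, 154.699 bits
#>   start end concept_id region_bits
#> 1     1   4     c_0001   24.471720
#> 2     5   5     c_0000    1.000000
#> ...
null_tableau_len(bench$collection[[2]], spec)$bits
#> 171.5253       # the dissection beats the null coding by ~17 bits
```

`encode_tableau()` / `decode_tableau()` turn any dissection into an actual
bit string and back; `infer_meta()`, `feature_vectors()`, `upgma()` and
`to_newick()` build the concept hierarchy; `cmd_tableau()` builds tableaux
from PDB/mmCIF coordinates (SSE assignment via a built-in Cα-geometry
assigner or any external segment table). A thin shell wrapper around the
`cmd_*` functions is installed at `inst/cli/folddict`.

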