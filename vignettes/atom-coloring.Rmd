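---
title: "Neighborhood-specific atom coloring and compound harmonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood-specific atom coloring and compound harmonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(molcolor)
library(dplyr)
```

## The problem

Atom-resolved metabolic networks need a name for every atom of every
compound that satisfies two rules: different atoms must have different
identifiers, and symmetric atoms — atoms in the same orbit of the molecular
graph's automorphism group — must share one. Atom indices in a molfile fail
the second rule; InChI-derived schemes fail on R-group entries and
over-specify charge and stereo detail that metabolic databases disagree on.
molcolor implements a neighborhood-specific graph coloring that satisfies
both rules, derives an ordered *compound* identifier from the atom
identifiers, and uses those identifiers at two levels of chemical
specificity to find corresponding compounds across two databases.

## The coloring procedure

Each atom starts from its **zero-layer string**: its own chemical
information, rendered in the fixed field order
`element | charge | atom stereo | isotope`, with disabled layers omitted.
Coloring then runs a breadth-first expansion per atom:

1. The atom's visited set starts as itself; its frontier is its directly
   bonded neighbors.
2. Each round, every frontier atom contributes the pair (connecting-bond
   token, its zero-layer string). The pairs are sorted lexicographically in
   the C locale and appended to the atom's identifier as one
   parenthesized layer. Sorting before concatenation is what makes the
   identifier canonical: no atom-input ordering can leak through.
3. The frontier advances to unvisited neighbors-of-frontier. A frontier
   atom's *connecting-bond descriptor* is the sorted concatenation of the
   tokens of every bond linking it to the already-visited set at the moment
   it enters the frontier, so atoms reachable through two bonds are
   distinguished from atoms reachable through one.

Every atom gets `min_rounds = 3` rounds before any uniqueness check; this
guards against early stopping that can leave two different compounds with
one compound identifier. After that, only atoms whose identifier is still
shared keep extending, until all identifiers are unique or every frontier
is exhausted. Symmetric atoms see identical shells at every distance, so
they necessarily finish with equal identifiers — ties between genuinely
symmetric atoms are never broken, by design.

Bond tokens are `1`, `2`, `3` and `a` (aromatic), with a `c`/`t` suffix
when bond stereochemistry is enabled. The aromatic token being distinct
from all Kekulé orders is what makes aromatic normalization (below)
meaningful.

### Validation and recoloring

Building layers from zero-layer strings keeps identifiers short, but in
rare topologies two *asymmetric* atoms can still collide: if two locally
symmetric branches meet at a shared junction, both atoms accumulate the
same layer strings. `validate_symmetry()` therefore re-expands BFS shells
simultaneously from every member of each identifier class and compares the
sorted multisets of (zero-layer, bond-descriptor) pairs layer by layer
until the whole graph is consumed; any mismatch flags the class as
pseudosymmetric. `recolor()` then reruns the extension for the flagged
atoms using each frontier atom's **full identifier** instead of its
zero-layer string — the richer token separates the conflated
neighborhoods — extending only until the members' strings diverge. The
repaired map is re-validated; the pipeline `color_molecule()` wires the
four steps together.

The `pseudosym_triring` fixture reproduces this failure mode on demand.
The full algorithm with `min_rounds = 3` already avoids the trap on that
molecule, so the repair path is exercised under a deliberately weakened
configuration (`max_rounds = 2`); `max_rounds` exists only for this
purpose and defaults to unlimited.

```{r pseudosym}
fx <- make_named_fixture("pseudosym_triring")
weak <- coloring_config("loose", min_rounds = 2, max_rounds = 2)
colors <- color_atoms(fx$graph, weak)
colors$full[["1"]] == colors$full[["6"]]       # the collision
report <- validate_symmetry(fx$graph, colors, weak)
length(report$invalid_groups)                  # flagged classes
repaired <- recolor(fx$graph, colors, report, weak)
identical(color_classes(repaired), symmetry_orbits(fx$graph))
```

### The oracle

`symmetry_orbits()` is an exact, independent check of the central
guarantee: it enumerates automorphisms of the colored graph by
backtracking (with iterated-refinement pruning) and returns their orbits.
It shares no code with the coloring path and is bounded at 30 colorable
atoms. The test suite demands exact agreement between final color classes
and oracle orbits on every named fixture and on 200 seeded random
molecules of 8–25 heavy atoms, under both presets.

## Tight and loose configurations

`coloring_config("tight")` includes every chemical layer (charge, atom
stereo parity, bond cis/trans, isotope); `"loose"` keeps only atom type
and bond type. Databases disagree on protonation state, drawn
stereochemistry and isotope annotation, so tight identifiers under-match
across databases while loose identifiers absorb exactly those
inconsistencies. Tight classes always refine loose classes, which gives
the matching strategy its order: match tight first (the stronger claim),
then loose; a pair found under both is reported once, as tight.

Hydrogens are excluded from coloring and neighborhood expansion by default
(`include_hydrogen = FALSE`) because the hydrogen count in a molfile is a
database convention, not chemistry: deleting explicit hydrogens never
changes heavy-atom identifiers.

## Compound identifiers

Atoms sharing a full identifier form a color class; each class renders as
`(count)[color]`, the rendered substrings are sorted lexicographically as
whole strings — counts participate in the ordering — and concatenated:

```{r identifier}
benzene <- aromatize(make_named_fixture("benzene_kekuleA")$graph)
identify_compound(benzene)$text
```

Square brackets inside a color string are backslash-escaped so
`parse_identifier()` is an exact inverse. Identifier equality is always
defined on the full string; `color_hash()` (32-bit FNV-1a) exists only for
display and indexing.

## Aromatic normalization

The coloring is deliberately sensitive to bond orders, so the same ring
drawn with alternating single/double bonds in two Kekulé placements would
color differently. Before coloring, molcolor rewrites every detected
aromatic system to bond order 4:

* **Reference matching** (`detect_by_reference()`): each fragment of a
  reference library is matched into the compound by subgraph isomorphism
  (igraph's VF2) respecting element symbols, with bond orders compared
  under the equivalence {single, double, aromatic} so Kekulé and aromatic
  drawings both hit. Two guards apply: a candidate image must contain at
  least one double or aromatic bond (a fully saturated ring such as
  cyclohexane must never match benzene), and overlapping matches are fused
  into maximal fragments, so fused ring systems normalize as one unit.
* **O/S heuristic** (`detect_heuristic()`): oxygen and sulfur lack
  aromatic atom-type annotations in common database schemes, so an O/S
  atom is aromatized when it sits on a smallest ring (size ≤ 8) whose
  every other member is an aromatic-labeled C or N. The ring-size cap is a
  documented choice; rings above 8 members are outside the heuristic's
  intent. A ring whose carbons carry no aromatic labels is never emitted,
  which keeps non-aromatic O-heterocycles (the `dioxin_flanked` fixture)
  untouched. Quinoid-type mislabeling in upstream annotations is a known
  hazard of any label-driven rule; as long as the same reference set is
  applied to both databases it does not affect harmonization.

The bundled library (benzene, pyridine, pyrrole, furan, thiophene,
imidazole, naphthalene) is a small stand-in adequate for tests and small
collections; production use expects a database-derived library directory.
Library entries deduplicate by loose compound identifier computed on an
aromatic-normalized copy, so Kekulé variants of one ring system enter
once. Hückel electron counting is intentionally not implemented:
aromaticity here comes from curated references plus the heuristic, because
purely rule-based perception mislabels quinoids and fused edge cases.

Fragment extraction keeps only bonds on cycles of the induced subgraph:
two rings joined by a rotatable single bond (biphenyl) are two fragments,
while edge-fused rings (naphthalene) are one.

## Double-bond stereochemistry

Acyclic C=C bonds get a `cis`/`trans` label from 2-D geometry, used only
when bond stereo is enabled (tight mode). On each end the reference
substituent is the non-hydrogen neighbor with the lowest element token
(ties by lowest index); the sign of the normalized cross product of the
substituent vector with the bond axis is compared across ends — equal
signs cis, opposite trans, and magnitudes below 1e-6 (collinear geometry)
yield no label. Ring-internal double bonds and terminal alkenes are never
labeled. The rule needs explicit hydrogens first
(`add_implicit_hydrogens()`) so substituent counts are complete, and
errors out on degenerate coordinates rather than guessing.

Implicit hydrogen counts use a default-valence table with
`effective valence = default + formal charge` (hydroxide gets one
hydrogen, ammonium four). Aromatic bonds contribute 1.5 to an atom's bond
order sum, floored after summation, which reproduces one hydrogen per
benzene carbon without Kekulé information. R-group tokens (`R`, `R#`,
`*`, `X`) and metals carry valence 0: they are colorable placeholders,
never expanded and never hydrogenated.

## Harmonization and EC validation

`harmonize_databases()` reads two database directories (per-compound
molfiles plus `reactions.tsv` and `crossrefs.tsv`), normalizes aromatics,
indexes both sides under both presets, and matches by identifier equality.
Within one identifier key the full Cartesian product of left and right
compounds is emitted: one-to-many matches are reported, never
auto-resolved, because disambiguation belongs to reaction-level evidence
downstream. Pairs are then classified two ways:

* `confirm_with_ids()` — the pair shares a (namespace, foreign id)
  cross-reference, or one side cites the other's native id directly.
* `validate_with_ec()` — both compounds participate in reactions and some
  EC number on the left agrees with one on the right on the first three
  levels (`ec3_verified`), or on all four when both are fully specified
  (`ec4_verified`). Wildcard ECs (`2.3.1.-`) participate at their
  specified depth, so a wildcard fourth level caps verification at three.
  Unparseable EC strings degrade to EC-less reactions with a warning.
  Pairs where either side joins no reaction land in `no_reactions`.

## The synthetic generators

`random_molecule()` grows a connected heavy-atom tree over C/N/O/S/P with
default valences respected, occasional double bonds, and ring closures
where spare valence allows — element frequencies are carbon-dominated as
in real metabolite sets. `make_database_pair()` plants a one-to-one
correspondence and then perturbs the right-hand copies with exactly the
representation noise the method is designed to absorb: alternative Kekulé
drawings, a shifted formal charge, atom reordering, dropped stereo
parity, plus unmatched extra compounds on both sides. Base compounds are
regenerated until their loose identifiers are pairwise distinct, so the
planted table is the unique correct harmonization result and precision
and recall of 1.0 are a property of the noise classes, not luck.

What the generators do **not** emulate: realistic metabolite size and
element distributions, tautomers and resonance forms, multi-fragment
salts, and annotation errors beyond the planted noise classes. Passing
tests therefore demonstrate the algorithmic guarantees — symmetry
consistency, representation invariance, decision logic — not robustness
to the full noise spectrum of real databases.

## Numerical and design choices

* Within-layer ordering, the class sort, and all string sorts use radix
  (C-locale) ordering — identifiers must not depend on the session locale.
* Layer delimiters: `( )` for coloring layers, `{ }` for recoloring
  layers, `:` between bond token and atom token, `,` between members. The
  grammar keeps concatenation injective.
* Coordinates are used only by the stereo rule; molfile serialization
  carries four decimals, and JSON round trips preserve full precision to
  1e-9.
* Multi-fragment entries are legal; coloring operates per connected
  component while the compound identifier covers the whole entry.
* V3000 molfiles are rejected explicitly; the parser targets V2000 with
  `M  CHG`/`M  ISO` property-block override semantics.
* Problem sizes in the checks: 200 random molecules (8–25 atoms, both
  presets) for orbit agreement, 20 permutations per fixture for
  invariance, 50-compound database pairs for planted-truth recovery, and
  a 1000-molecule coloring run as the scale smoke test.

## Known limitations

* Symmetries visible only in a 3-D embedding (rotations/reflections of
  the embedded graph) are out of scope; the orbit notion is graph
  automorphism on the 2-D connection table.
* Compounds that legitimately alternate between linear and circular forms
  or between resonance structures get different identifiers per form;
  unifying those representations is unresolved here as it is upstream.
* The geometric cis/trans rule is a documented stand-in for full
  stereo-perception; it reads drawn 2-D coordinates and stays silent when
  geometry is degenerate.
* The bundled aromatic library is small by construction; recall of
  reference detection on exotic heteroaromatics depends on the library
  supplied.
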