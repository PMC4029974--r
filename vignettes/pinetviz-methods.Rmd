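---
title: "Methods: querying, styling and laying out PPI networks with pinetviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: querying, styling and laying out PPI networks with pinetviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinetviz)
```

`pinetviz` makes the workflow of an interactive protein–protein interaction
(PPI) viewer scriptable and reproducible. This vignette documents the
methods, the tunable parameters and their defaults, the numerical and design
choices that were genuinely open, and what the synthetic test data does and
does not demonstrate.

## File formats and parsing

Interactions are undirected scored edges: two accessions, an aggregate
confidence score, then optional per-source evidence scores. Features attach
an organism (required) and arbitrary annotation columns to each accession;
expression is a numeric accession × condition matrix. All three files are
UTF-8, tab-separated, with `#` comment lines and trailing blanks ignored.

Parsing is *total*: every input line produces a record, a warning, or a
located error — never silent loss. The repairs are deliberate:

* duplicate unordered endpoint pairs keep the record with the **highest**
  aggregate score (preserving the strongest evidence) and warn;
* an interaction endpoint missing from the features file gets a stub
  protein with organism `"unspecified"` and a warning;
* duplicate accessions in the features file follow last-wins with a warning;
* self-interactions are kept and flagged; they appear in the table/CSV view
  but are skipped by layouts and the SVG drawing (a loop glyph adds noise
  without information at network scale).

Header detection differs by file. The interactions file uses the numeric
test — a first line whose third field does not parse as a number names the
evidence columns ("NaN" counts as numeric so that an explicitly non-finite
score is an error, not a header). That test cannot work for the features
file, where every cell is text; there a first line is a header only when
its first field is one of `id`, `accession`, `protein`, `protein_id`
(case-insensitive). The expression file always carries a header naming its
conditions.

Aggregate scores are checked for finiteness only; no [0, 1] range is
imposed because different source databases scale confidence differently.

## Prefilters and search modes

Prefilters are an ordered AND over conditions with operators `contains`
(case-insensitive substring — database descriptions vary in case),
`equals`, `gt`/`ge`/`lt`/`le` (numeric fields only, enforced when the
condition is compiled), and `present` (the cell was non-empty in the file,
so an explicit evidence score of 0 still counts as present). After each
condition the running interaction count is recorded; the sequence is
non-increasing by construction.

A protein-scope condition passes an interaction when **either** endpoint
satisfies it. This is the default because, on a mixed host–pathogen
dataset, filtering by one organism must keep the cross-species edges that
motivate the analysis; a `protein_match = "both"` switch restricts to
edges internal to the matching set.

The three search modes, for query $Q$ over $G=(V,E)$ with displayed set $D$:

* **normal**: $D \cup \{(u,v) \in E : u \in Q \lor v \in Q\}$;
* **explicit**: $D \cup \{(u,v) \in E : u,v \in Q\} \cup
  \{(u,v) \in E : u \in Q, v \in D_V\}$;
* **recursive**: $D \cup E[Q \cup N(Q)]$, the induced subgraph on the query
  and its neighbours — equivalently a normal query followed by an explicit
  query for each recovered protein, so every interaction between displayed
  proteins is shown.

All three are additive (nothing displayed is ever removed; re-running a
query is a no-op) and the results are closed (every endpoint is a displayed
protein). Unknown accessions go to a warnings channel rather than failing
the search, matching how a user pastes a list of identifiers of mixed
quality. Whether explicit mode should also connect proteins that were
displayed earlier but not re-queried is not derivable from first
principles; the additive reading implemented here never removes existing
content and only adds edges that touch the current query.

## Metrics

Degree, connected components and betweenness are computed on the
**unweighted** simple graph — edge confidence scores do not shorten paths,
and self-loops are excluded. Betweenness is
$C_B(v) = \sum_{s<t} \sigma_{st}(v)/\sigma_{st}$ over unordered pairs,
with disconnected pairs contributing nothing;
`normalized = TRUE` divides by $(n-1)(n-2)/2$. Both variants are exposed
because node-sizing conventions differ between tools. The computation is
delegated to `igraph`; the test suite validates it against an independent
all-pairs BFS path-counting enumeration (exact to $10^{-9}$ on graphs of
up to 30 nodes, 50 random graphs) and closed forms for stars and paths.
Component ids are renumbered 0..k−1 by decreasing size (ties: smallest
member accession) so downstream output is stable.

## Rule engine

A rule is data: a target (protein or interaction), an optional condition
(the filter grammar extended with `degree`, `betweenness` and expression
conditions for proteins, and endpoint membership — "interactions with
protein Y" — for edges), and an action. Styling starts from fixed defaults
(node fill `#888888`, radius 5 px, labels hidden, everything visible; edge
stroke `#999999`, width 1 px) and applies rules in list order; the later
rule wins on any attribute both touch. That list-order precedence also
resolves the interplay between a categorical coloring and a subsequent
per-element paint: it is a deliberate convention, chosen for
predictability, not something the underlying viewer model prescribes.

Categorical coloring walks the displayed proteins in their stored order,
assigns the fixed 12-color qualitative palette to distinct values in
first-seen order (cycling with a warning beyond 12), maps empty values to
a reserved "unannotated" gray listed last, and replaces the legend.
Value-based coloring interpolates each RGB channel linearly between two
colors over a stated `[vmin, vmax]`, clamping outside values; channels are
rounded **half-down** to integers so the midpoint of black and white is
`#7f7f7f` bit-stably on every platform. Type errors (a numeric operator on
a text field) are raised when the rule list is compiled, before any
element is styled.

## Layouts

**Force layout.** A Fruchterman–Reingold-style simulation: repulsion
$k^2/d$ between all pairs, spring attraction $d^2/k$ along edges, with
$k=\sqrt{wh/n}$, extended with a linear gravity force
$g\,( \mathbf{c}_{o(v)}-\mathbf{p}_v)$ pulling each node toward its
organism's anchor. Anchors: one organism sits at the canvas center; $m\ge2$
organisms are evenly spaced (in lexicographic order, so the assignment is
stable) on a circle of radius $\min(w,h)/4$, starting east and proceeding
counter-clockwise. Applying repulsion to *all* pairs — rather than only to
unlinked nodes — with springs strong enough to dominate on edges is the
standard formulation and visually equivalent; it is a documented divergence
from the qualitative description of a repulsion "between nodes without a
link".

Per-node displacement is capped by a temperature starting at
$\min(w,h)/10$ and decaying geometrically (`cooling_factor`, default
0.99); the simulation stops when the maximum displacement falls below
`displacement_tolerance` (default 0.05 px) or after `max_iterations`
(default 1000). Because the cap itself decays below the tolerance in about
760 iterations at the defaults, convergence within the iteration budget is
guaranteed, and the tests confirm it over 20 seeds on graphs up to 200
nodes.

The force multipliers are this package's own calibration (the underlying
viewer model names only the qualitative behaviour of a generic
force-directed engine): `repulsion_strength = 0.05` and
`gravity_strength = 0.5` (with `attraction_strength = 1`) were chosen once
so that, at the default 1000×1000 canvas, clusters neither collapse onto
their anchors nor get pushed to the canvas edge, and every node ends
nearest its own organism's anchor on datasets without cross-organism edges
— the testable form of "species separate visually". Initial positions are
the organism anchor plus uniform jitter of ±min(w,h)/20 from the seeded
generator (no jitter for a singleton network, whose equilibrium is exactly
the anchor); coincident points are separated through a minimum-distance
epsilon of 10⁻⁴.

All randomness uses a documented, language-portable linear congruential
generator (`state ← (1664525·state + 1013904223) mod 2³²`, uniforms
`(state+0.5)/2³²`), so identical inputs and seed give bit-identical
positions anywhere.

**Circle layout.** Deterministic and random-free: all nodes on one circle
of radius $0.4\min(w,h)$, organisms in contiguous arcs (lexicographic
order) separated by one empty slot each — no gaps for a single organism —
nodes within an arc sorted by accession, slot 0 at angle 0. Coordinates
follow the SVG convention (origin top-left, y down); angles are measured
in the conventional y-up sense, i.e. $y = c_y - r\sin\theta$.

## Rendering and export

SVG output is byte-stable: fixed element ordering (edges by canonical key
beneath nodes by accession), fixed `%.3f` coordinate formatting, no
timestamps or generated ids. Edges are drawn only when the edge and both
endpoints are visible. Labels use a generic sans-serif at 10 px for
portability; the legend occupies a right-hand group. An option maps
organisms to circle/square/diamond glyphs in lexicographic order. The PNG
exporter is a small deterministic scanline rasterizer over the emitted
SVG's lines, circles, rectangles and polygons, encoding through the `png`
package; its contract is dimensional (scale × canvas), and text is not
rasterized. The table view lists one row per displayed interaction
(self-loops included) with endpoint organisms, score and evidence columns,
sorted stably with ties on the second endpoint; CSV export follows RFC
4180 with minimal quoting and CRLF records.

## Sessions, replay and sharing

Histories store operations and their **parameters**, never results: replay
against the dataset is authoritative and the payload stays small. Replaying
a prefix yields the state after step *k*, which gives "jump to a point in
the history" for free. The serialized state (schema `pinv-state-v1`,
fixed key order, sorted set members) is the shareable artifact; it embeds
an FNV-1a 32-bit fingerprint of the dataset's canonical TSV serialization
so a collaborator loading the state against different data gets a hard
mismatch error instead of a silently wrong view — a safeguard this package
adds, not inherited behaviour. Rules added to a session are compiled
against the dataset immediately, so a history entry naming an unknown
field fails at record/replay time with its entry index. `embed_snippet()`
emits the single-iframe HTML fragment for embedding a hosted view.

## Synthetic data: what it shows and what it does not

The generator emulates the structural features the methods depend on:
organism blocks of configurable proportion, independent within- and
cross-organism edge probabilities, uniform (0, 1] confidence scores,
evidence cells present with probability 0.5, categorical annotations drawn
from a small vocabulary, and a uniform expression matrix (2 conditions by
default, values on (0, 10) — a deliberate, minimal stand-in since the
generator's contract only requires numeric conditions). Defaults (two
equal organisms, `edge_probability = 0.2`,
`cross_organism_probability = 0.05`) give sparse, mildly modular networks
of the shape the query and layout engines target.

It deliberately does **not** reproduce biological realism: no heavy-tailed
degree distributions, no correlation between evidence sources and the
aggregate score, no orthology structure, no hub proteins. Passing tests
therefore demonstrate the *correctness of the algorithms* (set semantics,
counts, invariants, determinism) on networks of realistic size and
sparsity — not that visual output on real interactome data will be
informative, which depends on annotation quality and network modularity.

The fixed TOY6 fixture (6 proteins, 2 organisms, 5 interactions, one
evidence value, one isolated protein) is small enough that every expected
value in the tests is derivable by hand.

## Problem sizes and runtime choices

The test and acceptance batches use sizes chosen to keep brute-force
oracles exact and fast while covering the regimes that matter: query-mode
oracle equivalence on 100 random datasets of up to 50 nodes; betweenness
enumeration on graphs of up to 30 nodes (the $O(n^3)$ oracle's comfortable
range) over 50 graphs; layout convergence over 20 seeds on graphs up to
200 nodes; 50 randomized 20-operation session replays. The interaction
pair-sampling in the generator is $O(n^2)$, which is adequate to the
few-hundred-node networks a desktop viewer displays.

## Known limitations

* Community detection / clustering of very large networks is out of scope.
* The query engine is exact-match only (no full-text relevance ranking or
  fuzzy matching).
* The force layout is a batch computation, not an animated simulation, and
  exposes no drag interaction.
* PSI-MITAB and other exchange formats are not parsed; datasets must be in
  the two-file TSV layout.
* The PNG rasterizer does not draw text (labels and legend text appear in
  SVG output only).
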