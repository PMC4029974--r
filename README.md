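# pinetviz

Scriptable visualization and querying of scored protein–protein interaction
(PPI) networks spanning one or more organisms.

Interactive PPI viewers let a biologist reduce a network of hundreds of
thousands of scored interactions to a readable subnetwork, color it by
annotation, and share the resulting view. `pinetviz` packages that workflow
as a reproducible R library plus a command-line tool: every step —
filtering, querying, styling, layout, export — is a pure function over
explicit state, every action is logged, and any view can be regenerated
exactly from its provenance history.

## Data model

A dataset is two (optionally three) tab-separated files:

* **interactions** — `accession_a  accession_b  score  [evidence …]`: an
  undirected edge with an aggregate confidence score in column 3 and
  optional per-source evidence scores (e.g. from STRING or IntAct) in
  columns 4+;
* **features** — `accession  organism  [annotation …]`: the organism is the
  one required annotation; further columns (description, functional class,
  gene name…) drive styling and filtering;
* **expression** (optional) — `accession` plus one numeric column per
  condition, for quantitative coloring.

## Core methods

* **Prefilters** — an ordered conjunction of conditions
  (`protein.organism contains tuberculosis`, `interaction.score ge 0.6`, …)
  over the whole dataset, reporting the cumulative interaction count after
  each condition. A protein-scope condition passes an interaction if at
  least one endpoint satisfies it (configurable to both).
* **Search modes** — for a query set *Q* over graph *G = (V, E)*:
  *normal* returns all edges with an endpoint in *Q*; *explicit* returns
  edges within *Q* (plus edges joining *Q* to the already displayed set);
  *recursive* returns the induced subgraph on *Q* ∪ N(*Q*), so every
  interaction between displayed proteins is shown. Searches are additive
  and never remove displayed content.
* **Metrics** — degree, connected components, and shortest-path
  betweenness centrality C_B(v) = Σ_{s<t} σ_st(v)/σ_st on the unweighted
  graph (optionally normalized by (n−1)(n−2)/2).
* **Rule engine** — ordered, serializable rules of the form
  *target* (protein/interaction) + *condition* + *action* (paint, label,
  resize, hide, categorical palette, two-color value gradient). Later
  rules override earlier ones; categorical coloring fills the legend.
* **Layouts** — a Fruchterman–Reingold-style force simulation (repulsion
  k²/d, edge springs d²/k, k = √(area/n)) extended with one linear gravity
  well per organism so species separate visually, plus an exact circle
  layout with contiguous per-organism arcs. Both are deterministic; all
  randomness flows through a documented linear congruential generator.
* **Exports and sessions** — byte-stable SVG (edges beneath nodes, legend
  group), PNG rasterization, RFC 4180 CSV of the table view, and a
  versioned JSON session state (`pinv-state-v1`) whose history replays to
  the identical view.

## Worked example

```r
library(pinetviz)
d <- toy6()                       # bundled 6-protein, 2-organism fixture
d
#> PPI dataset: 6 proteins (2 organisms), 5 interactions
#>   evidence sources: string
#>   feature columns:  description

apply_prefilters(d, list("protein.organism contains b",
                         "interaction.score ge 0.6"))
#> Prefilter: 5 interactions in dataset
#>   AND protein.organism contains b                   -> 2
#>   AND interaction.score ge 0.6                      -> 1
#> Subnetwork: 2 proteins, 1 interactions

sub <- search_network(d, "P3", mode = "recursive")
metric_table(sub)
#>   accession degree betweenness component_id
#> 1        P1      2           0            0
#> 2        P2      2           0            0
#> 3        P3      3           2            0
#> 4        P4      1           0            0

st <- apply_rules(sub, list(
  style_rule("protein", NULL, style_action("color_by_category", feature = "organism")),
  style_rule("protein", "protein.degree gt 2",
             style_action("show_label", feature = "description"))), d)
st$legend
#>   value   color
#> 1     A #1f77b4
#> 2     B #ff7f0e

lay <- force_layout(sub, d, layout_params(seed = 42))
lay
#> force layout: 4 nodes, 758 iterations, converged = TRUE
render_svg(sub, lay, st)
#> SVG document: 4 nodes, 4 edges, 1 labels, 2 legend entries
```

The two cumulative counts (2, then 1) show how each added condition
shrinks the candidate subnetwork; the recursive query around the hub P3
pulls in its neighbourhood and the P1–P2 edge between neighbours; only P3
(the single node with more than 2 interactions) receives a label; the two
organisms get the first two palette colors and their own gravity wells in
the layout.

The same pipeline from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pinetviz.R", package = "pinetviz"))')
Rscript $CLI fixtures --out data/
Rscript $CLI load   --interactions data/interactions.tsv --features data/features.tsv --state s.json
Rscript $CLI search --state s.json --ids P3 --mode recursive
Rscript $CLI layout --state s.json --engine force --seed 42
Rscript $CLI export --state s.json --svg net.svg --csv table.csv
Rscript $CLI session history --state s.json
```

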