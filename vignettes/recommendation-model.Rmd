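---
title: "A sequential decision-matrix model for genomics visualization recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sequential decision-matrix model for genomics visualization recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genovizrec)
```

## The problem

Choosing an interactive visualization for genome-mapped data is a design
problem with a large, structured space: every data attribute needs a visual
encoding, encodings combine into tracks, tracks into views, views into
multi-view arrangements, and the right choices depend jointly on the data's
shape (feature extent, density, attribute types, connectivity) and the
analyst's task. `genovizrec` implements a knowledge-based recommender over
this space. Its inputs are *descriptions* of data, never data itself: a
scenario names one or more files by format (BIGWIG, BED, BEDPE, SEG, VCF,
COOLER), their genome assembly, attribute counts by type (quantitative,
categorical, text), feature extent (point or segment), density (sparse or
contiguous) and connectivity (none, intra- or inter-genome, with sparse or
dense connection density), plus one task: *identify* (read values in a
region), *compare* (relate two regions), or *overview* (scan the genome for
patterns). Fields omitted from a description are filled from per-format
defaults (`defaults_for_format()`); e.g. BIGWIG implies point-based
contiguous signal, BED sparse segments, COOLER a dense intra-genome contact
network. An unset task defaults to *overview*, because recommendations are
already useful while a user is still describing data, and the pre-task
behaviour coincides with the overview rules.

## The model

The design space is decomposed into six components resolved in a fixed
order — encoding, alignment, layout, partition, arrangement, interactivity —
chosen so that each component's feasible options depend only on decisions
already made (an orthogonal arrangement, for instance, presupposes linear
tracks). Knowledge per component is a **decision matrix**: rows are output
options, columns are input factors, and each cell is +1 if the option
supports the factor, −1 otherwise. Scoring is cosine similarity between a
row and a component input vector that codes active factors as +1 and
inactive ones as −1. With both vectors in $\{\pm1\}^d$ the score is
$1 - 2m/d$, where $m$ is the number of disagreeing positions, so it lives
in $[-1, 1]$ and equals 1 exactly when a row supports precisely the active
factors.

Two properties of this coding matter in practice and shaped the packaged
matrices:

* **Absence matches absence.** A row with few +1 cells agrees with a
  mostly-inactive input on all the jointly negative positions, so narrow
  rows can outscore broadly applicable ones on small active sets. For this
  reason the hard design rules are enforced by *pruning* infeasible rows
  before ranking rather than by low scores alone.
* **Only mismatch counts matter.** All rows share the same norm, so
  preferences that hold "all else equal" need explicit factor columns. The
  contiguous-vs-segregated partition default is encoded this way: the
  contiguous row carries three always-active factor columns
  (`single_genomic_axis`, `track_economy`, `cross_chromosome_context`) that
  name its task-independent advantages — one continuous axis, one track
  instead of one per chromosome, preserved cross-chromosome context. Three
  columns (not one) are needed because a row supporting all three tasks
  always pays two mismatches on the inactive task columns; the weight-3
  default outweighs that, giving contiguous a strict lead for every task
  while segregated remains a feasible overview variation. A single "default"
  column would invert the intended order.

### Hard design rules

Four rules from visualization research and genomics practice act as
feasibility constraints (pruned options never enter a ranking) *and* are
reflected in matrix cells:

1. **Channel effectiveness.** Quantitative values map to position, length,
   or — for overview tasks only — color saturation; hue never encodes
   quantitative data. Categorical values get hue with a consistent
   colorblind-safe palette.
2. **Alignment.** Tracks from different files never overlay (occlusion);
   within one file, exactly one position/length track may overlay one color
   track. Stacking is the default and the stacking order always follows the
   file order of the scenario.
3. **Layout.** Position/length encodings of quantitative data are easier to
   read and compare in linear layouts, so circular layouts are pruned for
   identify/compare tasks whenever the scenario contains a quantitative
   attribute. Space-filling (Hilbert-curve) layouts render exactly one
   encoded attribute and serve genome-scale pattern search, so they require
   a single-encoding scenario and an overview task. (The overview
   restriction goes slightly beyond the single-track constraint: without
   it, the narrow space-filling row would outrank linear for single-track
   identify scenarios, which contradicts how region-navigation tasks are
   actually performed.)
4. **Arrangement.** Orthogonal (adjacency-matrix) arrangements require a
   dense network on linear tracks; circular layouts with network data pair
   with adjacent arrangements; a compare task without network data yields
   two parallel windows.

### Sequencing, ties and branching

`run_pipeline()` resolves C1→C6 in order. At each component the feasible
options are ranked and every option within `tolerance` (default `1e-9`, a
floating-point equality guard) of the maximum branches the candidate set as
a Cartesian product. Exact ties are therefore *design variations* — e.g. a
bar chart and a line chart for point-based contiguous quantitative signal —
and deliberately survive to the output; sorting is stable with matrix row
order as the tiebreak, so results are deterministic. Expansion is capped at
`max_candidates` (default 64) with a warning, since longer recommendation
lists are unusable. Interactivity (C6) is set-valued rather than branching:
the tied top patterns are all included, and any view holding multiple
tracks additionally receives coordinated zooming and panning as a hard
rule. A candidate's C6 score is the best included pattern's score; its
aggregate score is the mean of the six component scores, which keeps the
$[-1, 1]$ scale and weights components equally.

### Exhaustive scoring and optimality

`enumerate_all()` scores every feasible combination over all components'
full option sets — the harness used to select evaluation stimuli:
`select_stimuli()` returns the top-scored design and the design whose score
is closest to the median of the distribution (mean-of-middles median for
even counts; score ties in either role are resolved by a seeded uniform
draw, so selection is reproducible).

The sequential pipeline is greedy per component, and a greedy pass over
coupled scores need not reach the global maximum. Three modelling choices
make the packaged knowledge base *decoupled enough* that it provably does
(the test suite checks equality of the pipeline's best aggregate with the
exhaustive maximum over seeded random scenarios):

* Alignment (C2) is scored from structural factors only (file and track
  multiplicity); whether a position+color pair exists gates overlay
  *feasibility* but does not move scores.
* Layout factors (position/length usage, color-only profiles, the
  quantitative demotion of circular layouts) derive from the scenario's
  attribute kinds rather than from the encodings chosen on a particular
  branch. Attribute kinds determine the channel profile up to the
  saturation design variation, and the data description is also what
  drives the observable behaviour being modelled (adding a quantitative
  file removes circular recommendations).
* Interactivity (C6) is scored by task alone; its view/track-multiplicity
  columns are declared in the matrix but non-discriminating, because
  interaction patterns apply within a view and multi-track coordination is
  a hard rule rather than a preference.

Without these choices, a deliberately sub-optimal encoding could "buy back"
more score downstream than it loses (for instance by creating an overlay
pair or dodging the circular-layout prune), and the pipeline's top output
would not be the global optimum.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tolerance` | `1e-9` | tie width for `top_set()`; scores are rational with small denominators, so this acts as exact-tie detection |
| `max_candidates` | 64 | branch cap in `run_pipeline()` |
| `source` of `load_knowledge_base()` | packaged assets | alternative decision-matrix directory; one TSV per component plus a manifest |
| palette | 8-color Okabe–Ito | categorical colors, assigned by position so an attribute keeps its colors across tracks and candidates; counts beyond 8 cycle with a warning |
| saturation ramp | `#DEEBF7 → #08519C` | single-hue ramp for quantitative color |
| assembly default | `hg38` | coordinate system written into emitted documents when the description omits one |

## Output dialect

`emit_spec()` serializes a candidate as JSON in a pinned subset of the
Gosling grammar (schema asset: `inst/extdata/gosling-subset-schema.json`,
subset version 1.0): one view per window, tracks in file order, marks
bar/line/point/rect/text plus within/between-genome link marks, genomic
`x`/`xe` channels (1-based inclusive coordinates), quantitative `y`,
nominal or quantitative `color`. Overlay pairs merge into one track with
the color encoding under `overlay`. Compare and focus+context designs
attach a genome-wide overview/brush navigation object to each view; it is
navigation apparatus, not a data track, so it does not count toward track
totals. Data blocks are placeholder references (`placeholder://<label>.<format>`)
since the recommender never reads payloads. `validate_gosling_document()`
is the package's structural validator for this dialect and returns
violations rather than raising.

## The scenario generator

`random_scenario(seed)` draws 1–3 files with formats uniform over the six
supported formats, 1–2 attributes per file with kinds uniform over
quantitative/categorical/text, and a task uniform over the three tasks.
Feature fields follow the format defaults; 10% of file draws override them
with an arbitrary consistent combination (any extent/density, any
connection with a coherent density, a secondary assembly for inter-genome
links). The generator runs on a local RNG and restores global RNG state.
It emulates the *descriptive* diversity of real analyses — every format,
kind, task and connectivity class appears — but not their empirical joint
distribution: real corpora over-represent some combinations (e.g. BIGWIG
signal with identify tasks) and real files carry many attributes. Passing
property tests over generated scenarios therefore demonstrates rule
compliance and determinism across the whole description space, not
calibrated behaviour on any particular real-world workload.

## Numerical choices and degenerate inputs

Cosine scores are clamped to $[-1, 1]$ to absorb floating-point spillover;
all-zero vectors cannot arise under the ±1 coding. Ranking uses a stable
sort (`order`) so equal scores keep matrix row order. A single-track
candidate is treated as a stacked group of one. Scenarios with zero files
are rejected at parse/validation time; duplicate file labels, incoherent
connection fields and missing secondary assemblies are reported as
itemized validation violations rather than thrown one at a time.

## Known limitations

* The encoding-row inventory covers the mark/channel combinations the
  model can recommend; it is deliberately extensible (add a TSV row) but
  not exhaustive over all conceivable genomics glyphs.
* Gene-annotation and ideogram context tracks, rendering, and reading real
  data payloads are out of scope; emitted documents reference data by
  descriptor label only.
* Scores express the packaged domain knowledge, not learned weights; there
  is no user-preference term, and all factors weigh equally within a
  component.
* The evaluation-stimulus machinery reproduces the selection procedure
  (top vs closest-to-median), not any human-subject results.
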