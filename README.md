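# genovizrec

Knowledge-based recommendation of interactive genomics visualizations.

Genomics analysts routinely juggle heterogeneous genome-mapped data —
signal tracks (BIGWIG), feature intervals (BED), variants (VCF), copy-number
segments (SEG), paired intervals (BEDPE), contact matrices (COOLER) — and
must pick, for each combination of data and analysis task, an appropriate
interactive visualization: which marks and channels encode each attribute,
whether tracks stack or overlay, a linear / circular / space-filling layout,
how chromosomes are partitioned, how multiple views are arranged, and which
interaction patterns help. `genovizrec` automates that choice. It consumes
*abstract descriptions* of datasets (file format, attribute types, feature
extent and density, connectivity) plus one of three analysis tasks
(*identify*, *compare*, *overview*) and emits ranked, complete visualization
designs as JSON documents in a pinned subset of the Gosling grammar. No
data files are ever read — the recommendation operates on descriptors only.

## The model

Recommendation knowledge is stored as six **decision matrices**, one per
design component, resolved in a fixed sequence:

| | component | output options |
|---|---|---|
| C1 | encoding | mark + channel pairs (point/line/rect/text × position/length/saturation/hue) |
| C2 | alignment | stacked, overlayed |
| C3 | layout | linear, circular, space-filling |
| C4 | partition | contiguous, segregated |
| C5 | arrangement | single, parallel, adjacent, orthogonal |
| C6 | interactivity | focus+context, coordinated zoom/pan |

Each matrix has output options as rows, input factors as columns, and cells
in {+1, −1} ("this option supports this factor"). For a scenario, an input
vector **u** ∈ {+1, −1}^d is built per component (+1 for active factors, −1
otherwise) and every row **v** is scored by cosine similarity

&nbsp;&nbsp;&nbsp;&nbsp;s(u, v) = (u · v) / (‖u‖ ‖v‖) ∈ [−1, 1].

Options violating a hard design constraint (hue for quantitative data,
overlay across files, circular layouts for region-level tasks on
quantitative position encodings, orthogonal arrangements without a dense
network, multi-track space-filling curves) are pruned before ranking. Exact
score ties among the remaining top options branch the candidate set via a
Cartesian product, so design variations propagate to the user. Each
complete candidate carries its six component scores; their mean is the
aggregate score used for the final ranking. An exhaustive mode
(`enumerate_all()`) scores *every* feasible design — the sequential
pipeline provably attains its maximum on the packaged knowledge base — and
`select_stimuli()` picks the top-scored design plus the design closest to
the median score, the pairing used for evaluation studies. The matrices
ship as editable TSV assets (`inst/extdata/kb/`), so the encoded domain
knowledge can be revised without touching code.

## Worked example

Three files — disease-linked genes (BED, categorical), structural variants
(VCF, categorical), protein–DNA binding signal (BIGWIG, quantitative) — and
a *compare* task:

```r
library(genovizrec)
sc <- builtin_scenarios("walkthrough")
cands <- run_pipeline(sc)
for (cand in cands) print(cand)
```

```
<candidate> score 0.468 | stacked, linear, contiguous, parallel (2 views), focus_context+coordinated
    BED1     gene_class   rect+hue (interval)
    VCF1     variant_type point+hue
    BIGWIG1  signal       rect+length
<candidate> score 0.468 | stacked, linear, contiguous, parallel (2 views), focus_context+coordinated
    BED1     gene_class   rect+hue (interval)
    VCF1     variant_type point+hue
    BIGWIG1  signal       line+position
```

Exactly two tied designs: gene intervals as hue-colored rectangles,
variants as colored points, and the quantitative signal either as a bar
chart or as a line chart — stacked in file order on a linear, contiguous
genome axis, split into two parallel windows for region comparison, with
focus+context navigation and coordinated zoom/pan. Exporting the
line-chart variant:

```r
doc <- emit_spec(cands[[2]], sc)
writeLines(doc$text, "signal_line.json")
validate_gosling_document(doc)   # character(0): valid against the subset schema
```

The same workflow is available from a shell:

```sh
genovizrec recommend --scenario scenario.json --out recs/
genovizrec explain   --scenario scenario.json
genovizrec enumerate --scenario scenario.json --seed 7
```

`explain` prints every option's cosine score per component with the chosen
options starred; `enumerate` prints the exhaustive scored design listing and
the top/median-alternate stimulus pair.

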