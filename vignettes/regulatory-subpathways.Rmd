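---
title: "Scoring miRNA target-specific regulatory sub-pathways"
author: "rspnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring miRNA target-specific regulatory sub-pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rspnet)
```

## The model

A microRNA (miRNA) `M` represses a target gene `T`. The encoded protein
of `T` interacts physically with other proteins, and regulatory
influence can propagate along those interactions. `rspnet` models the
local downstream neighborhood of a target as the set of **regulatory
sub-pathways (RSPs)**: ordered triples `(T, G1, G2)` such that `T–G1`
and `G1–G2` are both edges of an undirected protein–protein interaction
(PPI) graph. Prefixing the regulating miRNA gives a miRNA-specific
sub-pathway `(M, T, G1, G2)`. Sub-pathways are simple paths by default:
`G2 != T`, because a path folding back onto its own target carries no new
downstream information (`allow_return = TRUE` relaxes this for users who
want the raw two-hop walk set).

Two scores qualify each sub-pathway, both computed from annotation-term
sets. Writing `[G]_X` for the set of namespace-X terms (Gene Ontology
Biological Process or Molecular Function) annotating gene `G`:

* **Jaccard score.** With `JC(S1, S2) = |S1 n S2| / |S1 u S2|`, the
  sub-pathway score is the mean of the two hop-wise coefficients,
  `JS_X = ( JC([T]_X, [G1]_X) + JC([G1]_X, [G2]_X) ) / 2`. The score
  rests on the assumption that directly interacting proteins tend to
  take part in the same biological processes or share molecular
  functions. If either hop has a zero coefficient — the pair shares no
  annotation — the sub-pathway is **not viable** in that namespace and
  is discarded. Both `JS_BP` and `JS_MF` are always reported; the
  namespace the user ranks by (the query's `namespace`) is the one that
  gates viability and feeds the p-value.
* **Overlap p-value.** For a gene pair with term-set sizes `x` and `y`,
  observed overlap `n`, and `N` distinct terms in the namespace, the
  pair p-value is the hypergeometric point probability
  `C(x, n) C(N - x, y - n) / C(N, y)` of seeing exactly that overlap by
  chance. The sub-pathway p-value is the **greater** of its two pair
  p-values — both hops must be improbably coherent for the sub-pathway
  to score well. An upper-tail variant (`tail = TRUE`, summing over
  overlaps `>= n`) is available for users who prefer an
  enrichment-style p-value; the point form is the default and the form
  used everywhere in this package's own analyses.

The equivalent triple-binomial expression
`C(N, n) C(N - n, x - n) C(N - x, y - n) / (C(N, x) C(N, y))` is kept as
an independent evaluation route ([pair_pvalue_literal()]), and the test
suite proves the two forms identical by exact integer cross-multiplication
on an exhaustive grid.

A note on reading the overlap count: the quantity `n` is the size of the
*intersection* of the two term sets. This is the only reading under
which the expression above is a probability (it then normalizes to 1
over all feasible `n`), and the test suite checks that normalization
exhaustively for every feasible configuration with `N <= 12`.

## From disease to network

A disease query proceeds in four steps:

1. select the disease (matching is case-insensitive, exact after
   trimming — no fuzzy matching);
2. collect its associated miRNAs and their target genes, optionally
   keeping only targets supported by at least one of the seven direct
   validation assays (HITS-CLIP, PAR-CLIP, IMPACT-Seq, CLASH, Luciferase
   Reporter Assay, 3LIFE, Genetic Testing) and only targets expressed in
   the query tissue;
3. enumerate and score all sub-pathways per target, keep viable ones
   with `p <= p_threshold`, and apply the optional filters (cancer-gene
   tags, a required gene, a required pathway, top-N by p-value);
4. assemble the regulatory network: miRNA nodes joined to their targets
   by regulation edges, plus **PPI closure** — every pair of genes in
   the network that interacts in the source graph is linked, whether or
   not a sub-pathway contains that pair. Closure adds edges, never
   nodes.

For a disease pair, both diseases run independently (each with its own
tissue setting) and the **comorbid genes** are the intersection of the
two sub-pathway gene sets, where a disease's gene set collects all three
positions T, G1 and G2. Interactors count as genes here deliberately:
two diseases with disjoint target sets can still share substantial
downstream machinery, and that shared machinery is precisely what a
comorbidity query is after.

Filter-order choices that were genuinely open are fixed as follows: all
record-level filters apply first and top-N truncation last, so "top 70"
always means the 70 best sub-pathways *satisfying* the filters; the
tissue filter constrains all three sub-pathway genes by default
(`tissue_scope = "all_genes"`), since a tissue-specific network should
not route through genes unexpressed in the tissue, with a
`"target_only"` mode for the looser reading. Pathway tags require all
three genes of a sub-pathway to be members (`pathway_rule = "all"`);
`"any"` is available where a coarser association is wanted.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `namespace` | `"MF"` | annotation namespace for ranking, viability and p-values |
| `p_threshold` | 0.001 (fixtures ship 0.005) | maximum sub-pathway p-value, in (0, 1] |
| `require_validated` | off | keep only direct-assay-validated targets |
| `cancer_filter` | `"none"` | `"target_only"` / `"all_genes"` require CRG/OCG/TSG tags |
| `tail` | off | upper-tail rather than point p-value |
| `top_n` | unset | keep the N smallest-p records after filtering |

Ties in p-value are broken deterministically: higher selected-namespace
Jaccard score first, then lexicographic `(T, G1, G2, miRNA)`. All
character sorting uses radix (C-locale) order so outputs are
byte-identical across platforms and locales.

## Numerical choices

Binomial coefficients are exact integer-valued doubles whenever every
intermediate stays below 2^53, which covers all universes that occur in
annotation practice at small set sizes; beyond that the computation
moves to log-gamma space and exponentiates once at the end. Degenerate
inputs are defined rather than special-cased downstream: `JC` of two
empty sets is 0 (hence non-viable, avoiding 0/0), a gene absent from an
annotation source has the empty term set, and an infeasible overlap
configuration (e.g. `n > min(x, y)`) is a domain error, never a silent
0. Scores are exported at 6 significant digits.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` writes the full set of input tables (GMT gene
sets, PPI edge list, disease–miRNA, miRNA–target with methods and
direction, gene–tissue, gene–cancer-tag, plus `config.yaml`) from a
single master seed, one pseudo-random stream per table so that resizing
one table never perturbs another. Background structure: Bernoulli PPI
edges at `ppi_density` over `n_genes` genes, uniform term assignment of
3–10 terms per gene and namespace, and an `edge_overlap_boost`
probability that an interacting pair receives an extra shared term
(without it, typical random Jaccard overlaps would be unrealistically
near zero). Defaults — 500 genes, density 0.016 (about 2,000 expected
edges), 300 BP / 150 MF terms, 40 pathways, 4 diseases — were chosen
once as a benchmark a laptop analyses in seconds while leaving room for
non-trivial background sub-pathways.

On top of the background, a PPI-isolated planted component provides
hand-checkable ground truth: two planted targets `TGT1`, `TGT2` (one
per planted disease) joined through a shared branch `SHB1–SHB2` with
fixed overlaps `x = y = z = 3`, `n1 = n2 = 2` in both namespaces, and a
decoy interactor `DCY1` carrying no annotation, whose paths must be
discarded by the zero-Jaccard rule. Because viability propagates
through `SHB1`, the cross paths `(TGT1, SHB1, TGT2)` and
`(TGT2, SHB1, TGT1)` are viable by construction, so the comorbidity
query over the two planted diseases returns exactly
`{SHB1, SHB2, TGT1, TGT2}` — recorded as such in `manifest.yaml`. The
manifest's overlap counts drive `expected_scores()`, an oracle that
recomputes JS and the p-values directly from `(x, y, z, n1, n2, N)`
without touching the pipeline.

The generator makes no attempt to reproduce real-database degree
distributions, the GO DAG (terms are flat labels, as in the scoring
itself, which only ever uses term lists), database release artifacts,
or identifier aliasing. Passing the planted-recovery tests therefore
demonstrates correctness of the mechanics — enumeration, scoring,
filtering, assembly, intersection — not biological validity of scores
on any particular public data release; headline counts from real
HMDD/TarBase/BioGRID snapshots depend on those releases and are out of
this package's scope.

## Worked example

```{r example}
fx <- file.path(tempdir(), "demo_fixture")
generate_fixture(fixture_spec(seed = 7), fx)
bundle <- load_bundle(fx, quiet = TRUE)
q <- query_from_options(bundle, "disease_01")
report <- run_single(bundle, q, file.path(tempdir(), "demo_run"))
report
read.delim(file.path(tempdir(), "demo_run", "rsps.tsv"))
```

The planted sub-pathway `(TGT1, SHB1, SHB2)` appears with
`JS_MF = 0.5` (both hops overlap 2 of 4 union terms) and
`p = 0.000799927`, matching the closed form
`3 (N - 3) / C(N, 3)` at `N = 150` MF terms; the decoy paths through
`DCY1` are absent.

## Known limitations

* Gene identity is the case-sensitive symbol as given; no alias
  resolution is attempted, so inputs must be pre-harmonized to one
  symbol space.
* p-values are raw point (or tail) probabilities; no multiple-testing
  correction is applied, matching the thresholding semantics of the
  query interface the package models. Users comparing many
  sub-pathways statistically should treat the p-value as a ranking
  score, not an error rate.
* The PPI graph is undirected and unweighted; evidence codes and
  interaction detection methods are not modeled.
* Direction flags (positive/negative regulation) are carried through
  but do not influence scoring.
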