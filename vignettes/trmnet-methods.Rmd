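---
title: "Reconstructing transcriptional regulatory modules from PPI networks"
author: "trmnet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing transcriptional regulatory modules from PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trmnet)
```

## The model

A transcriptional regulatory module (TRM) is modelled as a connected
piece of the cell's physical protein–protein interaction (PPI) network
that links a *target* transcription factor (the TF immunoprecipitated in
a ChIP-seq experiment) to the *enriched* TFs whose binding motifs are
over-represented in the target's binding regions and whose genes are
expressed in the cell type. Proteins that sit between target and
enriched TFs without motif evidence of their own are *bridge* proteins —
frequently chromatin modifiers or signalling molecules that cannot be
found from sequence alone, which is exactly why the PPI layer is worth
the extra machinery.

Formally, given an undirected PPI graph $G$, a target set $T$ and a
query set $Q$, a (target, query) pair is *admissible* when its shortest
path uses at most $b + 1$ edges, where $b$ is the maximum number of
bridge proteins allowed (default $b = 1$, i.e. paths of at most three
nodes). The module is the subgraph of $G$ induced on the union of the
nodes of **all** shortest paths over all admissible pairs. Using all
co-minimal paths (no sampling, no tie-breaking) keeps the result
deterministic and complete; using the *induced* subgraph keeps
query–query and bridge–bridge interactions that the paths themselves did
not traverse.

### Assumptions worth stating

* The PPI graph is treated as unweighted and undirected; edge
  multiplicity (number of supporting interaction records) is carried
  as an attribute, exported, and never used to filter or weight paths —
  no principled threshold for it exists.
* Only minimal-length paths per pair contribute. A longer detour between
  an adjacent pair would fit the length bound but is not a shortest
  path; including it would make modules grow with graph density rather
  than with regulatory signal.
* Target–target pairs are searched like target–query pairs (both ends
  are TFs of interest); `targetPairs = FALSE` disables this.
* An empty module is a legitimate outcome (a target absent from the PPI
  network, or no admissible pair) and is returned flagged, not as an
  error.

### The node-inclusion rule

Two readings of the search are defensible: keep only nodes lying on
admissible target–query shortest paths, or additionally keep all direct
neighbours of the target. We adopt the path-based rule as the default
because extra nodes are meaningful precisely as *bridges between TFs*;
a dangling neighbour with no motif evidence and no connecting role has
no claim to module membership. The looser variant is available as
`findTRM(..., includeNeighbors = TRUE)` for users who want the full
first shell around the target.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maxBridge` | 1 | bridge proteins per path; path length ≤ `maxBridge`+1 edges |
| `flank` | 200 bp | summit extension; regions are `2*flank` wide (400 bp) |
| `qThresh` (enrichment) | 0.05 | strict `q <` threshold per replicate run |
| `minFrac` | 0.8 | fraction of replicate runs required (ceiling rule: 8 of 10) |
| `qThresh` (matching) | 0.05 | strict `q <` threshold for library matches |
| expression cutoff | user-supplied | CPM > 1 for RNA-seq; log2-intensity cutoffs (e.g. 5.5 or 7.0) are dataset-specific and must be chosen by inspecting the value distribution (`expressionHistogram()`) and marker genes |
| `mode` (expression) | `"all"` | a gene must exceed the cutoff in all samples; `"any"` available |
| `alpha` | 0.05 | strict `p <` significance on raw hypergeometric p-values |

All q/cutoff comparisons are strict inequalities; boundary values
(q = 0.05, CPM = 1) never pass. The replicate threshold uses the
ceiling, so 80% of 10 runs means 8 runs exactly.

## Numerical and representational choices

* **Coordinates** are 0-based half-open internally; a summit at position
  $p$ extends to $[\max(0, p-f), p+f)$, which is exactly $2f$ wide
  (a closed ±200 interval would be 401 bp). Regions are clipped at the
  chromosome origin only; no sizes file is required.
* **Edge identity** is the unordered pair: A–B and B–A records collapse
  together with their multiplicities summed. Self-loops (homodimers) are
  stored and flagged but never traversed: they contribute nothing to
  target–query paths.
* **PWMs** are stored as given (counts or frequencies, rows fixed
  A,C,G,T) with no pseudocounts, because the package never scans
  sequence — matrices only need to be resolvable to genes. Cross-source
  motif id collisions are kept under `"<id>@<source>"` suffixes rather
  than overwritten, preserving provenance.
* **Ortholog mappings** expand one-to-many; the expression filter
  downstream corrects over-inclusion.
* **Hypergeometric tail** is the inclusive upper tail $P(X \ge k)$,
  via `phyper(k - 1, ..., lower.tail = FALSE)` — the off-by-one is
  handled in one place. No multiple-testing correction is applied by
  default (raw `p < 0.05` reporting, as is conventional for these
  phenotype scans); Benjamini–Hochberg is available via
  `adjust = "BH"`.
* **Jaccard of two empty edge sets** is defined as 0 with a warning so
  empty modules cannot inject NaN into a similarity matrix.
* **Clustering** runs complete linkage on Pearson distances
  $d = 1 - r$ between rows of the Jaccard matrix (diagonal included by
  default; `excludeDiagonal = TRUE` drops self-similarity). Labels are
  sorted before agglomeration so ties resolve deterministically. A
  constant similarity row has no defined correlation and raises an
  error naming the offending module.
* **TF-class OBO parsing**: each term's level is read from the standard
  `subset:` tag and gene-level terms carry `xref: EntrezGene:<id>`;
  factor-species (isoform) records are dropped before gene resolution,
  orphan terms are skipped with a warning, and a cyclic `is_a` chain is
  an error.

## What the synthetic generator emulates — and what it does not

`simulateStudy()` fabricates every input format the pipeline consumes:

* a random background PPI graph (Erdős–Rényi or Barabási–Albert) with a
  planted target–bridge–query component;
* replicate enrichment tables in which true motifs are enriched
  (q < 0.05) in at least 80% of runs *by construction* (failures are
  binomial at `noiseRate` but capped), while decoys always fail in more
  than 20% of runs;
* a match table, a motif→gene map, and an expression matrix whose
  expressed/background labels are drawn from well-separated modes
  (counts: Poisson(200)+1 vs 0, so CPM > 1 recovers labels exactly;
  log2 intensities: N(10,1) vs N(4,1), midpoint cutoff 7 recovers
  ≈ 99% of labels).

The planted component is deliberately generated **detached from the
background graph**. This makes the ground-truth module well defined —
the search provably returns exactly the planted nodes and edges — so
end-to-end recovery can be asserted as equality across hundreds of
seeds. The cost is realism: real modules are embedded in, not detached
from, the interactome, and real enrichment evidence is noisier and
correlated across motifs. Passing the recovery suite therefore
demonstrates the correctness of the plumbing and of the search
semantics, not the biological precision attainable on real data, which
depends on the quality of the PPI catalogue, the PWM library and the
expression cutoffs. One global seed fans out to fixed per-stage offsets,
so each stage is independently reproducible.

Problem sizes in the shipped test and acceptance suites were chosen as
the smallest that exercise all code paths convincingly: oracle
equivalence on 200+ random graphs of up to 30 nodes (where exhaustive
path enumeration is itself trustworthy), the full hypergeometric
enumeration for universes up to 12 genes, and 200 seeded end-to-end
pipeline runs on 30-gene backgrounds.

## Validation strategy

Three independent oracles back the implementation:

1. a brute-force module oracle that enumerates all simple paths up to
   the length bound per pair, keeps minimal ones, and induces the
   subgraph — no igraph path routine involved;
2. exhaustive subset enumeration for the hypergeometric tail;
3. a naive complete-linkage agglomerator compared through cophenetic
   matrices.

Printed per-gene phenotype tables of two published combined stem-cell
modules (embryonic: 13 of 77 proteins embryonic-lethal; hematopoietic:
22 of 96 with hematopoietic phenotypes) are shipped as transcribed
plain-text fixtures; the annotation-counting machinery reproduces those
overlap counts exactly. The headline module reconstructions themselves
are not reproducible at package scale — they require the original peak
sets, a specific 2013 interaction-database release and 2010-era PWM
sources — which is why validation rests on the worked examples and
property suites above.

## Known limitations

* Motif discovery and motif matching are consumed as result tables, not
  recomputed; their q-values are taken as final.
* No significance model for edge multiplicity or module overlap is
  provided (no accepted null model exists for either).
* The search is unweighted; confidence-weighted PPI networks would need
  a different path semantics.
* Gene identifiers are opaque strings; no live identifier validation or
  ortholog service is queried.
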