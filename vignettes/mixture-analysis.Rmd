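---
title: "Mixture interaction analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture interaction analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemmix)
options(chemmix.verbose = FALSE)
```

## The model

`chemmix` screens a mixture of 2–4 chemicals for potential interaction
endpoints using only chemical–protein interaction profiles and gene-set
annotation catalogs. The analysis is a pipeline of well-understood
pieces rather than a fitted model, so its assumptions are the
assumptions of those pieces:

1. **Target extraction.** A chemical's targets are the proteins linked
   to it with combined score at or above a confidence cutoff, mapped to
   gene symbols. The combined score (0–1000) is treated as an opaque
   confidence, not a binding affinity; the three named levels adopt the
   STITCH convention of 150 (low), 400 (medium) and 700 (high). Several
   proteins collapsing to one gene keep the maximum score, and duplicate
   link rows likewise collapse to the maximum — the conservative choice,
   since a pair is retained at a threshold whenever any of its
   attestations would be.
2. **Per-chemical enrichment.** Each namespace (GO, each pathway
   source, DO, DOLite, …) is tested separately: for every term, the
   one-sided hypergeometric upper tail `P(X >= k)` with the namespace's
   own gene universe as background, then Benjamini–Hochberg across all
   terms of that namespace, significance at adjusted p < `alpha`
   (default 0.05). Over-representation only — depletion is not a
   mixture-interaction signal in this design.
3. **Venn partitioning.** Target gene sets, and significant term-id
   sets per namespace, are partitioned into the `2^n - 1` disjoint
   membership regions. Every element appears in exactly one region;
   empty regions are materialized so downstream consumers see a fixed
   shape.
4. **Joint p-value.** A term significant for *every* chemical gets
   `p_j = prod_i p_i` over the per-chemical adjusted p-values, used to
   rank shared endpoints. It is a prioritization score, not a calibrated
   probability: the per-chemical tests share a background and target
   overlap, so independence does not hold and `p_j` should not be
   thresholded as if it were a p-value.
5. **Overall effect.** Enrichment of the union of all chemicals' target
   genes, labeling the mixture as one exposure.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `level` / threshold | `"high"` (≥ 700) | combined-score cutoff; integer overrides in \[0, 1000\] |
| `alpha` | 0.05 | BH-adjusted significance threshold, per namespace |
| chemicals | 2–4 | the supported mixture sizes; outside this range is a contract error |

The background universe for each namespace is **the union of that
catalog's term gene sets**, not a genome-wide list. This is
reproducible from the inputs alone and keeps each namespace
self-consistent; it does make `N` (and so the p-values) depend on
catalog coverage, which is the usual trade-off of catalog-derived
backgrounds.

## Design choices where the design was open

- **BH per chemical per namespace**, not jointly across namespaces.
  Namespaces differ vastly in term counts; a joint correction would let
  a large catalog dilute a small one. Per-namespace tracks also match
  how the outputs are organized (one enrichment table per namespace).
- **All catalog terms enter the BH family**, including terms with zero
  target overlap (their p is 1). Testing only overlapping terms would
  shrink `m` and make adjusted p-values depend on the target set in a
  way that is hard to reason about across chemicals.
- **Joint p-values only for the full intersection.** Terms significant
  for a strict subset of chemicals are reported in their Venn region
  without a joint p. Recomputing products over partial subsets would
  produce incomparable scores across regions.
- **Joint p accumulated in log10 space.** Products of many small
  adjusted p-values can pass below the double floor (≈1e-308); the
  log10 sum stays exact and the formatter reconstructs the
  mantissa/exponent from it, so a value like 1.00E-380 prints correctly
  even though the direct product is 0.
- **Exact-match chemical resolution.** Aliases (names and CAS numbers)
  are trimmed and case-folded, nothing more. Autocomplete and fuzzy
  matching are UI affordances, not analysis semantics; an ambiguous
  alias fails loudly listing the candidates rather than guessing.
- **Protein→gene mapping is one-to-one per protein** and a conflicting
  map is an input error. How the upstream databases collapse many-to-one
  cases is not observable from our inputs; refusing ambiguity is the
  only reproducible behavior.

## Numerical notes

- The hypergeometric tail is computed by the log-gamma-based survival
  function (`stats::phyper(k - 1, ..., lower.tail = FALSE)`), never by
  naive factorials; the test suite checks it against exhaustive
  enumeration of all draws for every parameter tuple with `N <= 12` to
  1e-12.
- BH is the textbook step-up written as a reverse cumulative minimum;
  the suite checks it against a literal `min over j >= i` oracle and
  against `stats::p.adjust`.
- Output ordering is fully deterministic: enrichment tables sort by
  (adjusted p, term id), shared terms by (log10 joint p, term id), Venn
  members lexicographically. Two runs on identical inputs produce
  byte-identical files.
- P-values print in 3-significant-figure scientific notation
  (`3.91E-10`); full-precision companions (17 significant digits, which
  round-trips a double exactly) are always written alongside, so no
  information is lost to formatting.
- Degenerate inputs: a chemical with zero targets after filtering stays
  in the mixture with empty outputs (its intersections are empty); a
  target set disjoint from a namespace's background yields an
  empty-records table flagged `no_testable_genes`, not an error.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` produces an internally consistent bundle: links
with scores in realistic bands (planted links uniform in \[700, 1000\]
so they survive every confidence level, filler uniform in \[150, 1000\]
so filtering is actually exercised), a 1:1 protein→gene map, alias
tables with names and CAS-style strings, and GMT catalogs sampled from
a synthetic gene universe. Ground truth (planted shared target genes
and planted co-enriched terms) is recorded in a manifest.

The reference configuration — seed 42, 200-gene universe, 20 terms of
8–15 genes per namespace, 30 link rows per chemical, 3 planted shared
targets, one term planted at fraction 1.0 — was chosen so that the
planted term's enrichment is unambiguous (all 8–15 of its genes among
≤ 30 targets against a ~150-gene effective background gives a raw p
many orders of magnitude below any BH threshold) while the whole bundle
stays small enough to regenerate in milliseconds. The namespaces are
two ("GO" and "DO") with the planted term in "DO", mirroring the
disease-term orientation of typical use; nothing downstream depends on
the labels.

What it does **not** emulate: the empirical STITCH score distribution
(real scores are heavily skewed low), correlated term memberships and
the GO DAG structure, many-to-one protein→gene collapses, organism
mixtures, or catalog sizes (real DO has thousands of terms). A green
planted-recovery test therefore establishes that the pipeline's
plumbing and statistics behave as specified on a known signal — it says
nothing about recovering any published case-study finding, which
depends on specific STITCH/GO/DO snapshots that are out of scope. Real
STITCH dumps are accepted unchanged.

## Known limitations

- The joint p-value inherits the dependence caveat above; it ranks, it
  does not test.
- Inhibition/activation action modes are not distinguished, so
  additive, synergistic and antagonistic effects cannot be separated.
- No dose–response component: presence above a confidence cutoff is
  the only notion of exposure strength.
- GO ancestor propagation and term–term redundancy reduction are not
  performed; a catalog is taken exactly as its GMT states it.
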