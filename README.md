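# chemmix

Shared-target and enrichment analysis for chemical mixtures.

## The problem

Humans are rarely exposed to one chemical at a time, yet most in-silico
toxicology works one chemical at a time. When 2–4 chemicals are taken
together, their *indirect* interactions — acting on the same proteins, or
perturbing the same functions, pathways and diseases — are early warning
signs of combined effects that no single-chemical analysis reveals.
`chemmix` screens for such potential interaction endpoints from
chemogenomics data: given a STITCH-shaped chemical–protein link table,
a protein→gene map and gene-set catalogs (GO, KEGG, Reactome, SMPDB,
DO, DOLite, … in GMT format), it identifies for each mixture

- the **shared interacting targets** (Venn-partitioned gene sets),
- the **co-enriched terms** per annotation namespace, with a product-form
  **joint p-value** prioritizing terms significant for every chemical,
- the **overall effect** of the mixture as one exposure (enrichment of
  the union of all target genes).

It is a library plus a small CLI, aimed at computational toxicologists
and drug-interaction researchers who have (or can download) STITCH-style
interaction dumps.

## The statistics

For one chemical, its target set is the genes whose proteins interact
with it at a chosen confidence (STITCH combined score ≥ 150/400/700 for
low/medium/high). Over-representation of a term with K member genes in a
background of N genes, given n targets in the background of which k hit
the term, is the hypergeometric upper tail

    p = P(X >= k),  X ~ Hypergeometric(N, K, n)

tested one-sidedly for every term of a namespace and corrected by the
Benjamini–Hochberg step-up procedure; terms with adjusted p < 0.05 are
called enriched. For a term enriched for *all* chemicals of the mixture,
the joint p-value is the product of the per-chemical adjusted p-values

    p_j = prod_i p_i

accumulated in log10 space so that products far below the double floor
(e.g. 1e-380) keep an exact representation. Smaller `p_j` = stronger
shared evidence.

## Worked example

Everything is testable offline through the seeded synthetic-data
generator, which writes a complete bundle (links, aliases, map, GMT
catalogs) with a known planted signal:

```r
library(chemmix)
cfg    <- fixture_config()                      # seed 42 reference fixture
bundle <- generate_fixture(cfg, tempfile())
data   <- read_fixture_bundle(bundle)
report <- analyze_mixture(c("chem01", "chem02"), data, level = "high")
print(report)
#> Mixture analysis of 2 chemicals at high confidence (alpha=0.05)
#>   CIDm00000001 (chem01): 19 target genes
#>   CIDm00000002 (chem02): 22 target genes
#>   shared target genes: 16
#>   namespace GO: 0 shared significant term(s)
#>   namespace DO: 1 shared significant term(s)
print(report$shared$DO$joint[[1]])
#> Joint p-value for DO:0010: 7.25E-28 (log10 = -27.1395) from 2 chemicals
```

The 16 shared genes are the 3 planted shared targets plus the 14 genes
of the planted disease term (one gene belongs to both groups); that
term (here `DO:0010`) is
enriched for both chemicals, so it is the one shared significant DO term
and its joint p-value is the product of the two adjusted p-values.
Combining published per-chemical adjusted p-values works the same way:

```r
format_pvalue(joint_pvalue(c(rifampin = 4.32e-8, efavirenz = 0.00906))$joint_p)
#> [1] "3.91E-10"
```

`write_report(report, "out/")` serializes everything deterministically:
per-chemical target detail and enrichment CSVs, `venn_regions.json`,
per-namespace `shared_terms_*.csv` (per-chemical adjusted p-values plus
the joint p-value) and `overall_*.csv` for the union-based effect.

## Command line

```sh
Rscript inst/cli/chemmix.R analyze \
  --chemicals chem01,chem02 --level high \
  --links links.tsv --aliases aliases.tsv --map protein_gene_map.tsv \
  --gmt GO=GO.gmt --gmt DO=DO.gmt --out out/
Rscript inst/cli/chemmix.R fixture --out bundle/ --seed 42
Rscript inst/cli/chemmix.R selfcheck --seed 42
```

Chemicals are queried by name or CAS number (exact, case-insensitive
match); `--threshold 650` overrides `--level` with an explicit score
cutoff. Exit codes distinguish usage/contract errors (2), chemical
resolution failures (3) and file-format/I-O errors (4).

## Scope

No database downloads, no dose–response modeling, no
additive/synergistic/antagonistic classification, no web UI; real STITCH
dumps are accepted unchanged if you supply them. See
`vignettes/mixture-analysis.Rmd` for the model, parameter choices and
limitations.
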