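# locuspacket

Standardized per-locus evidence packets for GWAS candidate gene
prioritization.

## The problem

Genome-wide association studies implicate loci, not genes. In
model-organism genetic reference populations (e.g. the Collaborative
Cross, a murine panel descended from 8 founder strains) mapping
resolution is low enough that a single significant locus routinely spans
tens of megabases and contains dozens to hundreds of genes. Moving from
"chr3:131–150 Mb is associated with cardiac function" to "*which* gene
drives it" means collating, for every gene in the interval, evidence of
very different kinds: study-specific results (differential expression
between conditions, *cis*-eQTLs, coding variants segregating in the
panel) and public annotation (knockout phenotypes, human disease
associations, fine-mapped molecular-QTL credible sets). Done by hand,
this is slow and inconsistent across loci, which makes side-by-side
comparison and team review unreliable.

`locuspacket` standardizes the whole path. For each locus it assembles a
"packet": a merged per-gene evidence sheet, screening results, and
figures, identically structured across loci so a team can review them in
parallel.

## The model

Candidate screening separates two kinds of boolean criteria over the
merged gene sheet:

- **Required** criteria every candidate must meet — typically
  *protein-coding*, *has a human ortholog*, and *expressed above 5 cpm
  in the validation cell type*. A gene passes the screen iff the
  conjunction of all required criteria is true.
- **Supportive** criteria that accumulate evidence — differential
  expression (`de.padj < 0.05`), a *cis*-eQTL record, a protein-altering
  variant, a prior gene–trait link mined from annotation services. Per
  gene, the count of satisfied supportive criteria and the exact set of
  satisfied criteria (the UpSet class) drive prioritization; very few
  genes show evidence of every kind.

Criteria are written in a small, closed boolean expression language
(comparisons, `& | !`, `is_missing()`, `contains()`, `abs()`) evaluated
with three-valued logic: a comparison against a missing value is
missing, and a missing final value is *false* — absent evidence is unmet
evidence, unless the criterion asks about missingness itself. The
language cannot call into R, so criteria files are safe to share and
re-run.

Around that core: build-tagged 1-based closed intervals with
transitive-overlap locus merging (`merge_loci`, bounded gap
configurable), identifier harmonization (symbol ↔ Ensembl ↔ human
ortholog, with explicit ambiguity), namespaced evidence layers attached
by left join from any table with a linkable column (gene symbol, Ensembl
ID, or coordinates — auto-detected), per-gene duplicate reduction with
declared policies (p-value-like columns take the minimum), offline-first
clients for Open Targets-style and InterMine-style services behind a
content-addressed request cache, and locus-zoom / UpSet figures.

## Worked example

The built-in synthetic study profile generates every input the pipeline
consumes — annotation, overlapping QTL regions, an IdMap, three
evidence layers with different link keys, recorded service payloads —
with planted ground truth:

```r
library(locuspacket)

prof <- fixture_profile(file.path(tempdir(), "study"), "mini", seed = 1)
project <- init_project(
  file.path(tempdir(), "cc_project"), prof$regions, mode = "region",
  build = genome_build("mm39", "Mus musculus"),
  annotation = prof$annotation, idmap = prof$idmap)

project$loci[, c("locus_id", "chrom", "start", "end", "source_count")]
#> # A tibble: 3 × 5
#>   locus_id             chrom   start     end source_count
#>   <chr>                <chr>   <dbl>   <dbl>        <int>
#> 1 locus_chr1_0.35_1.26 chr1   349393 1258679            2
#> 2 locus_chr2_0.2_0.82  chr2   200996  824951            1
#> 3 locus_chr2_1.34_1.64 chr2  1341437 1635217            1
```

Four input regions merged to three distinct loci (`source_count` 2 means
two overlapping trait intervals fused). Attach evidence and screen:

```r
project <- attach_layer(project, prof$layers$de, "de")        # by symbol
project <- attach_layer(project, prof$layers$eqtl, "eqtl")    # by Ensembl ID
project <- attach_layer(project, prof$layers$variants, "variant")  # by overlap

criteria <- list(
  criterion("protein_coding", 'biotype == "protein_coding"', "required"),
  criterion("has_human_ortholog", "!is_missing(human_ortholog)", "required"),
  criterion("expressed", "expression_cpm > 5", "required"),
  criterion("DE", "de.padj < 0.05", "supportive"),
  criterion("cis_eQTL", "!is_missing(eqtl.pval)", "supportive"),
  criterion("CC_variant", "!is_missing(variant.consequence)", "supportive"))

sheets <- make_gene_sheet(project, criteria)
summarize_counts(sheets$result)
#> <summary> 10 of 30 genes pass required criteria (33%)
#> # A tibble: 6 × 4
#>   name               kind       n_true   pct
#>   <chr>              <chr>       <int> <int>
#> 1 protein_coding     required       23    77
#> 2 has_human_ortholog required       21    70
#> 3 expressed          required       17    57
#> 4 DE                 supportive      5    17
#> 5 cis_eQTL           supportive      4    13
#> 6 CC_variant         supportive      4    13
```

Of the 30 gene×locus rows, 10 pass all three required criteria; the
per-criterion counts show how restrictive each screen is. The
evidence-overlap partition of the screened genes (what the UpSet figure
draws — each gene falls in exactly one class, its exact set of satisfied
supportive criteria):

```r
overlap_counts(sheets$result)[, c("key", "count")]
#> # A tibble: 7 × 2
#>   key                      count
#>   <chr>                    <int>
#> 1 ""                           2
#> 2 "CC_variant"                 2
#> 3 "DE&cis_eQTL"                2
#> 4 "cis_eQTL"                   1
#> 5 "DE"                         1
#> 6 "DE&CC_variant"              1
#> 7 "DE&cis_eQTL&CC_variant"     1
```

One gene shows all three evidence types — the kind of convergence that
nominates a candidate for validation. `build_packet(project, locus_id,
sheets)` then writes the per-locus bundle: a multi-sheet workbook
(Summary, Complete, custom subsets, MouseMine, OpenTargets), one CSV per
sheet, the UpSet figure, and — when a scan is attached with
`set_scan()` — a locus-zoom figure with association, founder
haplotype-effect, and gene tracks.

The same workflow is scriptable from a shell via `exec/locuspacket`
(`init`, `add`, `mine`, `sheet`, `packet`, `plot`, `fixtures`).

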