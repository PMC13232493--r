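---
title: "Methods: evidence aggregation and screening in locuspacket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence aggregation and screening in locuspacket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locuspacket)
```

# Scope and model

`locuspacket` operationalizes a simple observation about locus-to-gene
work in genetic reference populations: the statistics end at the locus,
and what follows is evidence bookkeeping. The package therefore computes
no association statistics. It takes mapped QTL intervals (or a gene
list) as given, and its contribution is a disciplined pipeline from
intervals to reviewable, identically structured per-locus packets:

1. **Geometry.** Intervals are 1-based and closed on both ends, the
   convention of GWAS tables and GTF annotation; BED-style half-open
   input must be shifted (+1 on starts) at read time. Every
   coordinate-bearing object is tagged with a genome build, and any
   operation combining two objects fails loudly on a build mismatch —
   the one error in this workflow that otherwise fails silently and
   completely.
2. **Membership.** A gene belongs to a locus if its gene body shares at
   least one base pair with the locus interval, strand-agnostic.
   Any-overlap is the inclusive choice, appropriate for a *screen* whose
   false positives are cheap (one extra row to review) and whose false
   negatives are invisible.
3. **Evidence.** Every evidence source — internal DE results, eQTL
   calls, variant tables, mined annotation — becomes a *layer*: reduced
   to one row per gene, its columns prefixed with the layer name, and
   left-joined onto the gene sheet. The left join is a contract: layers
   never add or remove sheet rows, and absent evidence stays visible as
   missingness, because the screening semantics depend on it.
4. **Screening.** Boolean criteria over the merged sheet, split into
   *required* (conjunctive hard screen) and *supportive* (counted
   evidence). The partition of screened genes by their exact set of
   satisfied supportive criteria is the package's central summary — the
   UpSet classes are disjoint and conserve the screened total, which is
   asserted on every call.

# The criteria language

Criteria are parsed by a closed recursive-descent grammar: column
identifiers (dots allowed), numeric/string/boolean literals,
`== != < <= > >= & | !` with C-like precedence, parentheses, and exactly
three functions (`is_missing`, `contains`, `abs`). Accepting arbitrary
host-language expressions would have been more flexible and strictly
worse: criteria files travel with projects, and evaluating them must not
be able to execute code. The grammar covers every criterion the screen
model needs (thresholds, equality, missingness tests, boolean
composition); anything fancier belongs in a precomputed layer column.

Evaluation is three-valued (Kleene): comparisons touching a missing
value are missing, `&`/`|` resolve whenever one operand decides the
outcome, and `!` propagates missingness. The *final* value of a
criterion coerces missing to `FALSE`: a gene with no eQTL record does
not satisfy "has an eQTL", and `is_missing()` exists for the cases where
missingness itself is the question. Type errors (ordering a text column,
comparing text to a number) are errors naming the column and operator,
never silent coercions.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `max_gap` (`merge_loci`) | 0 | bp | Merge only genuinely overlapping intervals; positive values merge across gaps `start2 − end1 ≤ max_gap`. No principled panel-independent gap exists, so it is exposed rather than guessed. |
| Ensembl-pattern threshold (`detect_link_key`) | 90% of non-missing values | — | Tolerates sporadic dirty cells without misclassifying genuinely mixed columns. |
| Duplicate reducers | p-value-like → `min`, numeric → `max`, logical → `any`, text → sorted distinct concat | — | The conservative aggregate when one gene has several eQTL/variant records; fully overridable per column. |
| `min_l2g` (`query_qtl`) | 0.5 | probability | "High confidence" locus-to-gene assignment has no canonical cutoff; 0.5 keeps assignments more likely right than wrong. Set 0 to keep everything. |
| Expression screen | `expression_cpm > 5` (a criterion, not code) | cpm | Conventional robust-expression threshold in the validation cell type; changing it is editing one criterion line. |
| Retry policy (live mining) | 3 attempts, exponential backoff 0.5 s base | — | Politeness floor for public APIs; never exercised offline. |

# Mining and the cache

All mining is *offline-first*: each request is content-addressed (md5 of
the canonicalized endpoint + body, parameter order irrelevant), answered
from the cache when present, and an explicit error when absent in
offline mode. Live fetches write through the cache, so any analysis can
be re-run later, byte-identically, with no network. The query functions
are pure functions of cached payloads; pagination is drained fully and
deduplicated. The association score returned by the disease endpoint is
stored verbatim — the package does not reinterpret it — and trait
filtering is a two-pass reading (an `explicit` pass for the study's
phenotype, a broader `related` pass) over case-insensitive patterns,
leaving the unfiltered table intact.

# Numerical and formatting choices

- **Percentages** are integers computed by round-half-away-from-zero
  (`percent_of`): 28.57% prints as 29%, 44.2% as 44%. Banker's rounding
  would agree on these but not at exact halves; one rule is fixed and
  documented. Zero denominators yield `NA`, never errors.
- **Locus widths** are `(end − start) / 1e6` to one decimal — the
  span convention of quoted GWAS intervals (131–150 Mb "spans 19 Mb");
  a point interval has width 0.
- **Locus slugs** are `locus_{chrom}_{startMb}_{endMb}` (Mb to ≤2
  decimals, trailing zeros trimmed), with deterministic numeric suffixes
  on collision, so packet files sort and diff across runs.
- **Sheet names** are capped at 31 characters (workbook limit) with
  deterministic numeric suffixes on post-truncation collisions.
- **Determinism.** Reduction output order follows first appearance;
  merged loci and query results are sorted on explicit keys; re-running
  any step on identical inputs rewrites byte-identical CSVs (workbook
  metadata excluded). CSV is the canonical output; the workbook renders
  the same tables (via an openpyxl helper when a suitable `python` is
  available) and is compared cell-for-cell in tests.
- **Degenerate inputs.** Empty region tables, empty evidence tables
  (columns attach, all missing), loci containing no genes, criteria
  sets that screen out everything, and empty mined results (sheets emit
  headers only) are all defined, tested states rather than errors.

# Open design points, and how they were decided

- **Gene×locus rows.** A gene overlapping two disjoint loci appears
  once per locus, and overlap counts tally gene×locus rows: each
  packet must be self-contained for review, and the same gene can be a
  candidate twice for different traits.
- **"Obvious human ortholog"** is not inferred; it is the presence of a
  non-empty ortholog field supplied by the user's IdMap, which makes the
  ortholog screen an ordinary criterion expression rather than
  special-cased code.
- **Ambiguous aliases** (one alias naming two genes) are surfaced as
  `ambiguous`, never auto-resolved — a silent misassignment would
  corrupt every downstream join. Identifier conflicts between an
  annotation and the IdMap keep the annotation's value and report the
  conflict.
- **Evidence fan-out.** A coordinate-linked evidence row spanning two
  genes is duplicated to both: the packet is gene-centric, and the
  variant is genuinely evidence for each.
- **Summary sheet contents**: provenance (build, versions, timestamps),
  screen counts, layer list, and the full criteria definitions — enough
  to re-derive the packet without the project object.

# The synthetic-data generator

The fixture profile emulates the *shape* of a reference-population GWAS
study — a mm39-like gene annotation with controlled biotype/ortholog/
expression composition, overlapping multi-trait QTL regions that merge,
three evidence layers deliberately linked by different keys (symbol,
Ensembl ID, coordinates), recorded service payloads including paginated
and empty cases, a scan with planted peaks and 8 founder haplotype
effects under two conditions. Everything is planted, not simulated:
exactly the chosen genes satisfy each criterion, and the manifest
records the resulting truth (merged intervals, membership, screened
sets, overlap classes) computed from the construction itself.

That is also its limitation. The generator has no linkage
disequilibrium, no genotypes, no correlated evidence, no noisy
identifiers beyond the planted alias collision, and non-overlapping
genes by default. Passing the end-to-end suite therefore demonstrates
that the *bookkeeping* is exact — counts, joins, screens, and outputs
are recovered perfectly and reproducibly — not that any biological
inference is valid on real data, where evidence quality, annotation
completeness, and build mismatches dominate. The test and acceptance
runs use the `mini` profile (2 chromosomes, 60 genes, 3 merged loci) so
the whole suite stays fast; `cc_like` reproduces the larger study shape
(10 chromosomes, 20 merged loci) for demonstration.

# Known limitations

- No coordinate conversion: inputs on another build must be lifted over
  before attaching; the build check makes the failure explicit.
- No Mendelian randomization or colocalization computation; externally
  computed results attach as ordinary layers.
- No LD-aware locus definition and no LD panel in the locus-zoom figure
  (none exists for the reference-population use case).
- Bulk-tissue evidence layers can obscure cell-type-specific effects;
  single-cell QTL types are retrievable (`sceqtl`, `scpqtl`) but their
  interpretation is left to the analyst.
- The final step of prioritization is deliberately manual: the package
  ranks nothing and weights nothing, it arranges the evidence so that a
  team can.
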