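---
title: "Measuring and validating prokaryotic genome annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and validating prokaryotic genome annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoqc)
```

## The problem

An archived genome record is a snapshot: once deposited, its annotation is
rarely updated, and errors propagate into every downstream analysis that
treats complete genomes as references. Annotation quality is not directly
observable, but it leaves quantitative traces. A genome annotated with an
aggressive ORF caller shows inflated coding density, a surplus of short
proteins and a depressed average protein length; a pipeline that never
assigns function leaves every product as "hypothetical protein"; a
submission prepared without validation may carry translated products on
pseudogenes, missing ribosomal RNAs, or duplicated locus_tags. `annoqc`
operationalizes these traces as a measure vector, a rule engine and a
checklist, so that a genome can be assessed before submission and cohorts
of genomes can be compared afterwards.

## The measure vector

For one genome record the package computes: replicon count, total length
(Mbp), pooled GC% (ambiguity codes excluded from numerator and
denominator), protein count, RNA count, the set and count of amino acids
covered by functional tRNAs, hypothetical-protein count, coding density,
average and minimum protein length, percent short proteins and percent
standard start codons.

Conventions that matter and are easy to get wrong:

* **Proteins** are CDS features without `/pseudo` (or a valued
  `/pseudogene` synonym). CDS carrying `/exception` or
  `/artificial_location` *do* count: both strategies yield real protein
  products.
* **Protein length** comes from the archived `/translation` when present
  — the archived record is authoritative — else from span arithmetic,
  `span/3 − 1` (the stop codon excluded; no `− 1` for 3'-partial CDS).
  Disagreement between the two is a lint finding (`STRUCT002`), never a
  silent correction.
* **Coding density** is proteins per kbp of genome. Report values are
  rounded half-away-from-zero to 2 decimals (so 182 proteins / 160 kbp
  prints 1.14), with raw values retained for arithmetic; the identity
  `raw_density × kbp = protein_count` holds exactly pre-rounding.
* **Standard starts** are judged on the first strand-aware codon of each
  non-pseudo CDS with a complete 5' end; 5'-partial CDS are excluded from
  both numerator and denominator. ATG counts; GTG/TTG do not, although
  they translate to M.
* **RNA count** covers tRNA, rRNA, ncRNA and tmRNA feature keys —
  transfer, ribosomal and non-coding RNAs. `misc_RNA` and `precursor_RNA`
  are excluded by default (configurable), as they denote products rather
  than additional genes.
* **tRNA coverage** parses `tRNA-Xxx` product tokens. Recognized tokens
  are the 20 standard amino acids plus Sec, Pyl, fMet, Ile2 and OTHER;
  completeness is always judged on the standard 20, so a
  selenocysteine tRNA raises the count to 21 without masking a missing
  tryptophan tRNA. Which nonstandard tokens an archive counts in its own
  reports is not documentable from outside, so the token list is
  configuration. Pseudo-tRNAs are tallied separately and never satisfy
  coverage.
* **Hypothetical proteins** are counted by normalized product name
  (case-folded, whitespace-collapsed) against a configurable set that
  deliberately includes the deprecated synonyms ("conserved hypothetical
  protein", "protein of unknown function", ...), so that pre-standard
  records are measurable; a CDS without any `/product` counts as
  hypothetical with a warning.

## Minimal standards and the rule engine

The compliance checklist asks: rRNAs (≥ 1 each of 5S, 16S, 23S,
classified from product names with subunit synonyms), tRNAs for all 20
amino acids, protein genes at expected density and not all unnamed, core
conserved functions present, locus_tags valid, pseudogene formats
respected, and the feature table structurally sound. Check outcomes are
PASS / WARN / FAIL / EXEMPT; findings carry a severity with a fixed
meaning: **ERROR** violates an archive prohibition (the record is
unsubmittable — e.g. a translated product on a `/pseudo` feature),
**FAIL** violates an accepted standard, **WARN** is outside guideline,
**INFO** is advisory. A genome is COMPLIANT iff no check FAILs and no
ERROR finding exists.

Thresholds, all in `qc_config()`:

| parameter | default | rationale |
|---|---|---|
| `short_protein_aa` | 150 aa | the conventional short-protein cutoff used in annotation reports |
| `density_lo`, `density_hi` | 0.5, 1.25 /kbp | brackets the extremes seen in real complete genomes (0.49 in a degraded intracellular pathogen; 1.19 in a dense neisserial genome) with margin; WARN not FAIL, because real biology produces both ends |
| `hypothetical_fail` | 0.95 | a ratio at or near 1 means no functional annotation at all, below minimal standards |
| `hypothetical_warn` | 0.8 | early warning short of failure |
| `z_threshold` | 3.0 | conventional outlier bound on scaled measures |

"Expected density" has no published numeric definition, so the band is an
explicit configurable surrogate, and the density check can only WARN.

Protein naming implements the accepted two-name rule: for proteins of
unknown function only "hypothetical protein" and "uncharacterized
protein" are acceptable, and the older synonyms are FAIL findings with a
suggested replacement. Style checks beyond that rule (whitespace, case,
"homolog"/"fragment" qualifiers, identifier-as-name) exist but default
off, since only the two-name rule is mandated.

Structured evidence follows the `/inference` grammar `category: type
[(same species)]:source:version[:source:version...]` with the type
vocabulary non-experimental / similar to (AA|DNA|RNA) sequence / profile /
ab initio prediction / alignment, and the `/experiment` form `category:
free text [PMID:nnn | doi:...]`. Parsing is total: unknown tokens become
findings, never crashes, and `render(parse(x))` is the canonical form of
`x`.

Pseudogene strategies: the non-negotiable rule is that no translated
product may derive from a feature labeled `/pseudo` (ERROR). A `/pseudo`
CDS should carry its product name in `/note`, not `/product` (WARN).
Frameshifts rescued by the "annotated by transcript or proteomic data"
exception must carry `/experiment` or `/inference` (FAIL otherwise);
`/artificial_location` products must be prefaced "LOW-QUALITY PROTEIN:"
(WARN otherwise); similarity-region `misc_feature`s carry neither gene nor
locus_tag (INFO). The proposal to split `/pseudo` into `/pseudogene` +
`/nonfunctional` is still pending at the archives; a valued `/pseudogene`
qualifier is accepted as a synonym with an INFO note. The "potential
pseudogene recorded only in a free-text note" strategy is by construction
untrackable and is documented here rather than linted.

Exceptions: genomes that genuinely cannot meet a standard (tRNA loss by
codon recoding in reduced endosymbiont genomes, assembly gaps spanning an
rRNA) are handled by a documented-exception note, `annotation-exception:
<CHECK_ID>: <free text>`, in a `/note` or structured-comment line. The
syntax is this package's own — the requirement for documented exceptions
is standard, the wire format is not — chosen to be explicit and greppable.
An exception flips a FAIL on the named check to EXEMPT and the genome to
COMPLIANT_WITH_EXEMPTIONS.

### The core-function catalog

A small set of functions is expected in essentially every prokaryotic
genome; the functions most often missed by annotation pipelines are short
ribosomal proteins. The shipped catalog holds the 12 functional groups
that were historically restored to reference genome copies (42 added
features in total, recorded per function), with expected average lengths
and spreads; matched proteins outside ±4 spreads are reported as INFO.
The full curated core set (on the order of 61 functions / 191 protein
clusters) was never published as a table, so it cannot be shipped
honestly; the catalog is therefore user-replaceable (a TSV with name
patterns), and a non-normative extension (more ribosomal proteins, tRNA
ligases) can be appended with `load_core_catalog(extended = TRUE)`.
Matching is by case-insensitive product-name pattern — a deliberate
limitation; a hook for user-supplied similarity-based hits is the
catalog-replacement path.

## Cross-genome comparison

`scale_columns()` centres each measure and divides by the sample (n−1)
standard deviation — the usual statistical convention; the choice is
asserted in tests since either denominator is defensible. Missing values
are ignored in moments and left missing (pairwise-complete handling).
`fit_line()` is ordinary least squares with R² = 1 − SSres/SStot and a
two-sided zero-slope t-test on n−2 df; its test oracle solves the normal
equations and computes the p-value from the incomplete-beta closed form,
so the library route and the closed form check each other. PCA fixes
signs so each component's largest-magnitude loading is nonnegative.
Clustering is agglomerative, Euclidean, average linkage; ties break
deterministically by input order. Outliers are |z| > 3 cells, reported
per genome — the pattern of one strain skewed against its cohort.

## The synthetic-data model

`generate_genome()` emulates an annotated prokaryotic replicon: CDS with
lengths drawn once from a truncated normal (default mean 300 aa, sd 80,
min 50 — typical bacterial protein-length scale), built backwards from
the amino-acid length as start codon + sense codons + stop; exact-count
assignment of hypothetical names, ATG starts and evidence qualifiers
(counts, not expectations, so truth equality is sharp rather than
statistical); gene companions and sequential locus_tags; tRNA/rRNA
complements by subset; the pseudogene strategy cases in clean form; and
intergenic filler whose G/C bases are assigned exactly to realize the
target GC, with the realized value recorded as truth. Each planted rule
violation is introduced exactly once. The same seed yields byte-identical
GenBank output.

What it does **not** emulate: operons and realistic gene spacing, codon
usage and amino-acid composition, overlapping genes, mobile elements,
biologically plausible RNA sequences (RNA features carry random
placeholder sequence of realistic length), or any phylogenetic structure
across genomes. Passing the generator-truth tests therefore demonstrates
that the measures and rules compute what they claim on records whose
truth is known — not that real archives are error-free or that the
thresholds are optimal for any particular clade.

Default study-condition sizes used in the tests and the acceptance
script: genomes of 30–80 kbp with 8–40 proteins, 50 seeded specs for
generator-truth equivalence, cohorts of ~6–40 points for the comparison
statistics. These are the package's chosen problem sizes: small enough to
regenerate from scratch everywhere, large enough that every count and
ratio is exercised away from degenerate values.

## Numerical and representational choices

* Internal coordinates are 0-based half-open; GenBank/GFF3/tbl convert at
  the boundary (1-based inclusive). The conversion is an involution and
  is tested as such.
* Origin-spanning locations are multi-segment joins whose first segment
  starts after the last ends; they are legal only on circular replicons.
* Report rounding is half-away-from-zero (R's `round()` is half-to-even,
  which would print 1.1375 as 1.14 only by accident of floating point).
* Translation uses NCBI table 11 by default, overridden by
  `/transl_table`; alternative initiation codons render M unless the CDS
  is 5'-partial; codons containing ambiguity letters give X; internal
  stops raise a typed condition carrying the codon index.
* Unknown feature keys and qualifiers are preserved verbatim and flagged
  INFO — a validator must not destroy the evidence it is judging.
* Duplicate locus_tags are judged per feature key, because a gene and its
  CDS legitimately share one tag.
* `evaluate()` is pure: same record and configuration, same report;
  reports embed the tool version and a configuration hash.

## Known limitations

GenBank parsing covers the flat-file subset the package writes plus the
common location forms; ASN.1 and the EMBL dialect are out of scope. Core
functions are detected by name only. Whether archive report tables count
`/exception` CDS as proteins is not documentable from outside; this
package counts them and says so. Cohort-scale reference results (the
thousand-genome regressions and heatmaps) depend on a specific archive
snapshot and are represented here by the property-based guarantees on
synthetic cohorts instead.
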