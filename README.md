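# annoqc — quality control for annotated prokaryotic genome records

Complete prokaryotic genomes serve as gold-standard references, but their
annotations vary widely in quality: missing ribosomal or transfer RNAs,
genomes where every protein is "hypothetical protein", pseudogenes carrying
forbidden translated products, inconsistent protein names, and unregistered
or duplicated locus_tags. `annoqc` measures and lints annotated genome
records against the community minimal annotation standards and the INSDC
feature-table conventions, and compares cohorts of genomes to spot strains
with skewed annotation.

The package has four layers:

1. **Record model and I/O** — GenBank flat files, GFF3 (+FASTA) and the
   INSDC 5-column feature table, with strand- and join-aware sequence
   extraction and translation under NCBI genetic-code table 11.
2. **Annotation-report measures** — per genome: replicon count, length,
   GC%, protein and RNA counts, amino acids covered by tRNAs, hypothetical
   protein count, coding density (proteins per kbp), average/minimum
   protein length, percent short proteins (< 150 aa) and percent standard
   (ATG) start codons.
3. **Minimal standards and lint** — a complete genome must carry at least
   one each of the 5S/16S/23S rRNAs, tRNAs for all 20 standard amino
   acids, protein-coding genes at expected density with the core conserved
   functions annotated, valid locus_tags, and pseudogenes in the accepted
   formats (no translated product on a `/pseudo` feature). ~30 registered
   rules produce findings on a fixed ERROR/FAIL/WARN/INFO scale, and a
   compliance report aggregates them with support for documented
   exceptions (`annotation-exception: <CHECK_ID>: <reason>`).
4. **Cross-genome comparison** — genome-by-measure matrices, z-score
   column scaling ((x − mean)/sd, sample sd), per-measure OLS regression
   against genome length with R² and two-sided p-values on n−2 df, PCA,
   average-linkage hierarchical clustering, and |z| > 3 outlier flagging.

A deterministic synthetic-genome generator (`genome_spec()`,
`generate_genome()`) produces annotated records with exactly known truth —
counts are constructed, not sampled — so every measure, rule and check is
testable without downloads; `gold_standard()` is a fully compliant fixture
and `case_fixture(rule_id)` violates exactly one rule.

## Worked example

```r
library(annoqc)

# coding density as reported: 4144 proteins over a 4640-kbp genome
coding_density(4144, 4640)
#> [1] 0.89

# a synthetic genome with known truth
g <- generate_genome(genome_spec(seed = 7, n_proteins = 25,
                                 hypothetical_fraction = 0.2))
compute_metrics(g$record)
#> <metrics_row> Synthetica exempli
#>   replicon_count           1
#>   total_length_mbp         0.060
#>   gc_percent               50.00
#>   protein_count            25
#>   rna_count                23
#>   trna_aa_count            20
#>   hypothetical_count       5
#>   coding_density           0.42
#>   avg_protein_len_aa       337
#>   min_protein_len_aa       189
#>   short_protein_percent    0.00
#>   standard_start_percent   92.00
```

The 25 proteins, 5 hypothetical names (the requested 20%), 20 tRNA amino
acids and 92% ATG starts are all constructed values the generator recorded
as truth. Validation of a fixture that puts a `/translation` on a
pseudogene — which the archives prohibit — yields:

```r
rep <- evaluate(case_fixture("PSEUDO001"))
rep$overall
#> [1] "NONCOMPLIANT"
print(rep$findings)
#> 1 finding(s):
#>   [ERROR] PSEUDO001 CDS 27841..28203 [SYN_0024]: pseudogene carries a
#>           translated product (/translation or /protein_id)
```

From a shell, the thin front end in `inst/exec/annoqc` exposes `report`,
`validate` (exit code 0/1/2 = compliant / with exemptions / noncompliant),
`compare` and `generate` subcommands over the same functions.

## Documentation

The methods vignette (`vignettes/annotation-qc.Rmd`) describes the
measures, every rule and threshold with its default and rationale, the
synthetic-data model and its limitations, and the numerical conventions
(rounding, coordinate systems, tie-breaking).
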