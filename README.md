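# sorfkit

Short open reading frames (sORFs, conventionally ≤ 100 encoded amino acids)
are catalogued by many resources — computational predictions, Ribo-seq
re-analyses, mass-spectrometry studies — each with its own genome build,
column layout, length conventions and class vocabulary, and with massive
redundancy between them. `sorfkit` is for anyone who needs those catalogs as
*one* dataset: it harmonizes heterogeneous per-source sORF tables into a
non-redundant repository in which every unique ORF carries uniform
coordinates, an experiment count (how many original entries described it),
transcript associations with relative coordinates, a normalized class
(uORF, dORF, overlapping, CDS-internal, ncRNA/NMD/NSD, intergenic) and a
Kozak-context call — plus the gene-set statistics to ask questions such as
"are ATF4 targets enriched in uORF-harboring genes?".

## The pipeline

1. **Ingest + QC** — per-source column dialects map any delimited catalog
   onto a common record table; each source's reported lengths are checked
   against the theoretical length (genomic span minus introns,
   `|start − stop| + 1 − Σ introns`); sources mismatching on > 95 % of
   comparable entries are rejected.
2. **Liftover** — every coordinate is remapped through a UCSC chain file;
   a record fails on unmapped coordinates, inconsistent strands, a changed
   chromosome, or a changed start–stop distance (checked in that order),
   and failures are dropped and tallied.
3. **Two-phase merge** — records sharing all six identity features
   (chromosome, strand, start, stop, splicing status, splice blocks)
   collapse into unique ORFs with `experiment_count` = group size; records
   with partial identity (chromosome + two of strand/start/stop) are
   absorbed by the best matching unique ORF or dropped.
4. **Annotation** — transcript models from a local GTF + genome FASTA give
   relative coordinates, per-transcript classes and Kozak categories
   (optimal `gccRccATGG`, strong −3 purine & +4 G, moderate, weak;
   "Kozak-alike" for non-ATG starts).
5. **Export** — repository CSV, BED12, FASTA (nucleotide/peptide), QC
   report, merge audit, stats summary.

For gene-list enrichment, with a universe of `N` genes, `K` of them
uORF-harboring, a list of `n` with intersection `k`:

    p = P(X ≥ k),  X ~ Hypergeometric(N, K, n)        (upper tail, log scale)
    OR = k (N − n − K + k) / ((n − k) (K − k))        (sample odds ratio)

with Benjamini–Hochberg adjustment across lists.

## Worked example

```r
library(sorfkit)
library(dplyr)

fx <- make_genome_annotation(tempfile("fixture"), seed = 1)
cats <- make_catalogs(fx, seed = 1, n_sources = 3, redundancy = 2,
                      shift_sources = 2)   # source 2 sits on a shifted build
cfg <- sorf_pipeline_config(
  sources = mutate(cats$catalogs, dialect = unname(cats$dialects[source_id])),
  gtf_path = fx$gtf_path, genome_path = fx$genome_path,
  out_dir = tempfile("repo"), cell_type_mapping = fx$cell_type_mapping
)
res <- run_sorf_pipeline(cfg)
res
#> <sorf_pipeline: 12 unique ORFs from 24 records (3 sources)>
#>   dropped: 0 source-QC, 0 liftover, 0 partial-merge
```

Each of the 12 planted ORFs was reported by 2 sources (one on another
genome build, lifted back through its chain file), merged to a single entry
with `experiment_count` 2:

```r
tidy(res) %>%
  select(orf_id, chrom, strand, start_pos, stop_pos, splicing,
         experiment_count, kozak_category) %>% head(5)
#> # A tibble: 5 × 8
#>   orf_id     chrom strand start_pos stop_pos splicing  experiment_count
#> 1 ORF0000001 chr1  +           1258     1293 unspliced                2
#> 2 ORF0000002 chr1  +            231      266 unspliced                2
#> 3 ORF0000003 chr1  +           2481     2516 unspliced                2
#> 4 ORF0000004 chr1  +           2931     3066 spliced                  2
#> 5 ORF0000005 chr1  -           4320     4285 unspliced                2
```

Note the transcription-orientation convention: on the minus strand
`start_pos > stop_pos` (row 5), and spliced ORFs keep their block structure
through liftover, merge and BED12 export.

Enrichment, reconstructing a published analysis from its marginal counts
(universe 19 985 genes, 8 863 uORF-harboring; ATF4/CHOP ChIP-seq targets and
ER-stress upregulated gene lists):

```r
enrich_genes(lists, feature_set, universe)
#> # A tibble: 4 × 8
#>   list_name     n_list n_feature n_overlap n_universe  p_value      fdr odds_ratio
#> 1 atf4             392      8863       256      19985 2.76e-17 5.52e-17       2.40
#> 2 chop             256      8863       166      19985 2.50e-11 3.34e-11       2.34
#> 3 congruent        484      8863       268      19985 5.41e- 7 5.41e- 7       1.57
#> 4 translational   1068      8863       736      19985 3.02e-62 1.21e-61       2.94
```

All four lists are significantly enriched in uORF-harboring genes
(FDR < 0.05); ATF4 targets are 2.4× as likely to harbor a uORF as the rest
of the universe — consistent with uORF-mediated translational control of the
integrated stress response.

`autoplot(res)` draws class counts; `autoplot()` on an enrichment table
draws the odds ratios. A thin CLI wrapper lives at
`inst/scripts/sorfkit-pipeline.R` (subcommands `fixtures`, `run-all`,
`enrich`).

## Package layout

* `R/catalog.R`, `R/export.R` — record model, dialects, readers, BED12/FASTA/CSV writers
* `R/qc.R` — theoretical lengths, source QC, gene recovery by overlap
* `R/chain.R`, `R/liftover.R` — chain interpreter, failure criteria
* `R/dedup.R` — two-phase merge
* `R/annotation.R`, `R/classify.R`, `R/attach.R` — transcript models, classes, Kozak, cell types
* `R/enrich.R` — hypergeometric enrichment, BH, odds ratios
* `R/fixtures.R` — synthetic genome/annotation/catalog generator
* `R/pipeline.R` — orchestration, `tidy()`/`glance()`/`autoplot()`

See `vignettes/sorfkit-methods.Rmd` for the full account of models,
conventions and design decisions.
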