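---
title: "Harmonizing short-ORF catalogs with sorfkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing short-ORF catalogs with sorfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorfkit)
library(dplyr)
```

## The problem

Short open reading frames (sORFs, conventionally encoding at most 100 amino
acids) are reported by heterogeneous resources: computational predictions,
ribosome profiling (Ribo-seq) re-analyses and mass-spectrometry studies.
Each source uses its own genome build, column layout, length conventions and
class vocabulary, and the same ORF is typically reported many times.
`sorfkit` turns such per-source catalogs into a non-redundant repository in
which every unique ORF carries uniform coordinates, an evidence count, its
transcript context, a normalized class and a Kozak-context call, and
provides the hypergeometric over-representation machinery used to ask
whether a gene list (e.g. stress-response transcription-factor targets) is
enriched in uORF-harboring genes.

## Coordinate model

Internally every ORF is stored 1-based inclusive in *transcription
orientation*: `start_pos` is the first nucleotide of the start codon and
`stop_pos` the third nucleotide of the stop codon, so `start_pos > stop_pos`
on the minus strand. This mirrors how start and stop are defined by codon
position rather than by interval order; interval work (overlap, BED export)
uses the derived low/high bounds, and BED12 output converts to 0-based
half-open coordinates.

Two conventions were genuinely open and are fixed package-wide:

* **Stop codon included.** The nucleotide length of an ORF includes its stop
  codon, so a length of `3(n+1)` nt encodes `n` amino acids. Sources
  reporting amino-acid lengths are converted with `3 * (aa + 1)` by
  declaring `length_unit = "aa"` in their dialect.
* **CDS bounds include the stop codon** as well (the annotation reader
  merges `stop_codon` features into the CDS extent), so ORF and CDS
  coordinates are directly comparable during classification.

## Per-source quality control

For each record the *theoretical length* is the genomic span
`|start - stop| + 1` minus intron lengths when splice blocks are given. When
a source reports lengths that disagree with the theoretical length for more
than 95% of its comparable entries, its splicing information is evidently
missing or broken and the whole source is rejected. Records whose length
cannot be computed (a missing coordinate) are excluded from the comparison
denominator; rejection is a default that `override_qc` can lift for audits.
The threshold is applied as "reject strictly above 0.95", so a source with
exactly 95% mismatches is kept — the boundary behaviour is tested at 94, 95
and 96 of 100.

## Liftover

Coordinates are homogenized onto one assembly through UCSC chain files. The
interpreter maps every coordinate of a record independently — start, stop
and each splice-block bound — and fails the record on the first triggered
criterion, checked in a fixed order so failure tallies are deterministic:

1. a coordinate has no chain interval (`fail_unmapped`);
2. remapped positions disagree on strand orientation (`fail_strand`); a
   *uniform* flip of all coordinates together is accepted and flips the
   record's strand;
3. a position's chromosome changed (`fail_chromosome`);
4. the genomic distance `|start - stop|` changed (`fail_distance`).

The distance criterion uses the genomic span rather than the spliced length
because it is applied before transcript attachment. The chain interpreter is
native to the package (per-position mapping is what the criteria need), and
its mappings are cross-checked in the test suite against
`rtracklayer::liftOver` on synthetic chains; `invert_chain()` guarantees the
round-trip property (chain then inverse restores all mappable coordinates
exactly).

## Two-phase redundancy merge

The identity of an ORF is the six-tuple (chromosome, strand, start, stop,
splicing status, splice blocks). Phase one groups records providing all six
and collapses each group into one unique ORF whose `experiment_count` is the
group size and whose provenance fields are unions. Phase two rescues records
with partial identity: the chromosome plus (i) strand and start, (ii) strand
and stop, or (iii) start and stop. Such records merge into the best matching
unique ORF agreeing on every field they provide; anything else is dropped
and counted.

"Best matching" needed a total order for reproducibility: candidates are
preferred by agreement on reported length, then start codon, then splicing
status, then by the highest phase-one experiment count, with the
lexicographically smallest identity key as the final tie-break. Matching is
evaluated against a snapshot of the phase-one output so that the outcome is
independent of processing order, each leftover is absorbed by exactly one
candidate, and the conservation law *sum of experiment counts + dropped =
input records* holds exactly. A strandless record's two coordinates carry no
orientation, so pattern (iii) compares them as an unordered pair against the
unique ORF's genomic bounds. Partially matched entries do increment the
experiment count — the count's purpose is to track how often the same ORF
was described.

## Annotation

Transcript models come from a local GTF (read with `rtracklayer`) plus a
genome FASTA (read with `Biostrings`). Relative coordinates are 1-based
along the spliced transcript in transcription orientation;
`genomic_to_relative()` and `relative_to_genomic()` are exact inverses over
exonic positions, and non-exonic positions return a distinct signal so the
ORF-transcript association is flagged rather than silently dropped.

Classification is per ORF-transcript association (an ORF can be a uORF on
one transcript and CDS-overlapping on another; the ORF-level class set is
the union). The decision table, in order: biotype
`nonsense_mediated_decay` gives `NMD-ORF` and `non_stop_decay` gives
`NSD-ORF`; on a coding transcript the ORF is `uORF` (entirely before the
CDS), `upstream-overlapping` (straddles the CDS start), `dORF` (entirely
after), `downstream-overlapping` (straddles the stop), and inside the CDS
the reading frame decides: in frame with the CDS start it is `CDS` (exact
coincidence being the canonical case — such entries are retained even above
100 aa), out of frame `CDS-internal-altframe`. Any other or missing biotype
yields `ncRNA-ORF`, and ORFs with no transcript at all are `intergenic`.
Where the class list left internal in-frame ORFs open, labelling them `CDS`
was chosen because they share the reading frame and stop of the annotated
product; only out-of-frame internal ORFs constitute a distinct coding
signal. The `short` flag (at most 100 aa of encoded peptide) is derived
solely from peptide length, the conventional threshold.

Kozak contexts are read off the spliced transcript around the start codon
(+1 is the first codon nucleotide): `optimal` requires the upstream six
nucleotides to match `gcc[AG]cc` *and* G at +4; `strong` is a purine at -3
with G at +4; `moderate` exactly one of the two; `weak` neither; `undefined`
when fewer than 3 nt upstream or 1 nt downstream exist. Optimal contexts
satisfy the strong conditions by construction, which the suite verifies by
exhaustive enumeration together with the partition property over all 4^7
length-7 contexts. The same positional tests around a non-ATG start codon
give a "Kozak-alike" call (`alike = TRUE`).

## Enrichment statistics

With a universe of `N` genes containing `K` feature genes (e.g. uORF
harborers), a list of `n` genes with `k` in the feature set has upper-tail
hypergeometric p-value `P(X >= k)` and sample odds ratio
`k (N - n - K + k) / ((n - k) (K - k))`. Both the list and the feature set
are intersected with the universe *before* counting — required for the
published marginal counts to be mutually consistent. P-values are computed
on the log scale (magnitudes near 1e-61 occur in practice) and adjusted with
Benjamini-Hochberg across the lists tested; FDR < 0.05 is the conventional
significance line. The sample (cross-product) odds ratio was chosen over a
conditional-MLE estimate because it reproduces all four published values at
two decimals.

## Synthetic fixtures

`make_genome_annotation()` plants, on a toy two-chromosome genome (12 kb
each), twelve transcripts covering every class branch: coding transcripts
with a 150-nt 5' UTR, 300-nt CDS and 150-nt 3' UTR, plus lncRNA, NMD and NSD
transcripts, on both strands, three of them intron-containing so that
planted ORFs span splice junctions. Each transcript carries exactly one
designed ORF: a real start codon (ATG, or CTG for the Kozak-alike case), a
stop-free codon body, a terminal stop, and a designed Kozak flank
(`GCCACC`/+4G for optimal down to `TTTTCC`/+4T for weak) written into the
transcript sequence and imprinted into the genome (reverse-complemented on
the minus strand). The manifest records every planted identity key, class,
Kozak category and sequence, and fully determines the expected pipeline
output.

`make_catalogs()` samples each planted ORF into a configurable number of
sources (default 3 sources, redundancy 2 — enough to exercise cross-source
merging while keeping catalogs small), writing two source layouts: the
standard column set, and an alternative layout with interval-style
coordinates, amino-acid lengths and different separators, so the dialect
machinery is exercised end to end. One source can be written on a shifted
coordinate system with a matching chain file. Corruption modes emulate real
heterogeneity — withheld strand, withheld stop, stripped splice blocks (the
length-mismatch failure source QC must catch). All generation flows from a
single seeded stream, consumed in a documented order, so outputs are
byte-reproducible.

What the fixtures do *not* emulate: real Ribo-seq read-level evidence,
overlapping gene structures, sequencing error, genuine assembly differences
beyond rigid chain operations, or the scale of real catalogs (millions of
entries). Passing the closure tests therefore demonstrates correctness of
the harmonization logic, not robustness to upstream data pathologies beyond
the modelled corruption modes.

## Numerical and testing choices

* All coordinate arithmetic is integer; the distance criterion is exact
  integer equality, no tolerance.
* Deterministic outputs everywhere: unique ORFs are ordered by identity
  key, stable identifiers are zero-padded ordinals in that order, partial
  merging uses the snapshot rule above.
* The test suite checks closure (pipeline output equals the manifest) on 20
  fixture seeds for classification and Kozak calls, dedup against an
  exhaustive pairwise oracle on catalogs up to 200 records, and the
  hypergeometric tail against full enumeration up to a universe of 12 —
  sizes chosen so the whole suite stays fast while every property is
  exercised on non-trivial inputs.
* `scripts/acceptance.R` recomputes the enrichment statistics from the
  published marginal counts and the fixture recovery rates from a fresh
  end-to-end run.

## Known limitations

* Conservation and coding-potential scores (PhyloCSF, PhastCons, FLOSS, ORF
  score) are pass-through fields; the package never computes them.
* Gene-ID spaces must be pre-harmonized before enrichment; no symbol
  conversion is attempted.
* Cell-type normalization is mechanical (a user-supplied two-column
  mapping); no ontology resolution.
* Fuzzy merging of near-identical coordinates is deliberately out of scope:
  identity is exact field equality.

## A worked example

```{r example, eval = FALSE}
fx <- make_genome_annotation(tempfile("fixture"), seed = 1)
cats <- make_catalogs(fx, seed = 1, n_sources = 3, redundancy = 2,
                      shift_sources = 2)
cfg <- sorf_pipeline_config(
  sources = mutate(cats$catalogs, dialect = unname(cats$dialects[source_id])),
  gtf_path = fx$gtf_path, genome_path = fx$genome_path,
  out_dir = tempfile("repo"), cell_type_mapping = fx$cell_type_mapping
)
res <- run_sorf_pipeline(cfg)
glance(res)   # stage counts: 24 records in, 12 unique ORFs, 0 dropped
tidy(res)     # the per-ORF repository table
autoplot(res) # class counts
```
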