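#' Theoretical nucleotide length of ORF records
#'
#' The theoretical length is the genomic distance between the start and stop
#' codons, `|start - stop| + 1`, minus the summed intron lengths when splice
#' blocks are provided. It is strand-symmetric and includes the stop codon.
#'
#' @param records Record tibble (vectorized over rows).
#' @return Integer vector of lengths in nucleotides; `NA` where a coordinate
#'   is missing (such records cannot enter the length-mismatch tally).
#' @export
theoretical_length <- function(records) {
  span <- abs(records$start_pos - records$stop_pos) + 1L
  introns <- map_int(records$blocks, intron_length)
  out <- span - introns
  out[is.na(records$start_pos) | is.na(records$stop_pos)] <- NA_integer_
  as.integer(out)
}

#' Per-source length-consistency quality control
#'
#' For every record of one source the theoretical length is compared with the
#' length the source reports. A record counts as mismatched only when both
#' lengths are computable and differ — a pervasive mismatch indicates the
#' source dropped its splicing information. Sources with more than 95% of
#' entries mismatched are rejected.
#'
#' @param records Record tibble, all from one source.
#' @param source_id Source label for the report; defaults to the records'
#'   `source_id`.
#' @param threshold Rejection threshold on the mismatch fraction (default
#'   0.95; a source is accepted while the fraction stays at or below it).
#' @return A one-row tibble: `source_id`, `n_entries`, `n_comparable`,
#'   `n_length_mismatch`, `mismatch_fraction`, `accepted`.
#' @export
qc_source <- function(records, source_id = NULL, threshold = 0.95) {
  source_id <- source_id %||% records$source_id[1] %||% NA_character_
  if (nrow(records) == 0L) {
    warn(sprintf("qc_source: source '%s' has no records", source_id))
    return(tibble(source_id = source_id, n_entries = 0L, n_comparable = 0L,
                  n_length_mismatch = 0L, mismatch_fraction = 0,
                  accepted = TRUE))
  }
  theo <- theoretical_length(records)
  reported <- records$len_nt
  comparable <- !is.na(theo) & !is.na(reported)
  mism <- comparable & theo != reported
  frac <- if (any(comparable)) sum(mism) / sum(comparable) else 0
  tibble(
    source_id = source_id,
    n_entries = nrow(records),
    n_comparable = sum(comparable),
    n_length_mismatch = sum(mism),
    mismatch_fraction = frac,
    accepted = frac <= threshold
  )
}

#' QC all sources of a combined catalog
#'
#' @param records Record tibble with a `source_id` column.
#' @inheritParams qc_source
#' @return One report row per source (see [qc_source()]).
#' @export
qc_catalog <- function(records, threshold = 0.95) {
  records %>%
    group_by(.data$source_id) %>%
    dplyr::group_map(~ qc_source(.x, source_id = .y$source_id,
                                 threshold = threshold)) %>%
    bind_rows()
}

#' Recover genes overlapping ORF coordinates
#'
#' When a source provides no gene, the gene(s) or ncRNA gene(s) whose genomic
#' extent overlaps the ORF interval are recovered from the annotation. The
#' overlap is strand-agnostic; genes on the ORF's own strand are listed
#' first, then each group sorted by gene ID. An empty result means the ORF is
#' intergenic.
#'
#' @param records Record tibble.
#' @param genes Gene-extent tibble with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (1-based inclusive), e.g. from [gene_extents()].
#' @return List (one element per record) of overlapping gene-ID vectors.
#' @export
recover_genes <- function(records, genes) {
  bounds <- genomic_bounds(records)
  usable <- !is.na(records$chrom) & !is.na(bounds$low) & !is.na(bounds$high)
  out <- rep(list(character(0)), nrow(records))
  if (!any(usable) || nrow(genes) == 0L) {
    return(out)
  }
  missing_chrom <- setdiff(unique(records$chrom[usable]), unique(genes$chrom))
  if (length(missing_chrom) > 0L) {
    warn(sprintf("recover_genes: chromosome(s) absent from annotation: %s",
                 paste(missing_chrom, collapse = ", ")))
    usable <- usable & records$chrom %in% genes$chrom
    if (!any(usable)) {
      return(out)
    }
  }
  q <- GenomicRanges::GRanges(
    records$chrom[usable],
    IRanges::IRanges(bounds$low[usable], bounds$high[usable])
  )
  s <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end)
  )
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  idx_usable <- which(usable)
  for (qi in unique(S4Vectors::queryHits(hits))) {
    gi <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == qi]
    rec <- idx_usable[qi]
    same <- !is.na(records$strand[rec]) & genes$strand[gi] == records$strand[rec]
    ids <- c(sort(genes$gene_id[gi][same]), sort(genes$gene_id[gi][!same]))
    out[[rec]] <- ids
  }
  out
}

#' Fill missing gene annotations by overlap
#'
#' Records without any gene ID get the genes recovered by [recover_genes()].
#'
#' @inheritParams recover_genes
#' @return The record tibble with `gene_ids` completed.
#' @export
fill_gene_ids <- function(records, genes) {
  need <- map_int(records$gene_ids, length) == 0L
  if (!any(need)) {
    return(records)
  }
  recovered <- recover_genes(records[need, , drop = FALSE], genes)
  records$gene_ids[need] <- recovered
  records
}
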