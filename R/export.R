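#' Assign stable ORF identifiers
#'
#' Unique ORFs get deterministic identifiers: a species/database tag followed
#' by a zero-padded ordinal assigned in lexicographic identity-key order, so
#' the same merged repository always yields the same names.
#'
#' @param uniques A unique-ORF tibble (see [merge_full()]).
#' @param tag Identifier prefix, e.g. `"HSORF"`.
#' @param width Zero-padding width of the ordinal.
#' @return `uniques` with an `orf_id` column, ordered by identity key.
#' @export
assign_orf_ids <- function(uniques, tag = "ORF", width = 7L) {
  keys <- identity_key(uniques)
  stopifnot(!anyNA(keys))
  uniques %>%
    mutate(.key = keys) %>%
    arrange(.data$.key) %>%
    mutate(orf_id = sprintf("%s%0*d", tag, width, row_number())) %>%
    select(-".key") %>%
    select("orf_id", everything())
}

# BED blocks of one record: its splice blocks, or the whole span when
# unspliced. Returned sorted by genomic start.
bed_blocks <- function(start_pos, stop_pos, blocks) {
  if (nrow(blocks) == 0L) {
    data.frame(start = min(start_pos, stop_pos), end = max(start_pos, stop_pos))
  } else {
    blocks[order(blocks$start), , drop = FALSE]
  }
}

#' Export unique ORFs as BED12
#'
#' Writes one BED12 line per ORF with 0-based half-open coordinates:
#' `chromStart` is the lowest genomic coordinate minus one, the block fields
#' encode the splice structure (a single block for unspliced ORFs) and
#' `thickStart`/`thickEnd` span the whole ORF. The `name` field carries the
#' stable `orf_id` and the score the experiment count (capped at 1000).
#'
#' @param uniques Unique-ORF tibble with complete identity keys and `orf_id`
#'   (see [assign_orf_ids()]).
#' @param path Output file.
#' @return The written tibble of 12 BED columns, invisibly.
#' @export
write_bed12 <- function(uniques, path) {
  stopifnot(!anyNA(identity_key(uniques)))
  if (!"orf_id" %in% names(uniques)) {
    uniques <- assign_orf_ids(uniques)
  }
  score <- if ("experiment_count" %in% names(uniques)) {
    pmin(uniques$experiment_count, 1000L)
  } else {
    rep(0L, nrow(uniques))
  }
  rows <- pmap(
    list(uniques$chrom, uniques$strand, uniques$start_pos, uniques$stop_pos,
         uniques$blocks, uniques$orf_id, score),
    function(chrom, strand, start_pos, stop_pos, blocks, orf_id, score) {
      b <- bed_blocks(start_pos, stop_pos, blocks)
      chrom_start <- b$start[1L] - 1L
      chrom_end <- b$end[nrow(b)]
      tibble(
        chrom = chrom,
        chromStart = chrom_start,
        chromEnd = chrom_end,
        name = orf_id,
        score = score,
        strand = strand,
        thickStart = chrom_start,
        thickEnd = chrom_end,
        itemRgb = "0",
        blockCount = nrow(b),
        blockSizes = paste(b$end - b$start + 1L, collapse = ","),
        blockStarts = paste(b$start - 1L - chrom_start, collapse = ",")
      )
    }
  )
  out <- bind_rows(rows)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(out)
}

#' Export ORF sequences as FASTA
#'
#' One entry per unique ORF carrying a sequence of the requested kind; ORFs
#' lacking it are skipped and the skip count reported.
#'
#' @param uniques Unique-ORF tibble with `orf_id`.
#' @param path Output FASTA file.
#' @param kind `"nucleotide"` (writes `nuc_seq`) or `"peptide"` (`pep_seq`).
#' @return Invisibly, a list with `written` and `skipped` counts.
#' @export
write_fasta <- function(uniques, path, kind = c("nucleotide", "peptide")) {
  kind <- match.arg(kind)
  seqs <- if (kind == "nucleotide") uniques$nuc_seq else uniques$pep_seq
  keep <- !is.na(seqs) & nzchar(seqs)
  skipped <- sum(!keep)
  if (skipped > 0L) {
    inform(sprintf("write_fasta: skipped %d ORF(s) without a %s sequence",
                   skipped, kind))
  }
  set <- if (kind == "nucleotide") {
    Biostrings::DNAStringSet(seqs[keep])
  } else {
    Biostrings::AAStringSet(seqs[keep])
  }
  names(set) <- uniques$orf_id[keep]
  Biostrings::writeXStringSet(set, path)
  invisible(list(written = sum(keep), skipped = skipped))
}

#' Export the repository as a flat CSV
#'
#' Mirrors the per-ORF feature inventory (location, splicing, lengths,
#' sequences, provenance, classes, Kozak context); multi-valued fields are
#' `"|"`-collapsed.
#'
#' @param uniques Annotated unique-ORF tibble.
#' @param path Output CSV.
#' @return The flattened tibble, invisibly.
#' @export
write_repository_csv <- function(uniques, path) {
  flat <- uniques %>%
    mutate(
      blocks = map_chr(.data$blocks, blocks_string),
      across(
        all_of(intersect(c("transcript_ids", "gene_ids", "cell_types",
                           "sources", "methods", "classes"), names(uniques))),
        ~ map_chr(.x, collapse_multi)
      )
    ) %>%
    select(-any_of(c("conservation", "tx_annotations")))
  readr::write_csv(flat, path, progress = FALSE)
  invisible(flat)
}

#' @importFrom dplyr any_of
NULL
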