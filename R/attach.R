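#' Attach transcripts and complete annotation of unique ORFs
#'
#' Completes each unique ORF after merging:
#'
#' 1. Missing nucleic sequences are extracted from the genome over the ORF's
#'    blocks (reverse-complemented on the minus strand); missing peptide
#'    sequences are the standard-code translation without the stop codon;
#'    the start codon is read off the sequence. ORFs whose extracted
#'    sequence length is not a multiple of 3 are flagged
#'    `frame_inconsistent` and retained (no peptide is derived for them).
#' 2. Transcript models are attached by ID when the sources provided IDs
#'    found in the annotation; otherwise by exon-compatible overlap: a
#'    same-strand transcript on which both ORF ends are exonic and the
#'    relative span equals the ORF's spliced length.
#' 3. For every ORF-transcript association the transcript-relative start and
#'    stop, the normalized class and the Kozak context are computed.
#'    Associations whose ORF ends are not exonic on the transcript are kept
#'    but flagged (`exonic = FALSE`, no class).
#'
#' @param uniques Unique-ORF tibble from [merge_catalog()].
#' @param txmodels Transcript models from [read_annotation()].
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path (optional;
#'   without it sequences and Kozak contexts stay missing).
#' @return `uniques` with columns `nuc_seq`, `pep_seq`, `start_codon` filled
#'   where derivable, plus `frame_inconsistent`, `tx_annotations` (list of
#'   per-association tibbles), `classes` (list; `"intergenic"` when no
#'   transcript is attached), `kozak_category`, `kozak_alike` (best-ranked
#'   association) and `short_flag` (peptide <= 100 aa).
#' @export
attach_transcripts <- function(uniques, txmodels, genome = NULL) {
  if (!is.null(genome) && is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  n <- nrow(uniques)
  uniques$frame_inconsistent <- rep(FALSE, n)
  tx_ann <- vector("list", n)
  classes <- vector("list", n)
  kozak_cat <- rep("undefined", n)
  kozak_alike <- rep(NA, n)

  for (i in seq_len(n)) {
    orf <- uniques[i, ]
    b <- bed_blocks(orf$start_pos, orf$stop_pos, orf$blocks[[1]])

    if (is.na(orf$nuc_seq) && !is.null(genome) && orf$chrom %in% names(genome)) {
      uniques$nuc_seq[i] <- spliced_sequence(genome, orf$chrom, b, orf$strand)
    }
    seq_i <- uniques$nuc_seq[i]
    if (!is.na(seq_i)) {
      if (nchar(seq_i) %% 3L != 0L) {
        uniques$frame_inconsistent[i] <- TRUE
      } else if (is.na(uniques$pep_seq[i]) && nchar(seq_i) >= 6L) {
        cds <- substr(seq_i, 1L, nchar(seq_i) - 3L)
        uniques$pep_seq[i] <- as.character(Biostrings::translate(
          Biostrings::DNAString(cds), if.fuzzy.codon = "X"))
      }
      if (is.na(uniques$start_codon[i])) {
        uniques$start_codon[i] <- substr(seq_i, 1L, 3L)
      }
      if (is.na(uniques$pep_len_aa[i]) && nchar(seq_i) %% 3L == 0L) {
        uniques$pep_len_aa[i] <- nchar(seq_i) %/% 3L - 1L
      }
    }

    ann <- associate_transcripts(uniques[i, ], txmodels)
    tx_ann[[i]] <- ann
    cls <- unique(ann$class[!is.na(ann$class)])
    classes[[i]] <- if (length(cls) == 0L) "intergenic" else sort(cls)
    defined <- ann[!is.na(ann$kozak_category) &
                     ann$kozak_category != "undefined", , drop = FALSE]
    if (nrow(defined) > 0L) {
      rank <- match(defined$kozak_category,
                    c("optimal", "strong", "moderate", "weak"))
      best <- which.min(rank)
      kozak_cat[i] <- defined$kozak_category[best]
      kozak_alike[i] <- defined$kozak_alike[best]
    }
  }

  uniques$tx_annotations <- tx_ann
  uniques$classes <- classes
  uniques$kozak_category <- kozak_cat
  uniques$kozak_alike <- kozak_alike
  uniques$transcript_ids <- map(tx_ann, ~ .x$transcript_id)
  uniques$short_flag <- !is.na(uniques$pep_len_aa) & uniques$pep_len_aa <= 100L
  uniques
}

# Per-ORF transcript association table. Returns a tibble with one row per
# associated transcript: transcript_id, exonic, rel_start, rel_stop, class,
# kozak_category, kozak_alike.
associate_transcripts <- function(orf, txmodels) {
  empty <- tibble(transcript_id = character(0), exonic = logical(0),
                  rel_start = integer(0), rel_stop = integer(0),
                  class = character(0), kozak_category = character(0),
                  kozak_alike = logical(0))
  ids <- orf$transcript_ids[[1]]
  by_id <- length(ids) > 0L
  cand <- if (by_id) {
    txmodels %>% filter(.data$transcript_id %in% ids)
  } else {
    lo <- min(orf$start_pos, orf$stop_pos)
    hi <- max(orf$start_pos, orf$stop_pos)
    txmodels %>%
      filter(.data$chrom == orf$chrom, .data$strand == orf$strand,
             .data$tx_start <= lo, hi <= .data$tx_end)
  }
  if (nrow(cand) == 0L) {
    return(empty)
  }
  theo_len <- theoretical_length(orf)
  rows <- map(seq_len(nrow(cand)), function(j) {
    tx <- cand[j, ]
    compatible_strand <- !is.na(orf$strand) && tx$strand == orf$strand &&
      tx$chrom == orf$chrom
    rs <- rl <- NA_integer_
    if (compatible_strand) {
      rs <- genomic_to_relative(orf$start_pos, tx$exons[[1]], tx$strand)
      rl <- genomic_to_relative(orf$stop_pos, tx$exons[[1]], tx$strand)
    }
    exonic <- !is.na(rs) && !is.na(rl) && rs < rl
    span_ok <- exonic && (is.na(theo_len) || rl - rs + 1L == theo_len)
    if (!by_id && !span_ok) {
      return(NULL) # overlap-based association requires exon compatibility
    }
    cls <- NA_character_
    kz <- tibble(category = "undefined", alike = NA)
    if (exonic) {
      cls <- classify_orf(rs, rl, tx$biotype, tx$cds_start_rel, tx$cds_stop_rel)
      if (!is.na(tx$seq)) {
        kz <- kozak_call(tx$seq, rs)[, c("category", "alike")]
      }
    }
    tibble(transcript_id = tx$transcript_id, exonic = exonic,
           rel_start = rs, rel_stop = rl, class = cls,
           kozak_category = kz$category, kozak_alike = kz$alike)
  })
  out <- bind_rows(compact(rows))
  if (nrow(out) == 0L) empty else out
}

#' Normalize cell-type labels with a mapping table
#'
#' Sources name cell contexts inconsistently; a two-column mapping table
#' (`raw`, `normalized`) converts each raw label to its curated name.
#' Unmapped labels pass through unchanged with one warning listing them.
#'
#' @param records Record or unique-ORF tibble with a `cell_types` list
#'   column.
#' @param mapping Data frame with columns `raw` and `normalized`.
#' @return The tibble with normalized `cell_types`.
#' @export
normalize_cell_types <- function(records, mapping) {
  stopifnot(all(c("raw", "normalized") %in% names(mapping)))
  lut <- set_names(mapping$normalized, mapping$raw)
  seen_unmapped <- character(0)
  records$cell_types <- map(records$cell_types, function(x) {
    if (length(x) == 0L) return(x)
    hit <- x %in% names(lut)
    seen_unmapped <<- union(seen_unmapped, x[!hit])
    sort(unique(c(unname(lut[x[hit]]), x[!hit])))
  })
  if (length(seen_unmapped) > 0L) {
    warn(sprintf("normalize_cell_types: unmapped label(s) passed through: %s",
                 paste(sort(seen_unmapped), collapse = ", ")))
  }
  records
}
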