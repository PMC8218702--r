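#' Describe how a source table maps onto the ORF record fields
#'
#' Each data source publishes its catalog with its own column names, length
#' units and coordinate conventions. A dialect is a plain list that names, for
#' every ORF record field, the column of the source table that carries it
#' (`NULL` when the source does not provide the field), plus three options:
#'
#' * `length_unit`: `"nt"` (default) or `"aa"`. Amino-acid lengths are
#'   converted to nucleotides as `3 * (aa + 1)` (stop codon included).
#' * `coord_style`: `"transcription"` (default; start/stop are the first
#'   nucleotide of the start codon and the last of the stop codon, so
#'   start > stop on the minus strand) or `"interval"` (start/stop are the
#'   low/high genomic bounds; they are re-oriented using the strand).
#' * `multi_sep`: separator for multi-valued cells (transcripts, genes,
#'   cell types); default `"|"`.
#'
#' @param chrom,strand,start,stop,splicing,blocks,length_nt,pep_length_aa,start_codon,nuc_seq,pep_seq,transcripts,genes,cell_types,method
#'   Column names in the source file, or `NULL` when absent.
#' @param length_unit,coord_style,multi_sep Options described above.
#' @param conservation Named character vector mapping pass-through score names
#'   (e.g. `phylocsf`, `phastcons`, `floss`, `orfscore`) to source columns.
#' @return A list of class `sorf_dialect`.
#' @export
#' @examples
#' sorf_dialect(chrom = "chr", start = "orf_start", stop = "orf_end")
sorf_dialect <- function(chrom = "chrom", strand = "strand",
                         start = "start_pos", stop = "stop_pos",
                         splicing = "splicing", blocks = "blocks",
                         length_nt = "length_nt",
                         pep_length_aa = "pep_length_aa",
                         start_codon = "start_codon",
                         nuc_seq = "nuc_seq", pep_seq = "pep_seq",
                         transcripts = "transcripts", genes = "genes",
                         cell_types = "cell_types", method = "method",
                         conservation = NULL,
                         length_unit = c("nt", "aa"),
                         coord_style = c("transcription", "interval"),
                         multi_sep = "|") {
  structure(
    list(
      chrom = chrom, strand = strand, start = start, stop = stop,
      splicing = splicing, blocks = blocks, length_nt = length_nt,
      pep_length_aa = pep_length_aa, start_codon = start_codon,
      nuc_seq = nuc_seq, pep_seq = pep_seq, transcripts = transcripts,
      genes = genes, cell_types = cell_types, method = method,
      conservation = conservation,
      length_unit = match.arg(length_unit),
      coord_style = match.arg(coord_style),
      multi_sep = multi_sep
    ),
    class = "sorf_dialect"
  )
}

dialect_col <- function(df, dialect, field) {
  col <- dialect[[field]]
  if (is.null(col) || !col %in% names(df)) {
    return(rep(NA_character_, nrow(df)))
  }
  x <- as.character(df[[col]])
  x[!nzchar(trimws(x %||% ""))] <- NA_character_
  x
}

#' Read one source catalog into an ORF record table
#'
#' Every row of the delimited source file becomes one ORF record. Fields the
#' source does not provide (or provides unparseably) are missing (`NA`),
#' never fabricated, and row order is preserved. A malformed splice-block
#' string demotes the record's splicing status to `"unknown"` with a warning;
#' a missing chromosome column is a hard error.
#'
#' @param path Delimited file (comma, tab or semicolon separated; sniffed by
#'   [readr::read_delim()] when `delim` is `NULL`).
#' @param dialect A [sorf_dialect()] mapping source columns to record fields.
#' @param source_id Identifier recorded in the `source_id` column of every
#'   record; defaults to the file name without extension.
#' @param delim Field delimiter, or `NULL` to guess.
#' @return A tibble with one row per source entry and columns `source_id`,
#'   `record_id`, `chrom`, `strand`, `start_pos`, `stop_pos`, `splicing`,
#'   `blocks` (list of data.frames), `len_nt`, `pep_len_aa`, `start_codon`,
#'   `nuc_seq`, `pep_seq`, `transcript_ids`, `gene_ids`, `cell_types` (list
#'   columns), `method` and `conservation` (list of named character vectors).
#'   Coordinates are 1-based inclusive in transcription orientation.
#' @export
read_catalog <- function(path, dialect = sorf_dialect(), source_id = NULL,
                         delim = NULL) {
  stopifnot(file.exists(path))
  source_id <- source_id %||% sub("\\.[^.]*$", "", basename(path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  chrom_col <- dialect$chrom
  if (is.null(chrom_col) || !chrom_col %in% names(df)) {
    abort(sprintf("catalog '%s' lacks the mandatory chromosome column '%s'",
                  path, chrom_col %||% "<unset>"))
  }
  as_records(df, dialect, source_id)
}

# Shared row -> record conversion (used by read_catalog and the fixture
# generator, which builds the raw data frame in memory).
as_records <- function(df, dialect, source_id) {
  n <- nrow(df)
  chrom <- dialect_col(df, dialect, "chrom")
  strand <- dialect_col(df, dialect, "strand")
  strand[!strand %in% c("+", "-")] <- NA_character_
  start_pos <- as_int_quiet(dialect_col(df, dialect, "start"))
  stop_pos <- as_int_quiet(dialect_col(df, dialect, "stop"))

  if (dialect$coord_style == "interval") {
    # re-orient (low, high) bounds into transcription order; rows with a
    # missing strand or a single coordinate are kept as given
    both <- !is.na(start_pos) & !is.na(stop_pos)
    neg <- both & !is.na(strand) & strand == "-"
    lo <- pmin(start_pos, stop_pos)
    hi <- pmax(start_pos, stop_pos)
    start_pos[both] <- if_else(neg, hi, lo)[both]
    stop_pos[both] <- if_else(neg, lo, hi)[both]
  }

  raw_blocks <- dialect_col(df, dialect, "blocks")
  blocks <- map(raw_blocks, function(x) {
    if (is.na(x)) empty_blocks() else parse_blocks(x)
  })
  malformed <- map_lgl(blocks, is.null)
  if (any(malformed)) {
    warn(sprintf("%s: %d record(s) with malformed splice-block strings; splicing set to 'unknown'",
                 source_id, sum(malformed)))
    blocks[malformed] <- list(empty_blocks())
  }

  splicing_raw <- tolower(dialect_col(df, dialect, "splicing"))
  splicing <- dplyr::case_when(
    splicing_raw %in% c("spliced", "true", "yes", "1") ~ "spliced",
    splicing_raw %in% c("unspliced", "false", "no", "0") ~ "unspliced",
    !is.na(splicing_raw) ~ "unknown",
    # no splicing column: infer from the block count when blocks are given
    map_int(blocks, nrow) >= 2L ~ "spliced",
    map_int(blocks, nrow) == 1L ~ "unspliced",
    TRUE ~ "unknown"
  )
  splicing[malformed] <- "unknown"
  # a spliced record must carry blocks; without them the status is unusable
  splicing[splicing == "spliced" & map_int(blocks, nrow) == 0L] <- "unknown"
  blocks[splicing != "spliced"] <- list(empty_blocks())

  len_nt <- as_int_quiet(dialect_col(df, dialect, "length_nt"))
  if (dialect$length_unit == "aa" && !is.null(dialect$length_nt)) {
    len_nt <- 3L * (len_nt + 1L)
  }
  pep_len <- as_int_quiet(dialect_col(df, dialect, "pep_length_aa"))

  sep <- dialect$multi_sep
  cons_cols <- dialect$conservation
  conservation <- if (is.null(cons_cols)) {
    rep(list(character(0)), n)
  } else {
    map(seq_len(n), function(i) {
      vals <- vapply(cons_cols, function(col) {
        if (col %in% names(df)) as.character(df[[col]][i]) else NA_character_
      }, "")
      vals[!is.na(vals)]
    })
  }

  tibble(
    source_id = rep(source_id, n),
    record_id = sprintf("%s:%d", source_id, seq_len(n)),
    chrom = chrom,
    strand = strand,
    start_pos = start_pos,
    stop_pos = stop_pos,
    splicing = splicing,
    blocks = blocks,
    len_nt = len_nt,
    pep_len_aa = pep_len,
    start_codon = toupper(dialect_col(df, dialect, "start_codon")),
    nuc_seq = toupper(dialect_col(df, dialect, "nuc_seq")),
    pep_seq = toupper(dialect_col(df, dialect, "pep_seq")),
    transcript_ids = map(dialect_col(df, dialect, "transcripts"), split_multi, sep = sep),
    gene_ids = map(dialect_col(df, dialect, "genes"), split_multi, sep = sep),
    cell_types = map(dialect_col(df, dialect, "cell_types"), split_multi, sep = sep),
    method = dialect_col(df, dialect, "method"),
    conservation = conservation
  )
}

#' Identity keys of ORF records
#'
#' The identity of an ORF is the tuple (chromosome, strand, start position,
#' stop position, splicing status, splicing coordinates); two entries
#' describing the same ORF share all six. The key string joins the fields
#' with `"|"`, with splice blocks in canonical sorted `"start-end"`
#' comma-joined form. A key is *complete* only when chromosome, strand and
#' both coordinates are present and the splicing status is known (with blocks
#' for spliced records); incomplete keys are `NA`.
#'
#' @param records A record or unique-ORF tibble.
#' @return Character vector of keys, `NA` where incomplete.
#' @export
identity_key <- function(records) {
  blk <- map_chr(records$blocks, blocks_string)
  key <- paste(records$chrom, records$strand, records$start_pos,
               records$stop_pos, records$splicing, blk, sep = "|")
  complete <- !is.na(records$chrom) & !is.na(records$strand) &
    !is.na(records$start_pos) & !is.na(records$stop_pos) &
    records$splicing %in% c("spliced", "unspliced") &
    (records$splicing != "spliced" | nzchar(blk))
  key[!complete] <- NA_character_
  key
}

# Genomic low/high bounds of each record (transcription orientation folded
# back into interval order).
genomic_bounds <- function(records) {
  tibble(
    low = pmin(records$start_pos, records$stop_pos),
    high = pmax(records$start_pos, records$stop_pos)
  )
}
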