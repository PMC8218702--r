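#' Load transcript models from a GTF annotation
#'
#' Builds one transcript model per `transcript_id`: exon structure, biotype,
#' genomic extent, transcript-relative CDS bounds and (when a genome is
#' given) the spliced transcript sequence. CDS bounds are taken over the
#' union of `CDS` and `stop_codon` features, so the canonical coding
#' sequence includes its stop codon — the same stop-inclusive convention
#' used for ORF coordinates.
#'
#' @param gtf_path GTF/GFF file with `exon`, `CDS` (and optionally
#'   `stop_codon`) features carrying `transcript_id`, `gene_id` and a
#'   biotype attribute (`transcript_biotype`, `biotype` or `gene_biotype`).
#' @param genome Optional genome as a named [Biostrings::DNAStringSet] or a
#'   FASTA path; enables sequence-dependent annotation (Kozak contexts).
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype`, `exons` (list of sorted block
#'   data.frames), `tx_start`, `tx_end`, `spliced_len`, `cds_start_rel`,
#'   `cds_stop_rel` (1-based transcript-relative, `NA` for non-coding) and
#'   `seq`.
#' @export
read_annotation <- function(gtf_path, genome = NULL) {
  gr <- rtracklayer::import(gtf_path)
  mc <- S4Vectors::mcols(gr)
  biotype_col <- intersect(c("transcript_biotype", "biotype", "gene_biotype"),
                           names(mc))[1]
  feats <- tibble(
    type = as.character(mc$type),
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    biotype = if (!is.na(biotype_col)) as.character(mc[[biotype_col]]) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  ) %>%
    filter(!is.na(.data$transcript_id))
  if (!is.null(genome) && is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }

  exons <- feats %>% filter(.data$type == "exon")
  cds <- feats %>% filter(.data$type %in% c("CDS", "stop_codon"))
  tx_ids <- unique(exons$transcript_id)

  models <- map(tx_ids, function(tx) {
    e <- exons %>% filter(.data$transcript_id == tx) %>% arrange(.data$start)
    blocks <- data.frame(start = e$start, end = e$end)
    strand <- e$strand[1L]
    chrom <- e$chrom[1L]
    spliced_len <- sum(blocks$end - blocks$start + 1L)
    cc <- cds %>% filter(.data$transcript_id == tx)
    cds_rel <- c(NA_integer_, NA_integer_)
    if (nrow(cc) > 0L) {
      lo <- min(cc$start)
      hi <- max(cc$end)
      g5 <- if (strand == "+") lo else hi # 5'-most genomic coordinate
      g3 <- if (strand == "+") hi else lo
      cds_rel <- c(genomic_to_relative(g5, blocks, strand),
                   genomic_to_relative(g3, blocks, strand))
    }
    seq <- if (!is.null(genome) && chrom %in% names(genome)) {
      spliced_sequence(genome, chrom, blocks, strand)
    } else {
      NA_character_
    }
    tibble(
      transcript_id = tx,
      gene_id = first_non_na(e$gene_id),
      chrom = chrom,
      strand = strand,
      biotype = first_non_na(e$biotype),
      exons = list(blocks),
      tx_start = min(blocks$start),
      tx_end = max(blocks$end),
      spliced_len = spliced_len,
      cds_start_rel = as.integer(cds_rel[1L]),
      cds_stop_rel = as.integer(cds_rel[2L]),
      seq = seq
    )
  })
  bind_rows(models)
}

# Spliced sequence of an exon chain (reverse-complemented on the minus
# strand).
spliced_sequence <- function(genome, chrom, blocks, strand) {
  parts <- vapply(seq_len(nrow(blocks)), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]],
                                    blocks$start[i], blocks$end[i]))
  }, "")
  s <- paste(parts, collapse = "")
  if (strand == "-") reverse_complement(s) else s
}

#' Genomic extents of genes in an annotation
#'
#' @param txmodels Transcript-model tibble from [read_annotation()].
#' @return Tibble `gene_id`, `chrom`, `strand`, `start`, `end` (the span of
#'   all transcripts of the gene).
#' @export
gene_extents <- function(txmodels) {
  txmodels %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      start = min(.data$tx_start),
      end = max(.data$tx_end),
      .groups = "drop"
    )
}

#' Convert genomic positions to transcript-relative coordinates
#'
#' Returns the 1-based position along the spliced transcript in
#' transcription orientation (position 1 is the first transcribed
#' nucleotide). Positions falling in introns or outside the transcript map
#' to `NA` — a distinct "not exonic" signal for the caller to flag.
#'
#' @param pos Integer vector of genomic positions (1-based).
#' @param exons Sorted exon block data.frame (`start`, `end`).
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of relative positions (`NA` where not exonic).
#' @export
genomic_to_relative <- function(pos, exons, strand) {
  widths <- exons$end - exons$start + 1L
  before <- c(0L, cumsum(widths))
  total <- sum(widths)
  vapply(pos, function(p) {
    if (is.na(p)) return(NA_integer_)
    i <- which(exons$start <= p & p <= exons$end)
    if (length(i) == 0L) return(NA_integer_)
    i <- i[1L]
    plus_rel <- before[i] + (p - exons$start[i] + 1L)
    if (strand == "+") as.integer(plus_rel) else as.integer(total - plus_rel + 1L)
  }, integer(1))
}

#' Convert transcript-relative positions back to genomic coordinates
#'
#' Inverse of [genomic_to_relative()].
#'
#' @param rel Integer vector of 1-based transcript-relative positions.
#' @inheritParams genomic_to_relative
#' @return Integer vector of genomic positions (`NA` when out of range).
#' @export
relative_to_genomic <- function(rel, exons, strand) {
  widths <- exons$end - exons$start + 1L
  before <- c(0L, cumsum(widths))
  total <- sum(widths)
  vapply(rel, function(r) {
    if (is.na(r) || r < 1L || r > total) return(NA_integer_)
    plus_rel <- if (strand == "+") r else total - r + 1L
    i <- findInterval(plus_rel - 1L, before)
    as.integer(exons$start[i] + (plus_rel - before[i]) - 1L)
  }, integer(1))
}
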