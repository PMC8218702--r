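# Build record tibbles in code for tests. `blocks` is given as the canonical
# "start-end,start-end" string ("" for none).
mk_records <- function(chrom = "chr1", strand = "+", start_pos = 100L,
                       stop_pos = 111L, splicing = "unspliced", blocks = "",
                       len_nt = NA_integer_, pep_len_aa = NA_integer_,
                       start_codon = NA_character_, nuc_seq = NA_character_,
                       pep_seq = NA_character_, transcript_ids = list(),
                       gene_ids = list(), cell_types = list(),
                       method = "riboseq", source_id = "test") {
  n <- max(lengths(list(chrom, strand, start_pos, stop_pos, splicing, blocks,
                        len_nt, method, source_id)),
           if (is.list(transcript_ids)) length(transcript_ids) else 0L,
           if (is.list(gene_ids)) length(gene_ids) else 0L,
           if (is.list(cell_types)) length(cell_types) else 0L)
  fill_list <- function(x) {
    if (length(x) == 0L) rep(list(character(0)), n)
    else if (is.list(x) && length(x) == n) x
    else rep(if (is.list(x)) x else list(x), length.out = n)
  }
  parse_blk <- function(s) {
    if (!nzchar(s)) return(data.frame(start = integer(0), end = integer(0)))
    pairs <- strsplit(strsplit(s, ",")[[1]], "-")
    out <- data.frame(start = as.integer(sapply(pairs, `[`, 1)),
                      end = as.integer(sapply(pairs, `[`, 2)))
    out[order(out$start), , drop = FALSE]
  }
  tibble::tibble(
    source_id = rep(source_id, length.out = n),
    record_id = paste0(rep(source_id, length.out = n), ":", seq_len(n)),
    chrom = rep(chrom, length.out = n),
    strand = rep(strand, length.out = n),
    start_pos = as.integer(rep(start_pos, length.out = n)),
    stop_pos = as.integer(rep(stop_pos, length.out = n)),
    splicing = rep(splicing, length.out = n),
    blocks = lapply(rep(blocks, length.out = n), parse_blk),
    len_nt = as.integer(rep(len_nt, length.out = n)),
    pep_len_aa = as.integer(rep(pep_len_aa, length.out = n)),
    start_codon = rep(start_codon, length.out = n),
    nuc_seq = rep(nuc_seq, length.out = n),
    pep_seq = rep(pep_seq, length.out = n),
    transcript_ids = fill_list(transcript_ids),
    gene_ids = fill_list(gene_ids),
    cell_types = fill_list(cell_types),
    method = rep(method, length.out = n),
    conservation = rep(list(character(0)), n)
  )
}
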