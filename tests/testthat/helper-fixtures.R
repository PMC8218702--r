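# One shared fixture bundle per seed, built lazily and reused across tests
# to keep the suite fast.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(seed = 1L) {
  key <- paste0("seed", seed)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("sorfkit_fx_", seed))
    .fixture_cache[[key]] <- make_genome_annotation(dir, seed = seed)
  }
  .fixture_cache[[key]]
}

# Fixture pipeline config from generated catalogs.
fixture_pipeline_config <- function(fx, cats, out_dir) {
  sorf_pipeline_config(
    sources = dplyr::mutate(cats$catalogs,
                            dialect = unname(cats$dialects[source_id])),
    gtf_path = fx$gtf_path,
    genome_path = fx$genome_path,
    out_dir = out_dir,
    cell_type_mapping = fx$cell_type_mapping
  )
}

# Uniques built straight from a fixture manifest (annotate-stage input).
manifest_to_uniques <- function(fx) {
  m <- fx$manifest
  recs <- mk_records(
    chrom = m$chrom, strand = m$strand, start_pos = m$start_pos,
    stop_pos = m$stop_pos, splicing = m$splicing, blocks = m$blocks,
    len_nt = m$len_nt,
    transcript_ids = as.list(m$transcript_id),
    gene_ids = as.list(m$gene_id)
  )
  merge_full(recs)$uniques
}
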