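#' Pipeline configuration
#'
#' Declares the inputs of an end-to-end repository build. `sources` is a
#' tibble with one row per catalog: `source_id`, `path`, `dialect` (list
#' column of [sorf_dialect()] objects) and `chain_path` (chain onto the
#' target assembly; `NA` to skip liftover for that source).
#'
#' @param sources Source table as above.
#' @param gtf_path,genome_path Annotation and genome of the target assembly.
#' @param out_dir Output directory.
#' @param cell_type_mapping Optional data frame (`raw`, `normalized`) or CSV
#'   path normalizing cell-type labels.
#' @param id_tag Prefix of stable ORF identifiers.
#' @param qc_threshold Mismatch-fraction rejection threshold (see
#'   [qc_source()]).
#' @param override_qc Keep sources that fail QC (audit use-cases).
#' @return A `sorf_pipeline_config` list; all referenced paths are checked
#'   to exist.
#' @export
sorf_pipeline_config <- function(sources, gtf_path, genome_path, out_dir,
                                 cell_type_mapping = NULL, id_tag = "ORF",
                                 qc_threshold = 0.95, override_qc = FALSE) {
  paths <- c(sources$path, sources$chain_path[!is.na(sources$chain_path)],
             gtf_path, genome_path,
             if (is.character(cell_type_mapping)) cell_type_mapping)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(sprintf("pipeline config references missing file(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (is.character(cell_type_mapping)) {
    cell_type_mapping <- readr::read_csv(cell_type_mapping,
                                         show_col_types = FALSE)
  }
  structure(
    list(sources = sources, gtf_path = gtf_path, genome_path = genome_path,
         out_dir = out_dir, cell_type_mapping = cell_type_mapping,
         id_tag = id_tag, qc_threshold = qc_threshold,
         override_qc = override_qc),
    class = "sorf_pipeline_config"
  )
}

#' Run the harmonization pipeline end to end
#'
#' Fixed stage order: ingest + per-source QC, liftover onto the target
#' assembly, two-phase redundancy merge, transcript attachment and
#' annotation (relative coordinates, classes, Kozak contexts, cell-type
#' normalization), then export (repository CSV, BED12, nucleotide and
#' peptide FASTA, QC report, merge audit, stats summary). Every input record
#' is accounted for in exactly one of: merged, dropped at source QC, dropped
#' at liftover, dropped at partial merge.
#'
#' @param config A [sorf_pipeline_config()].
#' @return A `sorf_pipeline` object: `uniques` (annotated unique-ORF
#'   tibble), `qc`, `lift_tally`, `merge_audit`, `stats` (one-row tibble),
#'   `paths` (written files). Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
run_sorf_pipeline <- function(config) {
  stopifnot(inherits(config, "sorf_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- stage 1: ingest + QC ------------------------------------------------
  per_source <- map(seq_len(nrow(config$sources)), function(i) {
    s <- config$sources[i, ]
    read_catalog(s$path, dialect = s$dialect[[1]], source_id = s$source_id)
  })
  qc <- bind_rows(map2(per_source, config$sources$source_id,
                       ~ qc_source(.x, source_id = .y,
                                   threshold = config$qc_threshold)))
  keep_src <- qc$accepted | config$override_qc
  n_input <- sum(map_int(per_source, nrow))
  dropped_qc <- sum(map_int(per_source[!keep_src], nrow))

  # --- stage 2: liftover ---------------------------------------------------
  lifted <- list()
  tallies <- list()
  dropped_lift <- 0L
  for (i in which(keep_src)) {
    recs <- per_source[[i]]
    cp <- config$sources$chain_path[i]
    if (!is.na(cp)) {
      res <- lift_catalog(recs, read_chain(cp))
      lifted[[length(lifted) + 1L]] <- res$records
      tallies[[length(tallies) + 1L]] <- res$tally
      dropped_lift <- dropped_lift + nrow(res$dropped)
    } else {
      lifted[[length(lifted) + 1L]] <- recs
    }
  }
  records <- bind_rows(lifted)
  lift_tally <- bind_rows(tallies) %>%
    group_by(.data$status) %>%
    summarise(n = sum(.data$n), .groups = "drop")

  # --- stage 3: two-phase merge -------------------------------------------
  merged <- merge_catalog(records)
  uniques <- merged$uniques

  # --- stage 4: annotation -------------------------------------------------
  txmodels <- read_annotation(config$gtf_path, config$genome_path)
  uniques <- fill_gene_ids(uniques, gene_extents(txmodels))
  uniques <- attach_transcripts(uniques, txmodels, config$genome_path)
  if (!is.null(config$cell_type_mapping)) {
    uniques <- normalize_cell_types(uniques, config$cell_type_mapping)
  }
  uniques <- assign_orf_ids(uniques, tag = config$id_tag)

  # --- stage 5: export -----------------------------------------------------
  paths <- list(
    repository = file.path(config$out_dir, "repository.csv"),
    bed = file.path(config$out_dir, "orfs.bed"),
    fasta_nt = file.path(config$out_dir, "orfs_nt.fa"),
    fasta_pep = file.path(config$out_dir, "orfs_pep.fa"),
    qc = file.path(config$out_dir, "qc_report.csv"),
    audit = file.path(config$out_dir, "merge_audit.csv"),
    stats = file.path(config$out_dir, "stats_summary.csv")
  )
  write_repository_csv(uniques, paths$repository)
  write_bed12(uniques, paths$bed)
  write_fasta(uniques, paths$fasta_nt, "nucleotide")
  write_fasta(uniques, paths$fasta_pep, "peptide")
  readr::write_csv(qc, paths$qc, progress = FALSE)
  readr::write_csv(merged$audit, paths$audit, progress = FALSE)

  stats <- pipeline_stats(uniques, n_input, dropped_qc, dropped_lift,
                          merged$dropped)
  readr::write_csv(stats, paths$stats, progress = FALSE)

  structure(
    list(uniques = uniques, qc = qc, lift_tally = lift_tally,
         merge_audit = merged$audit, stats = stats, paths = paths,
         config = config),
    class = "sorf_pipeline"
  )
}

# Repository-level summary counts (the shape of a database statistics
# table): totals, per-method tallies, transcript coverage, gene coverage.
pipeline_stats <- function(uniques, n_input, dropped_qc, dropped_lift,
                           dropped_partial) {
  methods <- uniques$methods
  tibble(
    n_input_records = n_input,
    n_unique_orfs = nrow(uniques),
    sum_experiment_count = sum(uniques$experiment_count),
    dropped_source_qc = dropped_qc,
    dropped_liftover = dropped_lift,
    dropped_partial_merge = dropped_partial,
    n_transcripts = length(union_multi(uniques$transcript_ids)),
    orfs_without_transcript = sum(map_int(uniques$transcript_ids, length) == 0L),
    orfs_predicted = sum(map_lgl(methods, ~ "prediction" %in% .x)),
    orfs_riboseq = sum(map_lgl(methods, ~ "riboseq" %in% .x)),
    orfs_ms = sum(map_lgl(methods, ~ "ms" %in% .x)),
    genes_with_sorf = length(union_multi(uniques$gene_ids)),
    orfs_with_class = sum(map_lgl(uniques$classes,
                                  ~ length(setdiff(.x, "intergenic")) > 0L))
  )
}

#' @export
print.sorf_pipeline <- function(x, ...) {
  cat(sprintf("<sorf_pipeline: %d unique ORFs from %d records (%d sources)>\n",
              x$stats$n_unique_orfs, x$stats$n_input_records,
              nrow(x$config$sources)))
  cat(sprintf("  dropped: %d source-QC, %d liftover, %d partial-merge\n",
              x$stats$dropped_source_qc, x$stats$dropped_liftover,
              x$stats$dropped_partial_merge))
  invisible(x)
}

#' Tidy the pipeline result into the per-ORF table
#'
#' @param x A `sorf_pipeline` object.
#' @param ... Unused.
#' @return The annotated unique-ORF tibble.
#' @method tidy sorf_pipeline
#' @export
tidy.sorf_pipeline <- function(x, ...) {
  x$uniques
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.sorf_pipeline
#' @return The stats tibble (counts per stage and per method).
#' @method glance sorf_pipeline
#' @export
glance.sorf_pipeline <- function(x, ...) {
  x$stats
}

#' Class-count bar plot of a built repository
#'
#' One bar per normalized ORF class, counting ORFs annotated with the class
#' (an ORF carrying several classes contributes to each).
#'
#' @param object A `sorf_pipeline` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sorf_pipeline
#' @export
autoplot.sorf_pipeline <- function(object, ...) {
  counts <- tibble(class = unlist(object$uniques$classes)) %>%
    count(.data$class)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$class, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "ORFs", title = "ORFs per class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Odds-ratio plot of enrichment results
#'
#' @param object A `sorf_enrichment` tibble from [enrich_genes()].
#' @param ... Unused.
#' @return A ggplot of odds ratios per gene list, significant lists
#'   (FDR < 0.05) highlighted.
#' @method autoplot sorf_enrichment
#' @export
autoplot.sorf_enrichment <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(significant = .data$fdr < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$list_name,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "odds ratio", y = NULL,
                  colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
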