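# Deterministic synthetic fixtures: a toy genome with planted transcripts
# and ORFs of designed class and Kozak context, plus redundant multi-source
# catalogs and matching chain files, all reproducible from an integer seed.
# The manifest written alongside is the ground truth the pipeline must
# recover exactly on uncorrupted fixtures.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)
  code
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

random_orf_seq <- function(len, start_codon = "ATG", second_codon = NULL) {
  stopifnot(len %% 3 == 0, len >= 9)
  n_body <- len / 3 - 2L
  body <- sample(NONSTOP_CODONS, n_body, replace = TRUE)
  if (!is.null(second_codon)) {
    body[1L] <- second_codon
  }
  paste0(start_codon, paste(body, collapse = ""), "TAA")
}

# Kozak designs: the 6-nt upstream flank and the constraint on the ORF's
# second codon (which carries the +4 position).
KOZAK_DESIGNS <- list(
  optimal = list(upstream = "GCCACC", second = "GCA"),
  strong = list(upstream = "TTTACC", second = "GGT"),
  moderate = list(upstream = "GCCACC", second = "TTT"),
  weak = list(upstream = "TTTTCC", second = "TTT")
)

#' Default fixture design
#'
#' One planted ORF per transcript, covering every normalized class, all four
#' Kozak categories, both strands, spliced and unspliced ORFs, and a
#' non-ATG ("Kozak-alike") start. Coding transcripts have a 150-nt 5' UTR, a
#' 300-nt CDS (stop codon included) and a 150-nt 3' UTR; `intron_after`
#' inserts a 100-nt intron after the given spliced position.
#'
#' @return A tibble with one row per planted transcript/ORF.
#' @export
fixture_plan <- function() {
  tibble::tribble(
    ~biotype, ~strand, ~intron_after, ~orf_class, ~kozak, ~start_codon,
    "protein_coding", "+", NA, "uORF", "optimal", "ATG",
    "protein_coding", "-", NA, "upstream-overlapping", "strong", "ATG",
    "protein_coding", "+", NA, "CDS-internal-altframe", "moderate", "ATG",
    "protein_coding", "-", 300, "CDS", "weak", "ATG",
    "protein_coding", "+", NA, "dORF", "strong", "ATG",
    "protein_coding", "-", NA, "downstream-overlapping", "weak", "ATG",
    "protein_coding", "+", 50, "uORF", "moderate", "ATG",
    "lncRNA", "+", NA, "ncRNA-ORF", "weak", "CTG",
    "nonsense_mediated_decay", "-", NA, "NMD-ORF", "strong", "ATG",
    "non_stop_decay", "+", NA, "NSD-ORF", "moderate", "ATG",
    "protein_coding", "-", NA, "uORF", "optimal", "ATG",
    "lncRNA", "-", 50, "ncRNA-ORF", "moderate", "CTG"
  )
}

#' Fixture configuration
#'
#' @param chrom_sizes Named integer vector of toy chromosome lengths.
#' @param plan Transcript/ORF design table (see [fixture_plan()]).
#' @param utr5,cds_len,utr3 Coding-transcript geometry in nucleotides
#'   (`cds_len` includes the stop codon).
#' @param intron_len Length of planted introns.
#' @return Config list for [make_genome_annotation()].
#' @export
fixture_config <- function(chrom_sizes = c(chr1 = 12000, chr2 = 12000),
                           plan = fixture_plan(), utr5 = 150L,
                           cds_len = 300L, utr3 = 150L, intron_len = 100L) {
  list(chrom_sizes = chrom_sizes, plan = plan, utr5 = utr5,
       cds_len = cds_len, utr3 = utr3, intron_len = intron_len)
}

# Relative ORF geometry for a designed class, given the coding geometry.
orf_geometry <- function(orf_class, utr5, cds_len) {
  cds_start <- utr5 + 1L
  cds_stop <- utr5 + cds_len
  switch(orf_class,
    "uORF" = c(start = 31L, len = 36L),
    "upstream-overlapping" = c(start = utr5 - 19L, len = 60L),
    "CDS-internal-altframe" = c(start = cds_start + 7L, len = 36L),
    "CDS" = c(start = cds_start, len = cds_len),
    "dORF" = c(start = cds_stop + 31L, len = 36L),
    "downstream-overlapping" = c(start = cds_stop - 20L, len = 60L),
    c(start = 31L, len = 36L) # ncRNA / NMD / NSD branches
  )
}

# Genomic blocks covered by a contiguous transcript-relative range.
rel_range_to_blocks <- function(rs, rl, exons, strand) {
  widths <- exons$end - exons$start + 1L
  # exon rel ranges in transcription order
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  rel_hi <- cumsum(widths[ord])
  rel_lo <- rel_hi - widths[ord] + 1L
  blocks <- list()
  for (k in seq_along(ord)) {
    a <- max(rs, rel_lo[k])
    b <- min(rl, rel_hi[k])
    if (a > b) next
    g <- relative_to_genomic(c(a, b), exons, strand)
    blocks[[length(blocks) + 1L]] <- data.frame(start = min(g), end = max(g))
  }
  out <- bind_rows(blocks)
  out[order(out$start), , drop = FALSE]
}

#' Generate a toy genome, annotation and ground-truth manifest
#'
#' Writes a random genome FASTA with planted transcripts whose spliced
#' sequences carry designed ORFs (start codon, stop-free body, stop codon)
#' in designed Kozak contexts, plus the matching GTF. Every planted ORF's
#' identity, class, Kozak category and sequences are recorded in the
#' manifest, which fully determines the expected pipeline output.
#' Generation is byte-reproducible from the seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config See [fixture_config()].
#' @return A fixture list: `dir`, `genome_path`, `gtf_path`,
#'   `manifest_path`, `manifest` (tibble), `txmodels`, `chrom_sizes`,
#'   `cell_type_mapping`, `config`.
#' @export
make_genome_annotation <- function(dir, seed = 1L, config = fixture_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plan <- config$plan
  sizes <- config$chrom_sizes
  with_seed(seed, {
    genome <- map_chr(sizes, random_dna)
    cursor <- setNames(rep(201L, length(sizes)), names(sizes))
    gtf <- list()
    manifest <- list()

    for (i in seq_len(nrow(plan))) {
      p <- plan[i, ]
      coding <- p$biotype %in% c("protein_coding")
      L <- if (coding) config$utr5 + config$cds_len + config$utr3 else 450L
      geom <- orf_geometry(p$orf_class, config$utr5, config$cds_len)
      if (geom[["start"]] + geom[["len"]] - 1L > L) {
        abort("fixture plan demands an ORF longer than its transcript")
      }

      # design the spliced transcript sequence
      seq <- random_dna(L)
      if (coding) {
        cds_seq <- random_orf_seq(config$cds_len)
        substr(seq, config$utr5 + 1L, config$utr5 + config$cds_len) <- cds_seq
      }
      kz <- KOZAK_DESIGNS[[p$kozak]]
      orf_seq <- random_orf_seq(geom[["len"]], p$start_codon, kz$second)
      rs <- geom[["start"]]
      rl <- rs + geom[["len"]] - 1L
      substr(seq, rs, rl) <- orf_seq
      substr(seq, rs - 6L, rs - 1L) <- kz$upstream

      # place on the genome
      chrom <- names(sizes)[(i - 1L) %% length(sizes) + 1L]
      has_intron <- !is.na(p$intron_after)
      g_len <- L + if (has_intron) config$intron_len else 0L
      g_start <- cursor[[chrom]]
      stopifnot(g_start + g_len - 1L <= sizes[[chrom]])
      cursor[[chrom]] <- g_start + g_len + 300L
      exons <- if (has_intron) {
        # intron_after is a spliced (transcription-order) position; on the
        # minus strand the genomic-first exon carries the transcript tail
        w1 <- if (p$strand == "+") p$intron_after else L - p$intron_after
        data.frame(
          start = c(g_start, g_start + w1 + config$intron_len),
          end = c(g_start + w1 - 1L, g_start + g_len - 1L)
        )
      } else {
        data.frame(start = g_start, end = g_start + L - 1L)
      }

      # imprint the transcript sequence into the genome, exon by exon
      widths <- exons$end - exons$start + 1L
      ord <- if (p$strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
      off <- 0L
      for (k in ord) {
        chunk <- substr(seq, off + 1L, off + widths[k])
        if (p$strand == "-") chunk <- reverse_complement(chunk)
        substr(genome[[chrom]], exons$start[k], exons$end[k]) <- chunk
        off <- off + widths[k]
      }

      tx_id <- sprintf("T%02d", i)
      gene_id <- sprintf("G%02d", i)
      attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                       gene_id, tx_id, p$biotype)
      gtf_row <- function(feature, s, e) {
        sprintf("%s\tsorfkit\t%s\t%d\t%d\t.\t%s\t.\t%s",
                chrom, feature, s, e, p$strand, attrs)
      }
      for (k in seq_len(nrow(exons))) {
        gtf[[length(gtf) + 1L]] <- gtf_row("exon", exons$start[k], exons$end[k])
      }
      if (coding) {
        cb <- rel_range_to_blocks(config$utr5 + 1L, config$utr5 + config$cds_len,
                                  exons, p$strand)
        for (k in seq_len(nrow(cb))) {
          gtf[[length(gtf) + 1L]] <- gtf_row("CDS", cb$start[k], cb$end[k])
        }
      }

      orf_blocks <- rel_range_to_blocks(rs, rl, exons, p$strand)
      g_ends <- relative_to_genomic(c(rs, rl), exons, p$strand)
      spliced <- nrow(orf_blocks) > 1L
      manifest[[length(manifest) + 1L]] <- tibble(
        orf_ref = sprintf("P%02d", i),
        chrom = chrom,
        strand = p$strand,
        start_pos = g_ends[1L],
        stop_pos = g_ends[2L],
        splicing = if (spliced) "spliced" else "unspliced",
        blocks = if (spliced) blocks_string(orf_blocks) else "",
        len_nt = geom[["len"]],
        pep_len_aa = geom[["len"]] %/% 3L - 1L,
        start_codon = p$start_codon,
        nuc_seq = orf_seq,
        pep_seq = as.character(Biostrings::translate(
          Biostrings::DNAString(substr(orf_seq, 1L, nchar(orf_seq) - 3L)))),
        transcript_id = tx_id,
        gene_id = gene_id,
        class = p$orf_class,
        kozak_category = p$kozak,
        kozak_alike = p$start_codon != "ATG"
      )
    }

    genome_path <- file.path(dir, "genome.fa")
    gset <- Biostrings::DNAStringSet(genome)
    names(gset) <- names(sizes)
    Biostrings::writeXStringSet(gset, genome_path)
    gtf_path <- file.path(dir, "annotation.gtf")
    writeLines(unlist(gtf), gtf_path)
    manifest <- bind_rows(manifest)
    manifest_path <- file.path(dir, "manifest.csv")
    readr::write_csv(manifest, manifest_path, progress = FALSE)

    list(
      dir = dir,
      genome_path = genome_path,
      gtf_path = gtf_path,
      manifest_path = manifest_path,
      manifest = manifest,
      txmodels = read_annotation(gtf_path, genome_path),
      chrom_sizes = sizes,
      cell_type_mapping = tibble(
        raw = c("HFF", "Human Foreskin Fibroblast", "HeLa", "hela", "Jurkat"),
        normalized = c("HFF", "HFF", "HeLa", "HeLa", "Jurkat")
      ),
      config = config
    )
  })
}

# Dialects for the two source-catalog styles the generator emits.
fixture_dialect <- function(style) {
  if (style == "plain") {
    sorf_dialect()
  } else {
    sorf_dialect(
      chrom = "chr", strand = "str", start = "orf_from", stop = "orf_to",
      splicing = "splice", blocks = "exon_coords", length_nt = "len_aa",
      start_codon = "codon", transcripts = "tx", genes = "gene",
      cell_types = "cells", method = "assay",
      length_unit = "aa", coord_style = "interval", multi_sep = ";",
      pep_length_aa = NULL, nuc_seq = NULL, pep_seq = NULL
    )
  }
}

#' Generate redundant multi-source catalogs with chain files
#'
#' Samples each planted ORF into `redundancy` of the `n_sources` sources,
#' writes one delimited catalog per source (odd-numbered sources use the
#' standard column layout, even-numbered ones an alternative layout with
#' interval-style coordinates and amino-acid lengths, exercising the dialect
#' machinery), plus a per-source chain file onto the fixture assembly.
#' Sources listed in `shift_sources` are written on a coordinate system
#' shifted `shift` nucleotides leftwards with a matching chain; all others
#' get an identity chain.
#'
#' Per-source corruption rates (each row suffers at most one corruption)
#' emulate real catalog heterogeneity: `drop_strand` (strand withheld),
#' `drop_stop` (stop coordinate withheld), `strip_blocks` (splice blocks
#' removed and the entry reported unspliced — the length-mismatch mode that
#' source QC must catch).
#'
#' @param fixture Fixture from [make_genome_annotation()].
#' @param seed Integer seed.
#' @param n_sources Number of sources.
#' @param redundancy Sources each ORF is planted in (capped at `n_sources`
#'   with a warning).
#' @param corruption Optional list: `corruption[[s]]` is a named list of
#'   rates for source `s`.
#' @param shift_sources Integer indices of sources on the shifted build.
#' @param shift Shift in nucleotides.
#' @return A list: `catalogs` (tibble of `source_id`, `path`, `style`,
#'   `chain_path`), `dialects` (named list), `expected_counts` (identity key
#'   to expected experiment count, exact for uncorrupted fixtures) and
#'   `records_planted` (rows emitted per source before corruption).
#' @export
make_catalogs <- function(fixture, seed = 1L, n_sources = 3L, redundancy = 2L,
                          corruption = NULL, shift_sources = integer(0),
                          shift = 10L) {
  if (redundancy > n_sources) {
    warn("make_catalogs: redundancy capped at the number of sources")
    redundancy <- n_sources
  }
  manifest <- fixture$manifest
  dir <- fixture$dir
  with_seed(seed + 1L, {
    assign_src <- map(seq_len(nrow(manifest)),
                      ~ sort(sample(n_sources, redundancy)))
    cats <- list()
    for (s in seq_len(n_sources)) {
      sid <- sprintf("src%d", s)
      style <- if (s %% 2L == 1L) "plain" else "alt"
      rows_idx <- which(map_lgl(assign_src, ~ s %in% .x))
      m <- manifest[rows_idx, , drop = FALSE]
      shift_s <- if (s %in% shift_sources) shift else 0L
      rates <- corruption[[s]] %||% list()
      df <- fixture_source_df(m, fixture, style, shift_s, rates)
      path <- file.path(dir, sprintf("%s.csv", sid))
      readr::write_csv(df, path, na = "", progress = FALSE)
      chain <- if (shift_s > 0L) {
        chain_shift(fixture$chrom_sizes - shift_s, shift_s)
      } else {
        chain_identity(fixture$chrom_sizes)
      }
      chain_path <- file.path(dir, sprintf("%s.chain", sid))
      write_chain(chain, chain_path)
      cats[[s]] <- tibble(source_id = sid, path = path, style = style,
                          chain_path = chain_path, n_rows = nrow(df))
    }
    keys <- identity_key(manifest %>% mutate(blocks = map(blocks, blocks_from_string)))
    list(
      catalogs = bind_rows(cats),
      dialects = set_names(
        map(bind_rows(cats)$style, fixture_dialect),
        bind_rows(cats)$source_id
      ),
      expected_counts = tibble(key = keys, orf_ref = manifest$orf_ref,
                               experiment_count = map_int(assign_src, length)),
      records_planted = bind_rows(cats) %>% select("source_id", "n_rows")
    )
  })
}

# Build the raw per-source data frame (in the source's own dialect) from
# manifest rows, applying the coordinate shift and at most one corruption
# per row.
fixture_source_df <- function(m, fixture, style, shift_s, rates) {
  n <- nrow(m)
  modes <- c("drop_strand", "drop_stop", "strip_blocks")
  pr <- vapply(modes, function(x) rates[[x]] %||% 0, numeric(1))
  chosen <- vapply(seq_len(n), function(i) {
    u <- runif(1)
    cum <- cumsum(pr)
    hit <- which(u < cum)
    if (length(hit) == 0L) "none" else modes[hit[1L]]
  }, "")

  start_pos <- m$start_pos - shift_s
  stop_pos <- m$stop_pos - shift_s
  blocks <- map_chr(m$blocks, function(b) {
    if (!nzchar(b)) return("")
    bl <- blocks_from_string(b)
    blocks_string(data.frame(start = bl$start - shift_s, end = bl$end - shift_s))
  })
  strand <- m$strand
  splicing <- m$splicing

  strand[chosen == "drop_strand"] <- NA_character_
  stop_pos[chosen == "drop_stop"] <- NA_integer_
  blocks[chosen == "strip_blocks"] <- ""
  splicing[chosen == "strip_blocks"] <- "unspliced"

  cells <- map_chr(seq_len(n), function(i) {
    paste(sample(fixture$cell_type_mapping$raw,
                 sample(1:2, 1)), collapse = ";")
  })
  method <- sample(c("prediction", "riboseq", "ms"), n, replace = TRUE)

  if (style == "plain") {
    tibble(
      chrom = m$chrom, strand = strand, start_pos = start_pos,
      stop_pos = stop_pos, splicing = splicing, blocks = blocks,
      length_nt = m$len_nt, start_codon = m$start_codon,
      transcripts = m$transcript_id, genes = m$gene_id,
      cell_types = gsub(";", "|", cells, fixed = TRUE), method = method
    )
  } else {
    # interval-style columns carry the (low, high) genomic bounds; rows with
    # a withheld stop keep the start codon coordinate in orf_from
    lo <- pmin(start_pos, stop_pos)
    hi <- pmax(start_pos, stop_pos)
    tibble(
      chr = m$chrom, str = strand,
      orf_from = if_else(is.na(stop_pos), start_pos, lo),
      orf_to = if_else(is.na(stop_pos), NA_integer_, hi),
      splice = splicing, exon_coords = blocks,
      len_aa = m$pep_len_aa, codon = m$start_codon,
      tx = m$transcript_id, gene = m$gene_id, cells = cells, assay = method
    )
  }
}
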