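two_exon_tx <- data.frame(start = c(1000L, 1200L), end = c(1099L, 1299L))

test_that("relative coordinates count along the spliced transcript", {
  expect_equal(genomic_to_relative(1250L, two_exon_tx, "+"), 151L)
  expect_equal(genomic_to_relative(1250L, two_exon_tx, "-"), 50L)
  expect_equal(genomic_to_relative(1000L, two_exon_tx, "+"), 1L)
  expect_equal(genomic_to_relative(1299L, two_exon_tx, "-"), 1L)
  # intronic and outside positions give the distinct not-exonic signal
  expect_true(is.na(genomic_to_relative(1150L, two_exon_tx, "+")))
  expect_true(is.na(genomic_to_relative(500L, two_exon_tx, "+")))
})

test_that("relative mapping is a bijection over exonic positions", {
  for (strand in c("+", "-")) {
    exonic <- c(1000:1099, 1200:1299)
    rel <- genomic_to_relative(exonic, two_exon_tx, strand)
    expect_setequal(rel, 1:200)
    expect_equal(relative_to_genomic(rel, two_exon_tx, strand), exonic)
  }
})

test_that("classification follows the decision table", {
  # coding transcript, CDS 101-400 (transcript-relative, stop included)
  cls <- function(s, e) classify_orf(s, e, "protein_coding", 101L, 400L)
  expect_equal(cls(10L, 60L), "uORF")
  expect_equal(cls(80L, 150L), "upstream-overlapping")
  expect_equal(cls(150L, 300L), "CDS-internal-altframe") # (150-101) %% 3 == 1
  expect_equal(cls(104L, 250L), "CDS")                   # in frame, internal
  expect_equal(cls(101L, 400L), "CDS")                   # exact coincidence
  expect_equal(cls(420L, 480L), "dORF")
  expect_equal(cls(390L, 450L), "downstream-overlapping")
  expect_equal(classify_orf(10L, 60L, "lncRNA", NA, NA), "ncRNA-ORF")
  expect_equal(classify_orf(10L, 60L, "nonsense_mediated_decay", NA, NA),
               "NMD-ORF")
  expect_equal(classify_orf(10L, 60L, "non_stop_decay", NA, NA), "NSD-ORF")
  expect_warning(
    expect_equal(classify_orf(10L, 60L, NA_character_, NA, NA), "ncRNA-ORF"),
    "biotype"
  )
})

test_that("Kozak categories match the canonical examples", {
  call_on <- function(context, codon_at = 7L) {
    kozak_call(context, codon_at)
  }
  opt <- call_on("GCCACCATGG")
  expect_equal(opt$category, "optimal")
  expect_false(opt$alike)
  expect_equal(call_on("TTTACCATGG")$category, "strong")
  expect_equal(call_on("GCCACCATGC")$category, "moderate")
  # non-ATG start, -3 pyrimidine but +4 G: one condition -> moderate, alike
  mod_alike <- call_on("TTTTCCCTGG")
  expect_equal(mod_alike$category, "moderate")
  expect_true(mod_alike$alike)
})

test_that("Kozak-alike applies the same positional tests to non-ATG starts", {
  res <- kozak_call("TTTACCCTGG", 7L)
  expect_equal(res$category, "strong")
  expect_true(res$alike)
})

test_that("contexts too close to the transcript ends are undefined", {
  expect_equal(kozak_call("ATGGCC", 1L)$category, "undefined")
  expect_equal(kozak_call("GCATGG", 3L)$category, "undefined")  # 2 nt upstream
  expect_equal(kozak_call("GCCACCATG", 7L)$category, "undefined") # no +4
})

test_that("Kozak categories partition all defined length-7 contexts", {
  nts <- c("A", "C", "G", "T")
  ctx <- expand.grid(m3 = nts, m2 = nts, m1 = nts, p1 = nts, p2 = nts,
                     p3 = nts, p4 = nts, stringsAsFactors = FALSE)
  upstream <- paste0(ctx$m3, ctx$m2, ctx$m1)
  cats <- kozak_category(upstream, ctx$p4)
  expect_equal(nrow(ctx), 4^7)
  expect_true(all(cats %in% c("strong", "moderate", "weak")))
  # with only 3 nt upstream the optimal prefix can never be established
  expect_false(any(cats == "optimal"))
  purine <- ctx$m3 %in% c("A", "G")
  g4 <- ctx$p4 == "G"
  expect_equal(cats == "strong", purine & g4)
  expect_equal(cats == "moderate", xor(purine, g4))
  expect_equal(cats == "weak", !purine & !g4)
})

test_that("every optimal context satisfies the strong conditions", {
  nts <- c("A", "C", "G", "T")
  six <- expand.grid(a = nts, b = nts, c = nts, d = nts, e = nts, f = nts,
                     stringsAsFactors = FALSE)
  upstream <- do.call(paste0, six)
  for (p4 in nts) {
    cats <- kozak_category(upstream, rep(p4, length(upstream)))
    opt <- cats == "optimal"
    if (any(opt)) {
      minus3 <- substr(upstream[opt], 4L, 4L)
      expect_true(all(minus3 %in% c("A", "G")))
      expect_true(p4 == "G")
      expect_true(all(grepl("^GCC[AG]CC$", upstream[opt])))
    }
  }
})

test_that("attachment completes sequences and flags unknown transcripts", {
  fx <- get_fixture(1)
  u <- manifest_to_uniques(fx)
  ann <- attach_transcripts(u, fx$txmodels, fx$genome_path)
  m <- fx$manifest
  key_m <- paste(m$chrom, m$strand, m$start_pos, m$stop_pos)
  key_u <- paste(ann$chrom, ann$strand, ann$start_pos, ann$stop_pos)
  idx <- match(key_u, key_m)
  expect_false(anyNA(idx))
  # extracted sequences equal the planted ground truth
  expect_equal(ann$nuc_seq, m$nuc_seq[idx])
  expect_equal(ann$pep_seq, m$pep_seq[idx])
  expect_equal(ann$start_codon, m$start_codon[idx])
  expect_equal(ann$pep_len_aa, m$pep_len_aa[idx])
  expect_true(all(ann$short_flag))
  expect_false(any(ann$frame_inconsistent))
  # ORF with a transcript ID absent from the annotation: retained, no class
  ghost <- manifest_to_uniques(fx)[1, ]
  ghost$transcript_ids <- list("T_MISSING")
  ghost_ann <- attach_transcripts(ghost, fx$txmodels, fx$genome_path)
  expect_equal(nrow(ghost_ann), 1L)
  expect_equal(ghost_ann$transcript_ids[[1]], character(0))
  expect_equal(ghost_ann$classes[[1]], "intergenic")
})

test_that("frame-inconsistent ORFs are flagged and retained", {
  fx <- get_fixture(1)
  u <- manifest_to_uniques(fx)[1, ]
  u$stop_pos <- u$stop_pos + 1L # span no longer a codon multiple
  u$nuc_seq <- NA_character_
  ann <- attach_transcripts(u, fx$txmodels, fx$genome_path)
  expect_true(ann$frame_inconsistent[1])
  expect_equal(nrow(ann), 1L)
})

test_that("cell-type labels normalize through the mapping table", {
  recs <- mk_records(cell_types = list(c("HFF", "Human Foreskin Fibroblast"),
                                       c("hela", "novellabel")))
  mapping <- tibble::tibble(
    raw = c("HFF", "Human Foreskin Fibroblast", "hela"),
    normalized = c("HFF", "HFF", "HeLa")
  )
  expect_warning(out <- normalize_cell_types(recs, mapping), "novellabel")
  expect_equal(out$cell_types[[1]], "HFF")
  expect_setequal(out$cell_types[[2]], c("HeLa", "novellabel"))
})
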