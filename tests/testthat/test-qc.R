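test_that("theoretical length is span minus introns, strand-symmetric", {
  recs <- mk_records(
    strand = c("+", "+", "-"),
    start_pos = c(100L, 100L, 111L),
    stop_pos = c(111L, 130L, 100L),
    splicing = c("unspliced", "spliced", "unspliced"),
    blocks = c("", "100-109,120-130", "")
  )
  expect_equal(theoretical_length(recs), c(12L, 21L, 12L))
  # block order in the string does not matter (canonicalized by sorting)
  recs2 <- mk_records(start_pos = 100L, stop_pos = 130L, splicing = "spliced",
                      blocks = "120-130,100-109")
  expect_equal(theoretical_length(recs2), 21L)
  # missing coordinate yields a distinct undefined result
  recs3 <- mk_records(stop_pos = NA_integer_)
  expect_true(is.na(theoretical_length(recs3)))
})

test_that("source rejection triggers strictly above 95% mismatch", {
  mismatched <- function(n) {
    mk_records(start_pos = seq_len(n) * 100L, stop_pos = seq_len(n) * 100L + 11L,
               len_nt = 99L)
  }
  matched <- function(n) {
    mk_records(start_pos = seq_len(n) * 100L, stop_pos = seq_len(n) * 100L + 11L,
               len_nt = 12L)
  }
  rep96 <- qc_source(dplyr::bind_rows(mismatched(96), matched(4)))
  expect_equal(rep96$mismatch_fraction, 0.96)
  expect_false(rep96$accepted)
  rep94 <- qc_source(dplyr::bind_rows(mismatched(94), matched(6)))
  expect_equal(rep94$mismatch_fraction, 0.94)
  expect_true(rep94$accepted)
  # exactly at the threshold the source is kept
  rep95 <- qc_source(dplyr::bind_rows(mismatched(95), matched(5)))
  expect_true(rep95$accepted)
})

test_that("QC verdict ignores record order and uncomputable lengths", {
  base <- dplyr::bind_rows(
    mk_records(start_pos = 1:50 * 10L, stop_pos = 1:50 * 10L + 11L, len_nt = 5L),
    mk_records(start_pos = 1:10 * 1000L, stop_pos = 1:10 * 1000L + 11L,
               len_nt = 12L),
    mk_records(start_pos = 1:40 * 7L, stop_pos = NA_integer_, len_nt = 12L)
  )
  r1 <- qc_source(base)
  set.seed(42)
  r2 <- qc_source(base[sample(nrow(base)), ])
  expect_equal(r1$mismatch_fraction, r2$mismatch_fraction)
  expect_equal(r1$accepted, r2$accepted)
  # the 40 records without a computable length stay out of the denominator
  expect_equal(r1$n_comparable, 60L)
  expect_equal(r1$mismatch_fraction, 50 / 60)
})

test_that("an empty source reports cleanly", {
  expect_warning(rep0 <- qc_source(mk_records()[0, ], source_id = "none"),
                 "no records")
  expect_equal(rep0$n_entries, 0L)
  expect_true(rep0$accepted)
})

test_that("gene recovery agrees with a brute-force overlap scan", {
  set.seed(7)
  genes <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:40),
    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
    strand = sample(c("+", "-"), 40, replace = TRUE),
    start = sample(1:5000, 40)
  )
  genes$end <- genes$start + sample(50:800, 40)
  recs <- mk_records(
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    strand = sample(c("+", "-"), 30, replace = TRUE),
    start_pos = sample(1:5500, 30)
  )
  recs$stop_pos <- recs$start_pos + 50L
  got <- recover_genes(recs, genes)
  for (i in seq_len(nrow(recs))) {
    hit <- genes$chrom == recs$chrom[i] &
      genes$start <= recs$stop_pos[i] & recs$start_pos[i] <= genes$end
    expect_setequal(got[[i]], genes$gene_id[hit])
    # strand-matched genes come first, each group sorted by ID
    same <- genes$strand[hit] == recs$strand[i]
    expect_equal(got[[i]], c(sort(genes$gene_id[hit][same]),
                             sort(genes$gene_id[hit][!same])))
  }
})

test_that("gene recovery handles containment, intergenic and overlapping genes", {
  genes <- tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    chrom = c("chr1", "chr1", "chr1"),
    strand = c("+", "+", "-"),
    start = c(400L, 540L, 3000L),
    end = c(1000L, 800L, 3100L)
  )
  recs <- mk_records(start_pos = c(450L, 2000L, 530L),
                     stop_pos = c(520L, 2050L, 560L))
  got <- recover_genes(recs, genes)
  expect_equal(got[[1]], "G1")     # containment
  expect_equal(got[[2]], character(0)) # intergenic
  expect_equal(got[[3]], c("G1", "G2")) # boundary of two overlapping genes
  # unknown chromosome: empty result plus a warning
  expect_warning(
    none <- recover_genes(mk_records(chrom = "chrZ"), genes),
    "absent"
  )
  expect_equal(none[[1]], character(0))
})
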