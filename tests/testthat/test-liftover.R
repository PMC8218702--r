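sizes <- c(chr1 = 10000L, chr2 = 8000L)

test_that("identity chain is a no-op and never fails", {
  recs <- mk_records(
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start_pos = c(100L, 511L, 1000L),
    stop_pos = c(111L, 500L, 1030L),
    splicing = c("unspliced", "unspliced", "spliced"),
    blocks = c("", "", "1000-1009,1020-1030")
  )
  res <- lift_catalog(recs, chain_identity(sizes))
  expect_equal(nrow(res$records), 3L)
  expect_equal(nrow(res$tally), 0L)
  expect_equal(res$records$start_pos, recs$start_pos)
  expect_equal(res$records$blocks, recs$blocks)
})

test_that("a rigid shift remaps every coordinate and preserves distance", {
  recs <- mk_records(start_pos = 100L, stop_pos = 111L)
  lifted <- lift_records(recs, chain_shift(sizes, 10L))
  expect_equal(lifted$lift_status, "ok")
  expect_equal(lifted$start_pos, 110L)
  expect_equal(lifted$stop_pos, 121L)
  expect_equal(abs(lifted$start_pos - lifted$stop_pos),
               abs(recs$start_pos - recs$stop_pos))
})

test_that("an insertion between start and stop fails the distance criterion", {
  recs <- mk_records(start_pos = 100L, stop_pos = 111L)
  lifted <- lift_records(recs, chain_insertion(sizes, "chr1", at = 105L, ins = 5L))
  # start stays at 100, stop moves to 116: distance 12 -> 17
  expect_equal(lifted$lift_status, "fail_distance")
  # an insertion outside the ORF shifts it rigidly instead
  ok <- lift_records(recs, chain_insertion(sizes, "chr1", at = 50L, ins = 5L))
  expect_equal(ok$lift_status, "ok")
  expect_equal(ok$start_pos, 105L)
})

test_that("coordinates falling in a chain gap are unmapped", {
  chain <- chain_deletion(sizes, "chr1", at = 105L, del = 3L)
  # the first record's start codon coordinate falls inside the deleted gap
  recs <- mk_records(start_pos = c(106L, 300L), stop_pos = c(117L, 311L))
  res <- lift_catalog(recs, chain)
  expect_equal(res$tally$status, "fail_unmapped")
  expect_equal(res$tally$n, 1L)
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$start_pos, 297L) # shifted left past the deletion
})

test_that("a uniform strand flip is accepted and flips the record strand", {
  recs <- mk_records(strand = "+", start_pos = 100L, stop_pos = 130L,
                     splicing = "spliced", blocks = "100-109,120-130")
  lifted <- lift_records(recs, chain_flip(sizes, "chr1"))
  expect_equal(lifted$lift_status, "ok")
  expect_equal(lifted$strand, "-")
  # position p maps to size - p + 1
  expect_equal(lifted$start_pos, 10000L - 100L + 1L)
  expect_equal(lifted$stop_pos, 10000L - 130L + 1L)
  expect_equal(lifted$blocks[[1]],
               data.frame(start = c(9871L, 9892L), end = c(9881L, 9901L)))
  expect_equal(abs(lifted$start_pos - lifted$stop_pos), 30L)
})

test_that("a chromosome change fails the chromosome criterion", {
  recs <- mk_records(start_pos = 100L, stop_pos = 111L)
  lifted <- lift_records(recs, chain_rename(sizes, "chr1", "chr9"))
  expect_equal(lifted$lift_status, "fail_chromosome")
})

test_that("lifting with a chain then its inverse restores coordinates", {
  fx <- get_fixture(1)
  recs <- manifest_to_uniques(fx) %>%
    dplyr::mutate(source_id = "m", record_id = paste0("m:", dplyr::row_number()),
                  method = "riboseq")
  for (chain in list(chain_shift(fx$chrom_sizes, 25L),
                     chain_flip(fx$chrom_sizes, "chr1"))) {
    fwd <- lift_records(recs, chain)
    expect_true(all(fwd$lift_status == "ok"))
    back <- lift_records(fwd %>% dplyr::select(-"lift_status"),
                         invert_chain(chain))
    expect_true(all(back$lift_status == "ok"))
    expect_equal(back$start_pos, recs$start_pos)
    expect_equal(back$stop_pos, recs$stop_pos)
    expect_equal(back$strand, recs$strand)
    expect_equal(back$blocks, recs$blocks)
  }
})

test_that("failure tally plus survivors conserves the input count", {
  chain <- chain_deletion(sizes, "chr1", at = 500L, del = 50L)
  set.seed(11)
  starts <- sample(100:900, 40) # some straddle / fall into the gap
  recs <- mk_records(start_pos = as.integer(starts),
                     stop_pos = as.integer(starts + 11L))
  res <- lift_catalog(recs, chain)
  expect_equal(nrow(res$records) + sum(res$tally$n), nrow(recs))
  expect_equal(nrow(res$dropped), sum(res$tally$n))
})

test_that("the native mapper agrees with rtracklayer liftOver", {
  chain_path <- withr::local_tempfile(fileext = ".chain")
  chain <- chain_insertion(sizes, "chr1", at = 400L, ins = 7L)
  write_chain(chain, chain_path)
  ch <- rtracklayer::import.chain(chain_path)
  pos <- c(10L, 399L, 400L, 401L, 2500L, 9999L)
  ours <- map_positions(chain, rep("chr1", length(pos)), pos)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos))
  theirs <- rtracklayer::liftOver(gr, ch)
  for (i in seq_along(pos)) {
    expect_equal(ours$pos[i], GenomicRanges::start(theirs[[i]])[1])
  }
})
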