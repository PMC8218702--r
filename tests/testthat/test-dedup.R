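test_that("identical fully described entries collapse with provenance unions", {
  recs <- mk_records(chrom = c("chr1", "chr1"), source_id = "x")
  recs$source_id <- c("a", "b")
  recs$record_id <- c("a:1", "b:1")
  res <- merge_full(recs)
  expect_equal(nrow(res$uniques), 1L)
  expect_equal(res$uniques$experiment_count, 2L)
  expect_equal(res$uniques$sources[[1]], c("a", "b"))
  expect_equal(nrow(res$leftovers), 0L)
})

test_that("splicing status difference keeps entries distinct", {
  recs <- mk_records(splicing = c("unspliced", "spliced"),
                     blocks = c("", "100-104,108-111"))
  res <- merge_full(recs)
  expect_equal(nrow(res$uniques), 2L)
  expect_equal(res$uniques$experiment_count, c(1L, 1L))
})

test_that("partial entries merge under the three documented patterns", {
  full <- mk_records(chrom = c("chr1", "chr1"), start_pos = c(100L, 300L),
                     stop_pos = c(111L, 311L))
  ph1 <- merge_full(full)
  # (i) strand + start
  lo1 <- mk_records(stop_pos = NA_integer_, source_id = "p1")
  # (ii) strand + stop
  lo2 <- mk_records(start_pos = NA_integer_, source_id = "p2")
  # (iii) start + stop, strand missing
  lo3 <- mk_records(strand = NA_character_, source_id = "p3")
  # no matching unique
  lo4 <- mk_records(start_pos = 999L, stop_pos = 1010L, source_id = "p4")
  # chromosome plus a single coordinate: never merged
  lo5 <- mk_records(strand = NA_character_, stop_pos = NA_integer_,
                    source_id = "p5")
  res <- merge_partial(dplyr::bind_rows(lo1, lo2, lo3, lo4, lo5), ph1$uniques)
  target <- which(res$uniques$start_pos == 100L)
  expect_equal(res$uniques$experiment_count[target], 4L)
  expect_equal(res$dropped, 2L)
  expect_equal(res$audit$outcome[res$audit$record_id == "p4:1"], "dropped")
  expect_equal(res$audit$outcome[res$audit$record_id == "p5:1"], "dropped")
  expect_match(res$audit$outcome[res$audit$record_id == "p1:1"], "chr1\\|\\+\\|100")
})

test_that("ambiguous partial entries go to the length-agreeing candidate", {
  full <- mk_records(chrom = c("chr1", "chr1"), strand = c("+", "+"),
                     start_pos = c(100L, 100L), stop_pos = c(111L, 120L),
                     len_nt = c(12L, 21L))
  ph1 <- merge_full(full)
  lo <- mk_records(stop_pos = NA_integer_, len_nt = 21L, source_id = "amb")
  res <- merge_partial(lo, ph1$uniques)
  absorbed <- which(res$uniques$experiment_count == 2L)
  expect_equal(res$uniques$stop_pos[absorbed], 120L)
})

test_that("conservation and idempotence hold", {
  recs <- random_catalog(101, 60)
  res <- merge_catalog(recs)
  expect_equal(sum(res$uniques$experiment_count) + res$dropped, nrow(recs))
  # feeding the merged set back in as a duplicate source doubles counts
  uniq <- res$uniques
  again <- mk_records(
    chrom = rep(uniq$chrom, 2L), strand = rep(uniq$strand, 2L),
    start_pos = rep(uniq$start_pos, 2L), stop_pos = rep(uniq$stop_pos, 2L),
    splicing = rep(uniq$splicing, 2L),
    blocks = rep(vapply(uniq$blocks, function(b) {
      if (nrow(b) == 0L) "" else paste(sprintf("%d-%d", b$start, b$end),
                                       collapse = ",")
    }, ""), 2L)
  )
  res2 <- merge_catalog(again)
  expect_equal(nrow(res2$uniques), nrow(uniq))
  expect_equal(sort(identity_key(res2$uniques)), sort(identity_key(uniq)))
  expect_equal(res2$uniques$experiment_count,
               rep(2L, nrow(uniq)))
})

test_that("merge outcome is invariant under input shuffling", {
  recs <- random_catalog(202, 80)
  res1 <- merge_catalog(recs)
  set.seed(99)
  res2 <- merge_catalog(recs[sample(nrow(recs)), ])
  k1 <- identity_key(res1$uniques)
  k2 <- identity_key(res2$uniques)
  expect_equal(sort(k1), sort(k2))
  expect_equal(res1$uniques$experiment_count[order(k1)],
               res2$uniques$experiment_count[order(k2)])
  expect_equal(res1$dropped, res2$dropped)
})

test_that("full merge equals the exhaustive pairwise oracle on catalogs <= 200", {
  for (seed in c(1, 2, 3)) {
    for (n in c(40, 120, 200)) {
      recs <- random_catalog(seed * 1000 + n, n)
      mine <- merge_full(recs)
      groups <- oracle_full_groups(recs)
      expect_equal(nrow(mine$uniques), length(unique(groups[!is.na(groups)])))
      expect_equal(sort(mine$uniques$experiment_count),
                   sort(as.integer(table(groups))))
      expect_equal(nrow(mine$leftovers), sum(is.na(groups)))
      # leftover absorption: every qualifying leftover that agrees with
      # exactly one unique on its provided fields must be absorbed
      res <- merge_partial(mine$leftovers, mine$uniques)
      expect_equal(sum(res$uniques$experiment_count) + res$dropped, n)
    }
  }
})
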