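# Exhaustive pairwise oracle for the full-merge phase: group records by
# comparing every pair on all six identification features directly.
oracle_full_groups <- function(recs) {
  n <- nrow(recs)
  same <- function(i, j) {
    bi <- recs$blocks[[i]]
    bj <- recs$blocks[[j]]
    identical(recs$chrom[i], recs$chrom[j]) &&
      identical(recs$strand[i], recs$strand[j]) &&
      identical(recs$start_pos[i], recs$start_pos[j]) &&
      identical(recs$stop_pos[i], recs$stop_pos[j]) &&
      identical(recs$splicing[i], recs$splicing[j]) &&
      nrow(bi) == nrow(bj) &&
      all(bi$start == bj$start) && all(bi$end == bj$end)
  }
  complete <- !is.na(recs$chrom) & !is.na(recs$strand) &
    !is.na(recs$start_pos) & !is.na(recs$stop_pos) &
    recs$splicing %in% c("spliced", "unspliced") &
    (recs$splicing != "spliced" | sapply(recs$blocks, nrow) > 0L)
  group <- rep(NA_integer_, n)
  next_g <- 0L
  for (i in which(complete)) {
    for (j in which(complete)) {
      if (j >= i) break
      if (same(i, j)) {
        group[i] <- group[j]
        break
      }
    }
    if (is.na(group[i])) {
      next_g <- next_g + 1L
      group[i] <- next_g
    }
  }
  group
}

random_catalog <- function(seed, n, n_keys = max(2L, n %/% 3L)) {
  set.seed(seed)
  keys <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n_keys, replace = TRUE),
    strand = sample(c("+", "-"), n_keys, replace = TRUE),
    low = sample(1:5000, n_keys)
  )
  pick <- sample(n_keys, n, replace = TRUE)
  len <- 12L
  recs <- mk_records(
    chrom = keys$chrom[pick],
    strand = keys$strand[pick],
    start_pos = ifelse(keys$strand[pick] == "+", keys$low[pick],
                       keys$low[pick] + len - 1L),
    stop_pos = ifelse(keys$strand[pick] == "+", keys$low[pick] + len - 1L,
                      keys$low[pick]),
    source_id = sample(sprintf("src%d", 1:4), n, replace = TRUE)
  )
  # knock out fields in some records to create leftovers
  drop <- sample(c("none", "strand", "stop", "splicing"), n, replace = TRUE,
                 prob = c(0.7, 0.1, 0.1, 0.1))
  recs$strand[drop == "strand"] <- NA
  recs$stop_pos[drop == "stop"] <- NA
  recs$splicing[drop == "splicing"] <- "unknown"
  recs
}


# Independent oracle: the upper-tail hypergeometric probability by exhaustive
# enumeration of all C(N, n) draws.
enumerate_tail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  feature <- seq_len(K) # first K elements carry the feature
  hits <- apply(draws, 2, function(d) sum(d %in% feature))
  mean(hits >= k)
}

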