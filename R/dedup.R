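first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA else x[[1L]]
}

union_multi <- function(lists) {
  sort(unique(unlist(lists)))
}

#' First merge phase: collapse fully described entries
#'
#' Entries providing every identification feature (chromosome, strand, start,
#' stop, splicing status and splice blocks) are grouped by identity key; each
#' group becomes one unique ORF whose `experiment_count` is the group size
#' and whose provenance fields (sources, methods, transcripts, genes, cell
#' types) are unions over the members. Entries with incomplete keys are
#' returned untouched as leftovers for [merge_partial()].
#'
#' @param records Record tibble (already lifted to one assembly).
#' @return A list with `uniques` (unique-ORF tibble) and `leftovers`.
#' @export
merge_full <- function(records) {
  key <- identity_key(records)
  complete <- !is.na(key)
  leftovers <- records[!complete, , drop = FALSE]
  full <- records[complete, , drop = FALSE]
  if (nrow(full) == 0L) {
    empty <- tibble(
      chrom = character(0), strand = character(0), start_pos = integer(0),
      stop_pos = integer(0), splicing = character(0), blocks = list(),
      experiment_count = integer(0), sources = list(), methods = list(),
      record_ids = list(), transcript_ids = list(), gene_ids = list(),
      cell_types = list(), len_nt = integer(0), pep_len_aa = integer(0),
      start_codon = character(0), nuc_seq = character(0),
      pep_seq = character(0), conservation = list()
    )
    return(list(uniques = empty, leftovers = leftovers))
  }
  groups <- split(seq_len(nrow(full)), key[complete])
  uniques <- bind_rows(map(groups, function(idx) {
    g <- full[idx, , drop = FALSE]
    tibble(
      chrom = g$chrom[1L],
      strand = g$strand[1L],
      start_pos = g$start_pos[1L],
      stop_pos = g$stop_pos[1L],
      splicing = g$splicing[1L],
      blocks = g$blocks[1L],
      experiment_count = nrow(g),
      sources = list(union_multi(g$source_id)),
      methods = list(union_multi(g$method)),
      record_ids = list(sort(g$record_id)),
      transcript_ids = list(union_multi(g$transcript_ids)),
      gene_ids = list(union_multi(g$gene_ids)),
      cell_types = list(union_multi(g$cell_types)),
      len_nt = first_non_na(g$len_nt),
      pep_len_aa = first_non_na(g$pep_len_aa),
      start_codon = first_non_na(g$start_codon),
      nuc_seq = first_non_na(g$nuc_seq),
      pep_seq = first_non_na(g$pep_seq),
      conservation = list(unlist(g$conservation)[
        !duplicated(names(unlist(g$conservation)))] %||% character(0))
    )
  }))
  uniques <- uniques %>% arrange(identity_key(uniques))
  list(uniques = uniques, leftovers = leftovers)
}

# Does a leftover qualify for partial matching? The chromosome plus one of
# the three documented field pairs must be present.
partial_qualifies <- function(records) {
  has_strand <- !is.na(records$strand)
  has_start <- !is.na(records$start_pos)
  has_stop <- !is.na(records$stop_pos)
  !is.na(records$chrom) &
    ((has_strand & has_start) | (has_strand & has_stop) | (has_start & has_stop))
}

#' Second merge phase: attach partially described entries
#'
#' Leftover entries providing the chromosome plus (i) strand and start, (ii)
#' strand and stop, or (iii) start and stop are merged into the best matching
#' unique ORF; all other leftovers, and qualifying ones without any match,
#' are dropped. Candidates must agree with the leftover on *every* field it
#' provides (including splicing status and blocks when present). "Best" is a
#' deterministic cascade: prefer candidates agreeing on reported length,
#' then on start codon, then on splicing status; then the highest
#' pre-existing experiment count; finally the lexicographically smallest
#' identity key. Matching is evaluated against a snapshot of the phase-one
#' output, so the result does not depend on leftover processing order.
#'
#' @param leftovers Leftover records from [merge_full()].
#' @param uniques Unique-ORF tibble from [merge_full()].
#' @return A list with `uniques` (updated), `dropped` (count) and `audit`
#'   (tibble mapping each leftover `record_id` to the absorbing identity key
#'   or `"dropped"`).
#' @export
merge_partial <- function(leftovers, uniques) {
  n_u <- nrow(uniques)
  if (nrow(leftovers) == 0L) {
    return(list(uniques = uniques, dropped = 0L,
                audit = tibble(record_id = character(0), outcome = character(0))))
  }
  ukeys <- if (n_u > 0L) identity_key(uniques) else character(0)
  snapshot_count <- uniques$experiment_count
  qualifies <- partial_qualifies(leftovers)
  assignment <- rep(NA_integer_, nrow(leftovers))

  for (i in which(qualifies)) {
    lo <- leftovers[i, ]
    cand <- rep(TRUE, n_u)
    if (!is.na(lo$chrom)) cand <- cand & uniques$chrom == lo$chrom
    if (!is.na(lo$strand)) cand <- cand & uniques$strand == lo$strand
    if (is.na(lo$strand) && !is.na(lo$start_pos) && !is.na(lo$stop_pos)) {
      # without a strand the two coordinates carry no orientation: compare
      # them as an unordered pair against the unique's genomic bounds
      cand <- cand &
        pmin(uniques$start_pos, uniques$stop_pos) ==
          min(lo$start_pos, lo$stop_pos) &
        pmax(uniques$start_pos, uniques$stop_pos) ==
          max(lo$start_pos, lo$stop_pos)
    } else {
      if (!is.na(lo$start_pos)) cand <- cand & uniques$start_pos == lo$start_pos
      if (!is.na(lo$stop_pos)) cand <- cand & uniques$stop_pos == lo$stop_pos
    }
    if (lo$splicing %in% c("spliced", "unspliced")) {
      cand <- cand & uniques$splicing == lo$splicing
      if (lo$splicing == "spliced" && nrow(lo$blocks[[1]]) > 0L) {
        cand <- cand &
          map_chr(uniques$blocks, blocks_string) == blocks_string(lo$blocks[[1]])
      }
    }
    idx <- which(cand)
    if (length(idx) == 0L) next
    if (length(idx) > 1L) {
      cand_len <- if_else(is.na(uniques$len_nt[idx]),
                          theoretical_length(uniques[idx, ]),
                          uniques$len_nt[idx])
      pref <- cbind(
        len = !is.na(lo$len_nt) & !is.na(cand_len) & cand_len == lo$len_nt,
        codon = !is.na(lo$start_codon) & !is.na(uniques$start_codon[idx]) &
          uniques$start_codon[idx] == lo$start_codon,
        splicing = lo$splicing %in% c("spliced", "unspliced") &
          uniques$splicing[idx] == lo$splicing
      )
      ord <- order(-pref[, "len"], -pref[, "codon"], -pref[, "splicing"],
                   -snapshot_count[idx], ukeys[idx])
      idx <- idx[ord]
    }
    assignment[i] <- idx[1L]
  }

  for (i in which(!is.na(assignment))) {
    j <- assignment[i]
    lo <- leftovers[i, ]
    uniques$experiment_count[j] <- uniques$experiment_count[j] + 1L
    uniques$sources[[j]] <- union_multi(c(uniques$sources[j], list(lo$source_id)))
    uniques$methods[[j]] <- union_multi(c(uniques$methods[j], lo$method))
    uniques$record_ids[[j]] <- sort(c(uniques$record_ids[[j]], lo$record_id))
    uniques$transcript_ids[[j]] <-
      union_multi(c(uniques$transcript_ids[j], lo$transcript_ids))
    uniques$gene_ids[[j]] <- union_multi(c(uniques$gene_ids[j], lo$gene_ids))
    uniques$cell_types[[j]] <- union_multi(c(uniques$cell_types[j], lo$cell_types))
  }

  audit <- tibble(
    record_id = leftovers$record_id,
    outcome = if_else(is.na(assignment), "dropped", ukeys[assignment])
  )
  list(uniques = uniques, dropped = sum(is.na(assignment)), audit = audit)
}

#' Two-phase merge of a lifted catalog
#'
#' Convenience wrapper running [merge_full()] then [merge_partial()].
#'
#' @inheritParams merge_full
#' @return A list with `uniques`, `dropped` and `audit` (see
#'   [merge_partial()]).
#' @export
merge_catalog <- function(records) {
  ph1 <- merge_full(records)
  merge_partial(ph1$leftovers, ph1$uniques)
}
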