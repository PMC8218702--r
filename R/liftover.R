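#' Lift ORF records onto a destination assembly
#'
#' Every genomic coordinate of a record — start, stop and each splice-block
#' bound — is remapped independently through the chain. The lift of a record
#' fails when, checking in this fixed order:
#'
#' 1. `fail_unmapped`: a present coordinate has no chain interval;
#' 2. `fail_strand`: the remapped positions do not agree on strand
#'    orientation (a *uniform* flip of all positions together is accepted and
#'    recorded by flipping the record's strand);
#' 3. `fail_chromosome`: the chromosome of a position changed, or positions
#'    disagree on chromosome;
#' 4. `fail_distance`: the genomic distance `|start - stop|` between the
#'    start and stop codons changed.
#'
#' Successful records carry fully remapped coordinates with splice blocks
#' re-sorted (and per-block bounds swapped after a uniform flip).
#'
#' @param records Record tibble.
#' @param chain A `sorf_chain` (see [read_chain()]).
#' @return Tibble of the input records plus a `lift_status` column with
#'   values `ok` or the failure codes above; `ok` rows are remapped.
#' @export
lift_records <- function(records, chain) {
  out <- records
  status <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    res <- lift_one(records[i, ], chain)
    status[i] <- res$status
    if (res$status == "ok") {
      out$chrom[i] <- res$record$chrom
      out$strand[i] <- res$record$strand
      out$start_pos[i] <- res$record$start_pos
      out$stop_pos[i] <- res$record$stop_pos
      out$blocks[[i]] <- res$record$blocks[[1]]
    }
  }
  out$lift_status <- status
  out
}

lift_one <- function(record, chain) {
  blocks <- record$blocks[[1]]
  coords <- c(record$start_pos, record$stop_pos, blocks$start, blocks$end)
  roles <- c("start", "stop", rep("blk_start", nrow(blocks)),
             rep("blk_end", nrow(blocks)))
  present <- !is.na(coords)
  if (!any(present)) {
    return(list(status = "ok", record = record)) # nothing to remap
  }
  mapped <- map_positions(chain, rep(record$chrom, sum(present)),
                          coords[present])
  if (!all(mapped$mapped)) {
    return(list(status = "fail_unmapped", record = record))
  }
  if (length(unique(mapped$flipped)) > 1L) {
    return(list(status = "fail_strand", record = record))
  }
  if (length(unique(mapped$chrom)) > 1L ||
      any(mapped$chrom != record$chrom)) {
    return(list(status = "fail_chromosome", record = record))
  }
  new_coords <- coords
  new_coords[present] <- mapped$pos
  new_start <- new_coords[roles == "start"]
  new_stop <- new_coords[roles == "stop"]
  if (!is.na(record$start_pos) && !is.na(record$stop_pos) &&
      abs(new_start - new_stop) != abs(record$start_pos - record$stop_pos)) {
    return(list(status = "fail_distance", record = record))
  }
  flipped <- mapped$flipped[1L]
  rec <- record
  rec$start_pos <- as.integer(new_start)
  rec$stop_pos <- as.integer(new_stop)
  if (flipped && !is.na(rec$strand)) {
    rec$strand <- if (rec$strand == "+") "-" else "+"
  }
  if (nrow(blocks) > 0L) {
    bs <- new_coords[roles == "blk_start"]
    be <- new_coords[roles == "blk_end"]
    nb <- data.frame(start = as.integer(pmin(bs, be)),
                     end = as.integer(pmax(bs, be)))
    nb <- nb[order(nb$start), , drop = FALSE]
    rownames(nb) <- NULL
    rec$blocks[[1]] <- nb
  }
  list(status = "ok", record = rec)
}

#' Lift a whole catalog, dropping failures
#'
#' Applies [lift_records()] and removes entries whose liftover failed,
#' tallying failures by status.
#'
#' @inheritParams lift_records
#' @return A list with `records` (ok entries, remapped), `tally` (tibble of
#'   `status`/`n` for failures) and `dropped` (the failed entries with their
#'   `lift_status`).
#' @export
lift_catalog <- function(records, chain) {
  lifted <- lift_records(records, chain)
  ok <- lifted$lift_status == "ok"
  tally <- lifted %>%
    filter(!ok) %>%
    count(status = .data$lift_status, name = "n")
  list(
    records = lifted %>% filter(ok) %>% select(-"lift_status"),
    tally = tally,
    dropped = lifted %>% filter(!ok)
  )
}
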