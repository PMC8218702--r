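# UCSC chain files describe ungapped aligned segments between a source
# ("target" in chain-speak, t) and a destination ("query", q) assembly.
# Internally a chain is a tibble of ungapped segments with 0-based half-open
# source coordinates; query coordinates are given on the query strand (i.e.
# on the reversed sequence when q_strand == "-"), exactly as in the format.

new_chain <- function(segments) {
  stopifnot(all(c("t_chrom", "t_size", "t_start", "t_end", "q_chrom",
                  "q_size", "q_strand", "q_start") %in% names(segments)))
  structure(as_tibble(segments), class = c("sorf_chain", class(tibble())))
}

#' Read a UCSC chain file
#'
#' @param path Chain file (plain text).
#' @return A `sorf_chain` tibble of ungapped aligned segments.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  segs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "chain")) {
      i <- i + 1L
      next
    }
    h <- strsplit(lines[i], "\\s+")[[1]]
    if (length(h) < 12L) {
      abort(sprintf("malformed chain header at line %d of %s", i, path))
    }
    t_chrom <- h[3]; t_size <- as.numeric(h[4]); t_cur <- as.numeric(h[6])
    q_chrom <- h[8]; q_size <- as.numeric(h[9]); q_strand <- h[10]
    q_cur <- as.numeric(h[11])
    i <- i + 1L
    repeat {
      if (i > length(lines) || !nzchar(lines[i])) {
        i <- i + 1L
        break
      }
      parts <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
      size <- parts[1]
      segs[[length(segs) + 1L]] <- tibble(
        t_chrom = t_chrom, t_size = t_size,
        t_start = t_cur, t_end = t_cur + size,
        q_chrom = q_chrom, q_size = q_size,
        q_strand = q_strand, q_start = q_cur
      )
      if (length(parts) == 1L) {
        i <- i + 1L
        break
      }
      t_cur <- t_cur + size + parts[2]
      q_cur <- q_cur + size + parts[3]
      i <- i + 1L
    }
  }
  new_chain(bind_rows(segs))
}

#' Write a chain object to a UCSC chain file
#'
#' Each ungapped segment is emitted as its own single-block chain record,
#' which any chain consumer accepts.
#'
#' @param chain A `sorf_chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(chain))) {
    s <- chain[i, ]
    size <- s$t_end - s$t_start
    writeLines(sprintf("chain %d %s %d + %d %d %s %d %s %d %d %d",
                       size, s$t_chrom, s$t_size, s$t_start, s$t_end,
                       s$q_chrom, s$q_size, s$q_strand, s$q_start,
                       s$q_start + size, i), con)
    writeLines(as.character(size), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Invert a chain
#'
#' Produces the chain mapping the destination assembly back onto the source,
#' so lifting with a chain and then its inverse restores every mappable
#' coordinate.
#'
#' @param chain A `sorf_chain`.
#' @return The inverted `sorf_chain`.
#' @export
invert_chain <- function(chain) {
  plus <- chain$q_strand == "+"
  size <- chain$t_end - chain$t_start
  new_chain(tibble(
    t_chrom = chain$q_chrom,
    t_size = chain$q_size,
    t_start = if_else(plus, chain$q_start, chain$q_size - chain$q_start - size),
    t_end = if_else(plus, chain$q_start + size, chain$q_size - chain$q_start),
    q_chrom = chain$t_chrom,
    q_size = chain$t_size,
    q_strand = if_else(plus, "+", "-"),
    q_start = if_else(plus, chain$t_start, chain$t_size - chain$t_end)
  ))
}

#' Map genomic positions through a chain
#'
#' @param chain A `sorf_chain`.
#' @param chrom Character vector of chromosomes (source assembly).
#' @param pos Integer vector of 1-based positions.
#' @return Tibble with one row per input position: `chrom` and `pos` on the
#'   destination assembly (plus-strand coordinates), `flipped` (the segment
#'   aligns to the reverse strand) and `mapped`. Unmapped positions have
#'   `NA` coordinates.
#' @export
map_positions <- function(chain, chrom, pos) {
  n <- length(pos)
  out <- tibble(chrom = rep(NA_character_, n), pos = rep(NA_integer_, n),
                flipped = rep(NA, n), mapped = rep(FALSE, n))
  for (i in seq_len(n)) {
    if (is.na(chrom[i]) || is.na(pos[i])) next
    x <- pos[i] - 1L # to 0-based
    hit <- which(chain$t_chrom == chrom[i] & chain$t_start <= x & x < chain$t_end)
    if (length(hit) == 0L) next
    s <- chain[hit[1L], ]
    q0 <- s$q_start + (x - s$t_start)
    if (s$q_strand == "-") {
      q0 <- s$q_size - 1L - q0
    }
    out$chrom[i] <- s$q_chrom
    out$pos[i] <- as.integer(q0 + 1L)
    out$flipped[i] <- s$q_strand == "-"
    out$mapped[i] <- TRUE
  }
  out
}

# --- synthetic chain constructors (used by fixtures and tests) -------------

#' Synthetic chains between toy assemblies
#'
#' Constructors for the chain operations the fixture generator plants:
#' `chain_identity` maps every chromosome onto itself unchanged;
#' `chain_shift` shifts all positions of every chromosome by a constant;
#' `chain_insertion` inserts `ins` destination bases at source position `at`
#' of one chromosome (positions at or beyond `at` shift right);
#' `chain_deletion` removes `del` source bases starting at `at` (those
#' positions become unmappable); `chain_flip` maps one chromosome onto the
#' reverse strand of the destination; `chain_rename` maps one chromosome
#' onto a differently named destination chromosome.
#'
#' @param sizes Named integer vector of chromosome lengths (source assembly).
#' @param shift,chrom,at,ins,del,to Operation parameters; `at` is 1-based.
#' @return A `sorf_chain`.
#' @name synthetic_chains
NULL

chain_skeleton <- function(sizes) {
  tibble(
    t_chrom = names(sizes), t_size = unname(sizes),
    t_start = 0, t_end = unname(sizes),
    q_chrom = names(sizes), q_size = unname(sizes),
    q_strand = "+", q_start = 0
  )
}

#' @rdname synthetic_chains
#' @export
chain_identity <- function(sizes) {
  new_chain(chain_skeleton(sizes))
}

#' @rdname synthetic_chains
#' @export
chain_shift <- function(sizes, shift) {
  segs <- chain_skeleton(sizes)
  segs$q_size <- segs$q_size + shift
  segs$q_start <- shift
  new_chain(segs)
}

#' @rdname synthetic_chains
#' @export
chain_insertion <- function(sizes, chrom, at, ins) {
  segs <- chain_skeleton(sizes)
  i <- which(segs$t_chrom == chrom)
  stopifnot(length(i) == 1L, at > 1, at <= sizes[[chrom]])
  cut <- at - 1 # 0-based boundary
  left <- segs[i, ]
  left$t_end <- cut
  left$q_size <- left$q_size + ins
  right <- segs[i, ]
  right$t_start <- cut
  right$q_start <- cut + ins
  right$q_size <- right$q_size + ins
  new_chain(bind_rows(segs[-i, ], left, right))
}

#' @rdname synthetic_chains
#' @export
chain_deletion <- function(sizes, chrom, at, del) {
  segs <- chain_skeleton(sizes)
  i <- which(segs$t_chrom == chrom)
  stopifnot(length(i) == 1L, at + del - 1 <= sizes[[chrom]])
  cut <- at - 1
  left <- segs[i, ]
  left$t_end <- cut
  left$q_size <- left$q_size - del
  right <- segs[i, ]
  right$t_start <- cut + del
  right$q_start <- cut
  right$q_size <- right$q_size - del
  new_chain(bind_rows(segs[-i, ], left, right))
}

#' @rdname synthetic_chains
#' @export
chain_flip <- function(sizes, chrom) {
  segs <- chain_skeleton(sizes)
  i <- which(segs$t_chrom == chrom)
  segs$q_strand[i] <- "-"
  segs$q_start[i] <- 0
  new_chain(segs)
}

#' @rdname synthetic_chains
#' @export
chain_rename <- function(sizes, chrom, to) {
  segs <- chain_skeleton(sizes)
  segs$q_chrom[segs$t_chrom == chrom] <- to
  new_chain(segs)
}
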