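# Internal helpers shared across modules.

# Parse a splice-block string like "100-109,120-130" (also accepts ";" as the
# pair separator) into a two-column integer data.frame sorted by start.
# Returns NULL when the string is malformed: non-numeric bounds, start > end,
# or overlapping blocks.
parse_blocks <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(empty_blocks())
  }
  pairs <- strsplit(trimws(x), "[,;]")[[1]]
  pairs <- pairs[nzchar(trimws(pairs))]
  m <- regmatches(pairs, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", pairs))
  if (any(lengths(m) != 3L)) {
    return(NULL)
  }
  starts <- as.integer(vapply(m, `[`, "", 2L))
  ends <- as.integer(vapply(m, `[`, "", 3L))
  if (any(is.na(starts)) || any(is.na(ends)) || any(starts > ends)) {
    return(NULL)
  }
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)])) {
    return(NULL) # overlapping blocks
  }
  data.frame(start = starts, end = ends)
}

empty_blocks <- function() {
  data.frame(start = integer(0), end = integer(0))
}

# Canonical comma-joined "start-end" representation, sorted by start.
# Empty string for no blocks.
blocks_string <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L) {
    return("")
  }
  o <- order(blocks$start)
  paste(sprintf("%d-%d", blocks$start[o], blocks$end[o]), collapse = ",")
}

blocks_from_string <- function(x) {
  b <- parse_blocks(x)
  if (is.null(b)) empty_blocks() else b
}

# Sum of intron gaps between consecutive blocks (0 for <= 1 block).
intron_length <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) <= 1L) {
    return(0L)
  }
  o <- order(blocks$start)
  s <- blocks$start[o]
  e <- blocks$end[o]
  sum(s[-1L] - e[-length(e)] - 1L)
}

# Collapse a character vector into a "|"-joined scalar (NA-safe).
collapse_multi <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_character_ else paste(x, collapse = "|")
}

split_multi <- function(x, sep = "|") {
  if (is.na(x) || !nzchar(x)) {
    return(character(0))
  }
  trimws(strsplit(x, sep, fixed = TRUE)[[1]])
}

as_int_quiet <- function(x) {
  suppressWarnings(as.integer(x))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
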