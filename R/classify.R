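#' Normalized ORF class labels
#'
#' The classes assigned per ORF-transcript association. The coding-transcript
#' branch compares transcript-relative ORF coordinates with the canonical CDS
#' (stop codon included); NMD and NSD classes are assigned purely from the
#' transcript biotype; all other biotypes (and transcripts without a usable
#' biotype or CDS) yield `ncRNA-ORF`; ORFs with no transcript association
#' are `intergenic` at the ORF level.
#'
#' @format Character vector of valid labels.
#' @export
orf_classes <- c(
  "uORF", "upstream-overlapping", "CDS-internal-altframe", "CDS",
  "dORF", "downstream-overlapping", "ncRNA-ORF", "NMD-ORF", "NSD-ORF",
  "intergenic"
)

#' Classify an ORF relative to one transcript
#'
#' Decision table (first match wins):
#'
#' * biotype `nonsense_mediated_decay` -> `NMD-ORF`; `non_stop_decay` ->
#'   `NSD-ORF`;
#' * on a coding transcript with an annotated CDS (`cds_start`..`cds_stop`,
#'   transcript-relative, stop codon included):
#'   ORF entirely before the CDS -> `uORF`; straddling the CDS start ->
#'   `upstream-overlapping`; entirely after the CDS -> `dORF`; straddling
#'   the CDS stop -> `downstream-overlapping`; inside the CDS in the CDS
#'   reading frame -> `CDS` (exact coincidence is the canonical case);
#'   inside the CDS out of frame -> `CDS-internal-altframe`;
#' * any other (or missing) biotype -> `ncRNA-ORF`.
#'
#' @param rel_start,rel_stop 1-based transcript-relative ORF bounds
#'   (`rel_start < rel_stop` in transcription orientation).
#' @param biotype Transcript biotype string (may be `NA`).
#' @param cds_start,cds_stop Transcript-relative CDS bounds (`NA` when
#'   non-coding).
#' @return One label from [orf_classes].
#' @export
classify_orf <- function(rel_start, rel_stop, biotype, cds_start, cds_stop) {
  if (is.na(biotype)) {
    warn("classify_orf: transcript without biotype; classified as ncRNA-ORF")
    return("ncRNA-ORF")
  }
  if (biotype == "nonsense_mediated_decay") return("NMD-ORF")
  if (biotype == "non_stop_decay") return("NSD-ORF")
  if (biotype != "protein_coding" || is.na(cds_start) || is.na(cds_stop)) {
    return("ncRNA-ORF")
  }
  if (rel_stop < cds_start) return("uORF")
  if (rel_start < cds_start) return("upstream-overlapping")
  if (rel_start > cds_stop) return("dORF")
  if (rel_stop > cds_stop) return("downstream-overlapping")
  if ((rel_start - cds_start) %% 3L == 0L) return("CDS")
  "CDS-internal-altframe"
}

#' Kozak context category of a start codon
#'
#' The context is read on the spliced transcript sequence around the start
#' codon (first codon nucleotide at relative position +1): positions -6..-1
#' upstream and +4 immediately downstream. Categories follow the classic
#' -3 purine / +4 G dichotomy:
#'
#' * `optimal`: upstream matches `gcc[AG]cc` (i.e. positions -6..-1 are
#'   `GCCRCC`) *and* +4 is `G`;
#' * `strong`: -3 is a purine and +4 is `G` (and not optimal);
#' * `moderate`: exactly one of the two conditions holds;
#' * `weak`: neither holds;
#' * `undefined`: fewer than 3 nucleotides upstream or 1 downstream
#'   available.
#'
#' The same positional tests are applied around non-ATG start codons
#' ("Kozak-alike" contexts, `alike = TRUE`).
#'
#' @param tx_seq Spliced transcript sequence.
#' @param start_rel 1-based relative position of the first codon nucleotide.
#' @return A one-row tibble: `category`, `alike`, `context` (the -6..+4
#'   window, `.`-padded where unavailable).
#' @export
kozak_call <- function(tx_seq, start_rel) {
  n <- nchar(tx_seq)
  if (is.na(tx_seq) || is.na(start_rel) || start_rel < 1L || start_rel + 2L > n) {
    return(tibble(category = "undefined", alike = NA, context = NA_character_))
  }
  codon <- toupper(substr(tx_seq, start_rel, start_rel + 2L))
  up_from <- max(1L, start_rel - 6L)
  upstream <- toupper(substr(tx_seq, up_from, start_rel - 1L))
  plus4 <- if (start_rel + 3L <= n) {
    toupper(substr(tx_seq, start_rel + 3L, start_rel + 3L))
  } else {
    ""
  }
  category <- kozak_category(upstream, plus4)
  context <- paste0(
    strrep(".", 6L - nchar(upstream)), upstream, codon,
    if (nzchar(plus4)) plus4 else "."
  )
  tibble(category = category, alike = codon != "ATG", context = context)
}

#' Kozak category from the flanking nucleotides alone
#'
#' Positional test shared by [kozak_call()] and the exhaustive-enumeration
#' checks: `upstream` holds up to 6 nucleotides immediately 5' of the start
#' codon and `plus4` the nucleotide immediately 3' of it.
#'
#' @param upstream Character vector of upstream flanks (0-6 nt each).
#' @param plus4 Character vector of +4 nucleotides (`""` when unavailable).
#' @return Character vector of categories.
#' @export
kozak_category <- function(upstream, plus4) {
  upstream <- toupper(upstream)
  plus4 <- toupper(plus4)
  n_up <- nchar(upstream)
  minus3 <- substr(upstream, n_up - 2L, n_up - 2L)
  purine3 <- minus3 %in% c("A", "G")
  g4 <- plus4 == "G"
  optimal <- n_up >= 6L & grepl("^GCC[AG]CC$", substr(upstream, n_up - 5L, n_up)) & g4
  out <- rep("weak", length(upstream))
  out[xor(purine3, g4)] <- "moderate"
  out[purine3 & g4] <- "strong"
  out[optimal] <- "optimal"
  out[n_up < 3L | !nzchar(plus4)] <- "undefined"
  out
}
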