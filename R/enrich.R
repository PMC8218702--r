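#' Over-representation of a gene set in gene lists
#'
#' For each gene list, tests whether the list is enriched in genes belonging
#' to the feature set (e.g. genes harboring at least one uORF) relative to a
#' gene universe. Both the list and the feature set are intersected with the
#' universe before counting. With `N` the universe size, `K` the feature-set
#' size in the universe, `n` the list size in the universe and `k` the
#' intersection, the p-value is the upper-tail hypergeometric probability
#' `P(X >= k)` (computed on the log scale, so magnitudes down to ~1e-61 and
#' below survive) and the odds ratio the sample cross-product ratio
#' `k (N - n - K + k) / ((n - k) (K - k))`. P-values are Benjamini-Hochberg
#' adjusted across all lists tested; FDR < 0.05 is the conventional
#' significance threshold.
#'
#' @param lists Named list of character vectors of gene IDs (or a single
#'   character vector).
#' @param feature_set Character vector of gene IDs carrying the feature.
#' @param universe Character vector of gene IDs; must be non-empty.
#' @return A tibble with one row per list: `list_name`, `n_list` (n),
#'   `n_feature` (K), `n_overlap` (k), `n_universe` (N), `p_value`, `fdr`,
#'   `odds_ratio`. Classed `sorf_enrichment` for [autoplot()].
#' @export
#' @examples
#' universe <- paste0("G", 1:100)
#' enrich_genes(list(demo = paste0("G", 1:10)), paste0("G", 1:50), universe)
enrich_genes <- function(lists, feature_set, universe) {
  stopifnot(length(universe) > 0L)
  if (!is.list(lists)) {
    lists <- list(list = lists)
  }
  if (is.null(names(lists))) {
    names(lists) <- paste0("list", seq_along(lists))
  }
  universe <- unique(universe)
  feature_set <- intersect(unique(feature_set), universe)
  N <- length(universe)
  K <- length(feature_set)
  rows <- imap(lists, function(ids, nm) {
    ids <- intersect(unique(ids), universe)
    n <- length(ids)
    k <- length(intersect(ids, feature_set))
    if (n == 0L) {
      warn(sprintf("enrich_genes: list '%s' is empty after universe filtering", nm))
      return(tibble(list_name = nm, n_list = 0L, n_feature = K,
                    n_overlap = 0L, n_universe = N, p_value = 1,
                    odds_ratio = NA_real_))
    }
    tibble(
      list_name = nm, n_list = n, n_feature = K, n_overlap = k,
      n_universe = N,
      p_value = hyper_upper_tail(k, K, N, n),
      odds_ratio = sample_odds_ratio(N, K, n, k)
    )
  })
  out <- bind_rows(rows) %>%
    mutate(fdr = bh_adjust(.data$p_value)) %>%
    select("list_name", "n_list", "n_feature", "n_overlap", "n_universe",
           "p_value", "fdr", "odds_ratio")
  class(out) <- c("sorf_enrichment", class(out))
  out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X` the number of feature genes in a draw of `n` from a
#' universe of `N` containing `K` feature genes. Wraps the hypergeometric
#' distribution on the log scale.
#'
#' @param k Observed intersection size.
#' @param K Feature-set size in the universe.
#' @param N Universe size.
#' @param n List size in the universe.
#' @return The tail probability, exact for `k = 0` (probability 1).
#' @export
hyper_upper_tail <- function(k, K, N, n) {
  if (k <= 0L) {
    return(1)
  }
  exp(phyper(k - 1L, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Sample (cross-product) odds ratio of the enrichment 2x2 table
#'
#' @inheritParams hyper_upper_tail
#' @return `k (N - n - K + k) / ((n - k) (K - k))`; `Inf` when a denominator
#'   term is 0 and the numerator is positive, `NaN` when both vanish.
#' @export
sample_odds_ratio <- function(N, K, n, k) {
  (k * (N - n - K + k)) / ((n - k) * (K - k))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotonicity enforcement; output order matches input
#' order. Wraps [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted values (FDR), same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) {
    return(numeric(0))
  }
  p.adjust(p, method = "BH")
}

#' Read a one-ID-per-line gene list
#'
#' @param path Text file with one gene ID per line; blank lines and
#'   duplicate IDs are dropped.
#' @return Character vector of IDs.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Genes harboring at least one ORF of given classes
#'
#' Extracts from an annotated unique-ORF table the set of gene IDs whose
#' ORFs carry any of the requested class labels — e.g. the uORF-harboring
#' gene set fed to [enrich_genes()].
#'
#' @param uniques Annotated unique-ORF tibble (see [attach_transcripts()]).
#' @param classes Class labels to select (default `"uORF"`).
#' @param txmodels Transcript models used to resolve transcript IDs to gene
#'   IDs; when `NULL`, the ORFs' own `gene_ids` are used.
#' @return Sorted character vector of gene IDs.
#' @export
genes_with_orf_class <- function(uniques, classes = "uORF", txmodels = NULL) {
  has <- map_lgl(uniques$classes, ~ any(.x %in% classes))
  if (is.null(txmodels)) {
    return(union_multi(uniques$gene_ids[has]))
  }
  genes <- map(uniques$tx_annotations[has], function(ann) {
    hit <- ann$transcript_id[!is.na(ann$class) & ann$class %in% classes]
    txmodels$gene_id[txmodels$transcript_id %in% hit]
  })
  union_multi(genes)
}
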