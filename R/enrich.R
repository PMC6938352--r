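#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for the number of annotated genes in a random list of size
#' `n` drawn from a universe of `N` genes of which `K` carry the term;
#' evaluated with `stats::phyper` (log-space internally).  `k = 0` gives 1.
#'
#' @param N Universe size.
#' @param K Universe genes carrying the term.
#' @param n List size.
#' @param k Annotated genes in the list (vectorized).
#' @return Upper-tail probabilities.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(N < 0) || any(K < 0) || any(K > N) || any(n < 0) || any(n > N)) {
    abort("need 0 <= K <= N and 0 <= n <= N")
  }
  if (any(k < 0 | k > n | k > K)) abort("need 0 <= k <= min(K, n)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of a gene list
#'
#' Tests every annotation term with at least one hit in the list against
#' the annotation universe (all annotated genes, mirroring a genome-wide
#' reference list, or an explicit `universe`), BH-adjusts across the tested
#' terms, and sorts by adjusted p.
#'
#' @param genes Character vector of gene ids (e.g. an Up or Down DE list).
#'   Genes outside the universe are dropped with a warning.
#' @param annotations Long annotation tibble ([read_annotations()]).
#' @param alpha Significance cut-off on the BH-adjusted p.
#' @param universe Optional explicit universe (e.g. the expressed genes);
#'   defaults to all annotated genes.
#' @return A tibble `term`, `N`, `K`, `n`, `k`, `p`, `p_adj`,
#'   `significant`, sorted by `p_adj`.
#' @export
enrich <- function(genes, annotations, alpha = 0.05, universe = NULL) {
  annotations <- validate_annotations(annotations)
  universe <- unique(universe %||% annotations$gene_id)
  annotations <- annotations[annotations$gene_id %in% universe, ]
  genes <- unique(genes)
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d gene(s) outside the annotation universe dropped",
                 length(outside)))
    genes <- setdiff(genes, outside)
  }
  if (length(genes) == 0) abort("no genes left to test after universe filter")
  N <- length(universe)
  n <- length(genes)
  per_term <- annotations |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$gene_id),
                     k = sum(unique(.data$gene_id) %in% genes)) |>
    dplyr::filter(.data$k >= 1)
  if (nrow(per_term) == 0) {
    warn("no term has a hit in the list; nothing to test")
    return(tibble(term = character(0), N = integer(0), K = integer(0),
                  n = integer(0), k = integer(0), p = numeric(0),
                  p_adj = numeric(0), significant = logical(0)))
  }
  per_term |>
    dplyr::mutate(N = N, n = n,
                  p = hypergeom_upper_tail(N, .data$K, n, .data$k)) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p),
                  significant = .data$p_adj <= alpha) |>
    dplyr::select("term", "N", "K", "n", "k", "p", "p_adj", "significant") |>
    dplyr::arrange(.data$p_adj, .data$p, .data$term)
}
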