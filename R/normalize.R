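#' TMM normalization factors
#'
#' Trimmed mean of M-values: each sample's factor is a doubly trimmed (30%
#' on log-ratios, 5% on average log-intensity), inverse-variance-weighted
#' mean of gene-wise log2 ratios against a reference sample, rescaled so
#' factors multiply to one.  Effective library size = factor x library
#' size.  Computed with edgeR's TMM implementation.
#'
#' @param counts Counts tibble ([read_counts()]).
#' @param reference Optional reference `sample_id`; edgeR's upper-quartile
#'   heuristic picks one when `NULL`.
#' @return A tibble with columns `sample_id`, `lib_size`, `tmm_factor`,
#'   `eff_lib_size`.
#' @export
tmm_factors <- function(counts, reference = NULL) {
  m <- counts_matrix(counts)
  if (any(colSums(m) == 0)) {
    abort(paste0("sample with all-zero counts: ",
                 colnames(m)[which(colSums(m) == 0)[1]]))
  }
  refcol <- NULL
  if (!is.null(reference)) {
    refcol <- match(reference, colnames(m))
    if (is.na(refcol)) abort(paste0("unknown reference sample: ", reference))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = refcol)
  tibble(sample_id = colnames(m),
         lib_size = unname(colSums(m)),
         tmm_factor = unname(f),
         eff_lib_size = unname(f * colSums(m)))
}

#' Normalized log2 counts per million
#'
#' log2 CPM on TMM-effective library sizes with a pseudo-count, the
#' expression scale used for trait correlation, clustering and the
#' co-expression network.
#'
#' @inheritParams tmm_factors
#' @param factors Output of [tmm_factors()]; computed when `NULL`.
#' @param prior_count Pseudo-count added before the log.
#' @return A tibble shaped like `counts` with log2 CPM values.
#' @export
cpm_log2 <- function(counts, factors = NULL, prior_count = 0.5) {
  m <- counts_matrix(counts)
  factors <- factors %||% tmm_factors(counts)
  eff <- factors$eff_lib_size[match(colnames(m), factors$sample_id)]
  lc <- edgeR::cpm(m, lib.size = eff, log = TRUE, prior.count = prior_count)
  matrix_to_counts(lc)
}
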