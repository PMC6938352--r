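#' Genotype-class mean expression
#'
#' Averages per-sample expression within each of the four genotype classes
#' (1^F271, 1^F288, 2^F271, 2^F288), the unit at which traits are measured
#' and at which the small-n correlation rule applies.
#'
#' @param expr Expression tibble (`gene_id` + one column per sample), e.g.
#'   from [cpm_log2()].
#' @param design Design tibble.
#' @return A tibble `gene_id` + the four class columns in canonical order.
#' @export
genotype_means <- function(expr, design) {
  design <- align_design(expr, design)
  m <- counts_matrix(expr)
  out <- vapply(NIL_CLASSES, function(cl) {
    idx <- which(design$class == cl)
    if (length(idx) == 0) abort(paste0("genotype class absent: ", cl))
    rowMeans(m[, idx, drop = FALSE])
  }, numeric(nrow(m)))
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(out))
}

#' Critical Pearson correlation for the exact t rule
#'
#' The significance of a Pearson correlation over n units is tested with
#' `t = r / sqrt((1 - r^2) / (n - 2))` on n - 2 degrees of freedom; the
#' critical |r| at two-sided level `alpha` is therefore
#' `t* / sqrt(t*^2 + n - 2)` with `t*` the 1 - alpha/2 t quantile.  With
#' the study's n = 4 genotype classes and alpha = 0.05 this gives 0.95.
#'
#' @param n Number of paired observations (>= 3).
#' @param alpha Two-sided significance level.
#' @return The critical absolute correlation in (0, 1).
#' @export
#' @examples
#' critical_r(4, 0.05)  # 0.95
critical_r <- function(n, alpha = 0.05) {
  if (any(n < 3)) abort("n must be >= 3")
  if (any(alpha <= 0 | alpha >= 1)) abort("alpha must lie in (0, 1)")
  tstar <- qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(tstar^2 + n - 2)
}

#' Gene-trait Pearson correlations with the exact small-n rule
#'
#' One record per (gene, trait): Pearson r across the shared genotype
#' classes, its t statistic, and the significance verdict
#' `|r| > critical_r(n, alpha)`.  Zero-variance vectors have no defined
#' correlation; such records are returned with `r = 0` and
#' `significant = FALSE`, with a warning.
#'
#' @param expr_means Output of [genotype_means()] (or any `gene_id` +
#'   unit-column tibble).
#' @param traits Long trait tibble ([read_traits()]).
#' @param alpha Significance level of the t rule.
#' @return A tibble `gene_id`, `trait`, `r`, `t`, `n`, `critical_r`,
#'   `significant`.
#' @export
correlate_genes_traits <- function(expr_means, traits, alpha = 0.05) {
  traits <- validate_traits(traits)
  classes <- names(expr_means)[-1]
  wide <- tidyr::pivot_wider(traits, names_from = "trait", values_from = "value")
  if (!setequal(wide$class, classes)) {
    abort("expression and trait tables cover different genotype classes")
  }
  wide <- wide[match(classes, wide$class), ]
  em <- counts_matrix(expr_means)
  n <- length(classes)
  rc <- critical_r(n, alpha)
  trait_names <- setdiff(names(wide), "class")

  zero_var_genes <- apply(em, 1, sd) == 0
  if (any(zero_var_genes)) {
    warn(sprintf("%d gene(s) with zero expression variance; r set to 0",
                 sum(zero_var_genes)))
  }
  out <- purrr::map_dfr(trait_names, function(tr) {
    y <- wide[[tr]]
    if (sd(y) == 0) {
      warn(paste0("trait '", tr, "' has zero variance; r set to 0"))
      r <- rep(0, nrow(em))
    } else {
      r <- suppressWarnings(as.vector(cor(t(em), y)))
      r[zero_var_genes] <- 0
    }
    r <- pmin(pmax(r, -1), 1)
    tibble(gene_id = rownames(em), trait = tr, r = r,
           t = ifelse(abs(r) < 1, r / sqrt((1 - r^2) / (n - 2)),
                      sign(r) * Inf),
           n = n, critical_r = rc, significant = abs(r) > rc)
  })
  out
}

#' UPGMA hierarchical clustering of expression rows
#'
#' Euclidean distances with unweighted pair-group average linkage, used to
#' order genes for heatmap display.
#'
#' @param x Tibble `gene_id` + numeric columns, or a numeric matrix with
#'   rownames.
#' @return The `stats::hclust` tree; leaf order via [cluster_order()].
#' @export
hcluster <- function(x) {
  m <- if (is.data.frame(x)) counts_matrix(x) else x
  if (any(!is.finite(m))) abort("non-finite values in clustering input")
  if (nrow(m) < 2) abort("need at least two rows to cluster")
  hclust(dist(m, method = "euclidean"), method = "average")
}

#' @rdname hcluster
#' @param tree An `hclust` object from [hcluster()].
#' @return `cluster_order()`: row labels in dendrogram leaf order.
#' @export
cluster_order <- function(tree) tree$labels[tree$order]
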