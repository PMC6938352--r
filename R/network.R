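#' Build a |PCC|-thresholded co-expression network
#'
#' Computes all-pairs Pearson correlations of genotype-class mean expression
#' and keeps an edge wherever |r| strictly exceeds the threshold.  All input
#' genes stay in the node set; genes without any edge are isolated and get
#' module `NA`.  Connected components are labelled M1..Mk by decreasing node
#' count, ties broken by the lexicographically smallest member gene.
#'
#' The default threshold is the procedure's literal 0.995 (described as the
#' 0.01-level cut-off even though the exact t rule at n = 4 gives 0.990);
#' both values can be passed explicitly.
#'
#' @param expr_means Tibble `gene_id` + genotype-class columns
#'   ([genotype_means()]).
#' @param genes Optional subset of genes to use as nodes (e.g. the final DE
#'   set); defaults to all rows.
#' @param threshold Edge threshold on |r| (strict inequality).
#' @return An object of class `coexpr_network`: list with `nodes`
#'   (`gene_id`, `module`, `degree`), `edges` (`gene_a`, `gene_b`, `r`),
#'   `threshold`.
#' @export
build_network <- function(expr_means, genes = NULL, threshold = 0.995) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  if (!is.null(genes)) {
    missing <- setdiff(genes, expr_means$gene_id)
    if (length(missing) > 0) {
      abort(paste0("gene absent from expression matrix: ", missing[1]))
    }
    expr_means <- expr_means[match(genes, expr_means$gene_id), ]
  }
  m <- counts_matrix(expr_means)
  if (nrow(m) < 2) abort("need at least two genes")
  zv <- apply(m, 1, sd) == 0
  if (any(zv)) {
    warn(sprintf("%d zero-variance gene(s) excluded from edges", sum(zv)))
  }
  cm <- suppressWarnings(cor(t(m)))
  cm[zv, ] <- 0
  cm[, zv] <- 0
  idx <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  edges <- tibble(gene_a = rownames(cm)[idx[, 1]],
                  gene_b = rownames(cm)[idx[, 2]],
                  r = cm[idx])
  new_network(rownames(cm), edges, threshold)
}

# assemble nodes + module labels from an edge list
new_network <- function(gene_ids, edges, threshold) {
  nodes <- tibble(gene_id = gene_ids,
                  module = label_components(gene_ids, edges))
  deg <- table(c(edges$gene_a, edges$gene_b))
  nodes$degree <- as.integer(deg[nodes$gene_id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "coexpr_network")
}

#' Connected-component module labels
#'
#' Components of the undirected graph over genes with at least one edge,
#' labelled M1..Mk by decreasing size (ties: smallest member gene id);
#' isolated genes get `NA`.
#'
#' @param gene_ids All node gene ids.
#' @param edges Edge tibble with columns `gene_a`, `gene_b`.
#' @return Character vector of module labels aligned with `gene_ids`.
#' @export
label_components <- function(gene_ids, edges) {
  module <- rep(NA_character_, length(gene_ids))
  names(module) <- gene_ids
  if (nrow(edges) == 0) return(unname(module))
  g <- igraph::graph_from_data_frame(edges[c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  ord <- order(-vapply(members, length, 0L),
               vapply(members, function(x) min(sort(x)), ""))
  for (k in seq_along(ord)) {
    module[members[[ord[k]]]] <- paste0("M", k)
  }
  unname(module[gene_ids])
}

#' @export
print.coexpr_network <- function(x, ...) {
  k <- sum(!is.na(unique(x$nodes$module)))
  cat(sprintf("Co-expression network: %d nodes, %d edges (|r| > %s), %d module(s)\n",
              nrow(x$nodes), nrow(x$edges), format(x$threshold), k))
  invisible(x)
}

#' Per-module trait-correlation summary
#'
#' For each module, counts the member genes whose expression is
#' significantly correlated (|r| > `pcc_cut`, strict) with at least one
#' trait, with at least two of the trait trio (cell wall degradability
#' IVNDFD, hemicellulose Hcell/NDF, cellulose Cell/NDF), and with IVNDFD
#' itself.
#'
#' @param x A `coexpr_network`, or any tibble with columns `gene_id`,
#'   `module` (so the packaged reference table can be summarized directly).
#' @param correlations Long correlation records ([correlate_genes_traits()]
#'   or [table1_correlations()]) covering the network genes.
#' @param pcc_cut Significance cut-off on |r|.
#' @param trio The three traits making up the trio count.
#' @return A tibble `module`, `n_genes`, `n_any_trait`, `n_trio2`,
#'   `n_ivndfd`.
#' @export
module_summary <- function(x, correlations, pcc_cut = 0.95,
                           trio = c("IVNDFD", "Hcell/NDF", "Cell/NDF")) {
  nodes <- if (inherits(x, "coexpr_network")) x$nodes else as_tibble(x)
  missing_traits <- setdiff(c(trio, "IVNDFD"), unique(correlations$trait))
  if (length(missing_traits) > 0) {
    abort(paste0("trait absent from correlation records: ", missing_traits[1]))
  }
  sig <- correlations |>
    dplyr::filter(abs(.data$r) > pcc_cut) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(any_trait = dplyr::n() > 0,
                     trio2 = sum(.data$trait %in% trio) >= 2,
                     ivndfd = any(.data$trait == "IVNDFD"))
  nodes |>
    dplyr::filter(!is.na(.data$module)) |>
    dplyr::left_join(sig, by = "gene_id") |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     n_any_trait = sum(.data$any_trait, na.rm = TRUE),
                     n_trio2 = sum(.data$trio2, na.rm = TRUE),
                     n_ivndfd = sum(.data$ivndfd, na.rm = TRUE)) |>
    dplyr::arrange(factor(.data$module,
                          levels = paste0("M", seq_len(nrow(nodes)))))
}

#' Export / import a co-expression network
#'
#' Writes GraphML (with node module/degree and edge r attributes) and an
#' edge-list TSV; `read_network_graphml()` round-trips the GraphML back
#' into a `coexpr_network`.
#'
#' @param network A `coexpr_network`.
#' @param graphml,edges_tsv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
export_network <- function(network, graphml = NULL, edges_tsv = NULL) {
  if (!is.null(graphml)) {
    g <- as_igraph(network)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(edges_tsv)) {
    readr::write_tsv(network$edges, edges_tsv, progress = FALSE)
  }
  invisible(c(graphml = graphml, edges_tsv = edges_tsv))
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges,
    directed = FALSE,
    vertices = dplyr::mutate(network$nodes,
                             module = dplyr::coalesce(.data$module, "NA")))
}

#' @rdname export_network
#' @param path A GraphML file written by [export_network()].
#' @param threshold Threshold to record on the imported network.
#' @export
read_network_graphml <- function(path, threshold = 0.995) {
  g <- igraph::read_graph(path, format = "graphml")
  edges <- igraph::as_data_frame(g, what = "edges")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- tibble(gene_a = edges$from, gene_b = edges$to, r = edges$r)
  new_network(nodes$name, edges, threshold)
}

#' @method tidy coexpr_network
#' @export
tidy.coexpr_network <- function(x, ...) x$edges

#' @method glance coexpr_network
#' @export
glance.coexpr_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_modules = dplyr::n_distinct(x$nodes$module, na.rm = TRUE),
         n_isolated = sum(is.na(x$nodes$module)),
         threshold = x$threshold)
}
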