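TABLE1_MD5 <- "94a4d3558e84095232d248e4a6b93deb"

#' Load the packaged 125-gene reference table
#'
#' Returns the packaged transcription of the study's comprehensive list of
#' the 125 introgression-specific (common QTL) differentially expressed
#' genes: per gene the direction of regulation in the F288-allele NILs, the
#' printed Pearson correlations with the four cell-wall traits (IVNDFD,
#' hemicellulose, cellulose and lignin content), the co-expression module
#' label (M1..M7, `NA` for genes outside the network), SPE flags, and
#' whether the gene lies in the introgressed region or at the fine-mapped
#' locus.
#'
#' @return A tibble with 125 rows and columns `gene_id`, `gene_name`,
#'   `trend`, `pcc_ivndfd`, `pcc_hcell`, `pcc_cell`, `pcc_lignin`, `module`,
#'   `spe`, `in_qtl_region`, `in_qtl_locus`, `annotation`.
#' @export
#' @examples
#' t1 <- load_table1()
#' table(t1$trend)
load_table1 <- function() {
  path <- system.file("extdata", "table1.tsv", package = "nilnet", mustWork = TRUE)
  if (unname(tools::md5sum(path)) != TABLE1_MD5) {
    abort("packaged table1.tsv does not match its recorded checksum")
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         gene_id = "c", gene_name = "c", trend = "c",
                         pcc_ivndfd = "d", pcc_hcell = "d", pcc_cell = "d",
                         pcc_lignin = "d", module = "c", spe = "c",
                         in_qtl_region = "l", in_qtl_locus = "l",
                         annotation = "c"),
                       na = character())
  x$module[x$module == "NA"] <- NA_character_
  stopifnot(nrow(x) == 125,
            all(abs(c(x$pcc_ivndfd, x$pcc_hcell, x$pcc_cell, x$pcc_lignin)) <= 1),
            all(x$trend %in% c("Up", "Down")),
            all(x$spe %in% c("SPE_F271", "SPE_F288", "none")))
  x
}

#' Reshape the reference table's printed correlations to long records
#'
#' Produces one row per (gene, trait) with the printed Pearson r and its
#' significance under the exact small-n rule (|r| > critical r at n = 4),
#' in the shape returned by [correlate_genes_traits()].
#'
#' @param table1 Output of [load_table1()].
#' @param alpha Significance level for the t-based rule.
#' @return A tibble with columns `gene_id`, `trait`, `r`, `n`, `critical_r`,
#'   `significant`.
#' @export
table1_correlations <- function(table1 = load_table1(), alpha = 0.05) {
  long <- tidyr::pivot_longer(
    table1[c("gene_id", "pcc_ivndfd", "pcc_hcell", "pcc_cell", "pcc_lignin")],
    -"gene_id", names_to = "trait", values_to = "r")
  long$trait <- TRAIT_NAMES[match(long$trait,
    c("pcc_ivndfd", "pcc_hcell", "pcc_cell", "pcc_lignin"))]
  rc <- critical_r(4, alpha)
  dplyr::mutate(long, n = 4L, critical_r = rc, significant = abs(.data$r) > rc)
}
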