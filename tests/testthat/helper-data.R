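# shared builders for small in-code fixtures

study_design <- function() {
  tibble::tibble(
    sample_id = c("p1_F271_r1", "p1_F271_r2", "p1_F288_r1",
                  "p2_F271_r1", "p2_F271_r2", "p2_F288_r1", "p2_F288_r2"),
    nil_pair = c(1, 1, 1, 2, 2, 2, 2),
    allele = c("F271", "F271", "F288", "F271", "F271", "F288", "F288"),
    replicate = c(1, 2, 1, 1, 2, 1, 2))
}

counts_tbl <- function(m, gene_ids = sprintf("g%02d", seq_len(nrow(m))),
                       sample_ids = colnames(m) %||%
                         sprintf("s%d", seq_len(ncol(m)))) {
  out <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(out) <- sample_ids
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a toy genome + annotation for promoter extraction tests
write_toy_genome <- function(dir, contigs, features) {
  fasta <- file.path(dir, "genome.fa")
  writeLines(unlist(purrr::map2(names(contigs), contigs,
                                ~ c(paste0(">", .x), .y))), fasta)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3", features), gff)
  c(fasta = fasta, gff = gff)
}
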