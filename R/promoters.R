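#' Extract TSS-anchored promoter sequences from FASTA + GFF3
#'
#' For every gene the promoter is the 1,000 bases (configurable) upstream of
#' the transcription start site followed by the 5' UTR, taken on the gene's
#' coding strand (minus-strand genes are reverse-complemented), so the
#' sequence always reads 5' to 3' into the gene.  The positional axis puts
#' -1 on the base immediately upstream of the TSS and 0 on the first UTR
#' base.  Genes whose 5' UTR is shorter than `min_utr` bases are excluded
#' (guards against false promoter regions); promoters running off the contig
#' start are truncated and flagged.
#'
#' @param fasta Path to the genome (or contig) FASTA.
#' @param gff Path to a GFF3 with `gene` and `five_prime_UTR` features
#'   (`five_prime_UTR` may point at the gene directly or via an mRNA).
#' @param upstream Upstream window length in bases.
#' @param min_utr Minimum 5' UTR length; shorter genes are dropped.
#' @return A tibble with columns `gene_id`, `sequence`, `utr_length`,
#'   `upstream_length`, `truncated`.  The number of UTR-filtered genes is
#'   reported and stored in attribute `n_excluded`.
#' @export
read_promoters <- function(fasta, gff, upstream = 1000, min_utr = 10) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  feat <- as.data.frame(rtracklayer::import(gff))
  feat$Parent <- vapply(feat$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")

  genes <- feat[feat$type == "gene", ]
  if (nrow(genes) == 0) abort("no gene features in GFF3")
  # resolve five_prime_UTR parents, hopping over mRNA features when present
  utr <- feat[feat$type == "five_prime_UTR", ]
  id2parent <- setNames(feat$Parent, feat$ID)
  owner <- utr$Parent
  via_mrna <- owner %in% feat$ID[feat$type == "mRNA"]
  owner[via_mrna] <- id2parent[owner[via_mrna]]
  utr_len <- tapply(utr$width, owner, sum)

  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    L <- unname(utr_len[gid])
    if (is.na(L) || is.null(L)) L <- 0
    if (L < min_utr) return(NULL)
    contig <- as.character(genes$seqnames[i])
    if (!contig %in% names(seqs)) {
      abort(paste0("GFF contig '", contig, "' missing from FASTA"))
    }
    clen <- length(seqs[[contig]])
    if (genes$strand[i] == "-") {
      tss <- genes$end[i]
      lo <- tss - L + 1
      hi <- min(clen, tss + upstream)
      if (lo < 1) abort(paste0("5' UTR of '", gid, "' extends beyond contig"))
      s <- Biostrings::reverseComplement(Biostrings::subseq(seqs[[contig]], lo, hi))
      up_len <- hi - tss
      truncated <- tss + upstream > clen
    } else {
      tss <- genes$start[i]
      lo <- max(1, tss - upstream)
      hi <- tss + L - 1
      if (hi > clen) abort(paste0("5' UTR of '", gid, "' extends beyond contig"))
      s <- Biostrings::subseq(seqs[[contig]], lo, hi)
      up_len <- tss - lo
      truncated <- tss - upstream < 1
    }
    tibble(gene_id = gid, sequence = toupper(as.character(s)),
           utr_length = as.integer(L), upstream_length = as.integer(up_len),
           truncated = truncated)
  })
  kept <- dplyr::bind_rows(out)
  n_excluded <- nrow(genes) - nrow(kept)
  inform(sprintf("%d promoter(s) kept, %d excluded (5' UTR < %d bases)",
                 nrow(kept), n_excluded, min_utr))
  attr(kept, "n_excluded") <- n_excluded
  kept
}

#' Write a promoter set as FASTA + GFF3 contigs
#'
#' Serializes a promoter tibble (as produced by [simulate_promoters()]) into
#' one synthetic contig per gene: the promoter sequence followed by `pad`
#' downstream bases, with `gene` and `five_prime_UTR` features.  Genes with
#' `strand == "-"` are stored reverse-complemented so that re-extraction
#' exercises the strand-aware path.
#'
#' @param promoters Tibble with columns `gene_id`, `sequence`, `utr_length`
#'   and optionally `strand`.
#' @param fasta,gff Output paths.
#' @param pad Downstream padding in bases.
#' @return Invisibly, the two paths.
#' @export
write_promoter_files <- function(promoters, fasta, gff, pad = 50) {
  strand <- promoters$strand %||% rep("+", nrow(promoters))
  pads <- vapply(seq_len(nrow(promoters)), function(i) {
    paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE), collapse = "")
  }, "")
  fwd <- paste0(promoters$sequence, pads)
  contigs <- Biostrings::DNAStringSet(fwd)
  minus <- strand == "-"
  contigs[minus] <- Biostrings::reverseComplement(contigs[minus])
  names(contigs) <- paste0("ctg_", promoters$gene_id)
  Biostrings::writeXStringSet(contigs, fasta)

  n <- nrow(promoters)
  up <- nchar(promoters$sequence) - promoters$utr_length
  clen <- nchar(fwd)
  gene_start <- ifelse(minus, 1L, up + 1L)
  gene_end <- ifelse(minus, clen - up, clen)
  utr_start <- ifelse(minus, clen - up - promoters$utr_length + 1L, up + 1L)
  utr_end <- ifelse(minus, clen - up, up + promoters$utr_length)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(names(contigs), 2),
    ranges = IRanges::IRanges(start = c(gene_start, utr_start),
                              end = c(gene_end, utr_end)),
    strand = rep(ifelse(minus, "-", "+"), 2),
    type = rep(c("gene", "five_prime_UTR"), each = n),
    ID = c(promoters$gene_id, paste0(promoters$gene_id, ".utr1")),
    Parent = IRanges::CharacterList(c(replicate(n, character(0)),
                                      as.list(promoters$gene_id))))
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}
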