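#' Read a gene-by-sample count table
#'
#' Reads a tab-delimited table whose first column holds gene identifiers and
#' whose remaining columns hold non-negative integer read counts, one column
#' per sample.
#'
#' @param path Path to a tab-delimited text file.
#' @return A tibble with a `gene_id` character column followed by one integer
#'   column per sample.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  validate_counts(x)
}

#' @rdname read_counts
#' @param counts A counts tibble as returned by [read_counts()].
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(validate_counts(counts), path, progress = FALSE)
  invisible(path)
}

#' Validate a counts tibble
#'
#' Checks gene-id uniqueness and that every count cell is a non-negative
#' integer, naming the offending cell otherwise.
#'
#' @inheritParams write_counts
#' @return The validated tibble, invisibly coerced to integer counts.
#' @export
validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (ncol(counts) < 2) abort("counts table needs a gene_id column plus >= 1 sample column")
  dup <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene ids: ", paste(unique(dup), collapse = ", ")))
  }
  for (j in names(counts)[-1]) {
    v <- counts[[j]]
    if (!is.numeric(v)) abort(paste0("non-numeric counts in column '", j, "'"))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      abort(sprintf("invalid count at gene '%s', sample '%s': %s",
                    counts$gene_id[bad[1]], j, format(v[bad[1]])))
    }
    counts[[j]] <- as.integer(round(v))
  }
  counts
}

#' Per-sample library sizes (column sums)
#'
#' @inheritParams write_counts
#' @return A tibble with columns `sample_id` and `lib_size`.
#' @export
library_sizes <- function(counts) {
  m <- counts_matrix(counts)
  tibble(sample_id = colnames(m), lib_size = unname(colSums(m)))
}

# counts tibble -> integer matrix with gene rownames
counts_matrix <- function(counts) {
  m <- as.matrix(counts[-1])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  out <- as_tibble(m, rownames = "gene_id")
  out
}

#' Read and validate a NIL sample design table
#'
#' The design describes the 2-pair x 2-allele NIL layout: each sample belongs
#' to one NIL pair (1 or 2) and carries either the recurrent F271 allele or
#' the introgressed F288 allele at the QTL region.  Unbalanced layouts (the
#' study kept 2/1/2/2 replicates after removing one 1^F288 sample) are
#' supported; every genotype class must keep at least one sample.
#'
#' @param path Path to a tab-delimited file with columns `sample_id`,
#'   `nil_pair`, `allele`, `replicate`.
#' @return A validated design tibble with an added `class` column
#'   (`"1^F271"`, `"1^F288"`, `"2^F271"`, `"2^F288"`).
#' @export
read_design <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(sample_id = "c", allele = "c"))
  validate_design(x)
}

#' @rdname read_design
#' @param design A design data frame.
#' @export
validate_design <- function(design) {
  design <- as_tibble(design)
  need <- c("sample_id", "nil_pair", "allele", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) abort(paste0("design lacks columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(design$sample_id)) abort("duplicate sample_id in design")
  if (!all(design$nil_pair %in% c(1, 2, "1", "2"))) abort("nil_pair must be 1 or 2")
  bad <- setdiff(unique(design$allele), ALLELES)
  if (length(bad) > 0) abort(paste0("unknown allele label: ", paste(bad, collapse = ", ")))
  if (!all(design$replicate == round(design$replicate) & design$replicate >= 1)) {
    abort("replicate must be a positive integer")
  }
  design$nil_pair <- as.integer(design$nil_pair)
  design$class <- class_label(design$nil_pair, design$allele)
  empty <- setdiff(NIL_CLASSES, design$class)
  if (length(empty) > 0) {
    abort(paste0("genotype class without samples: ", paste(empty, collapse = ", ")))
  }
  design
}

# check that counts columns and design rows agree, return design ordered
# as the count columns
align_design <- function(counts, design) {
  design <- validate_design(design)
  samples <- names(counts)[-1]
  if (!setequal(samples, design$sample_id)) {
    abort("count columns and design sample_ids differ")
  }
  design[match(samples, design$sample_id), ]
}

#' Read a genotype-class by trait table
#'
#' Long format: one row per (genotype class, trait) with a numeric value.
#' Traits are cell-wall phenotypes such as IVNDFD (in vitro neutral
#' detergent fiber digestibility, %) or Hcell/NDF (hemicellulose as % NDF).
#'
#' @param path Path to a tab-delimited file with columns `class`, `trait`,
#'   `value`.
#' @return A validated tibble.
#' @export
read_traits <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(class = "c", trait = "c"))
  validate_traits(x)
}

#' @rdname read_traits
#' @param traits A traits data frame.
#' @export
validate_traits <- function(traits) {
  traits <- as_tibble(traits)
  need <- c("class", "trait", "value")
  miss <- setdiff(need, names(traits))
  if (length(miss) > 0) abort(paste0("traits lack columns: ", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(traits$class), NIL_CLASSES)
  if (length(bad) > 0) abort(paste0("unknown genotype class: ", paste(bad, collapse = ", ")))
  if (!is.numeric(traits$value) || anyNA(traits$value)) {
    abort("trait values must be numeric and complete")
  }
  if (anyDuplicated(traits[c("class", "trait")])) {
    abort("more than one value for a (class, trait) pair")
  }
  traits
}

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Read an IUPAC motif library
#'
#' @param path Path to a tab-delimited file with columns `name`, `pattern`;
#'   patterns use IUPAC nucleotide codes (e.g. the NAC-binding CATGTG or the
#'   GCC-box core GCCGCC).
#' @return A validated tibble.
#' @export
read_motifs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  validate_motifs(x)
}

#' @rdname read_motifs
#' @param motifs A motif data frame.
#' @export
validate_motifs <- function(motifs) {
  motifs <- as_tibble(motifs)
  if (!all(c("name", "pattern") %in% names(motifs))) {
    abort("motif table needs columns name, pattern")
  }
  if (anyDuplicated(motifs$name)) abort("duplicate motif names")
  if (any(!nzchar(motifs$pattern))) abort("empty motif pattern")
  for (i in seq_len(nrow(motifs))) {
    chars <- strsplit(toupper(motifs$pattern[i]), "")[[1]]
    bad <- setdiff(chars, IUPAC_CODES)
    if (length(bad) > 0) {
      abort(sprintf("motif '%s': invalid IUPAC character '%s'",
                    motifs$name[i], bad[1]))
    }
    motifs$pattern[i] <- paste(chars, collapse = "")
  }
  motifs
}

#' Read a gene-to-term annotation table
#'
#' @param path Path to a tab-delimited file with columns `gene_id`, `term`;
#'   one row per assignment.  The set of annotated genes defines the
#'   enrichment universe.
#' @return A validated tibble.
#' @export
read_annotations <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  validate_annotations(x)
}

#' @rdname read_annotations
#' @param annotations An annotation data frame.
#' @export
validate_annotations <- function(annotations) {
  annotations <- as_tibble(annotations)
  if (!all(c("gene_id", "term") %in% names(annotations))) {
    abort("annotation table needs columns gene_id, term")
  }
  if (any(!nzchar(annotations$term)) || anyNA(annotations$term)) {
    abort("terms must be non-empty strings")
  }
  dplyr::distinct(annotations, .data$gene_id, .data$term)
}
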