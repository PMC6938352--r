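#' Configuration for the synthetic NIL study generator
#'
#' Bundles all parameters of the synthetic data emulating the study design:
#' two NIL pairs, two alleles (F271 recurrent / F288 introgressed), with the
#' study's unbalanced 2/1/2/2 replication by default.  Counts are negative
#' binomial around log-normal baselines, with planted gene categories:
#' `allele` genes shift by the allele effect identically in both pairs (the
#' signal the stepwise procedure should keep), `nil` genes differ between
#' pairs only, `interaction` genes have a pair-specific allele effect (both
#' should be screened out), and SPE genes are structural zeros in one allele
#' class with a low positive mean in the other.
#'
#' @param n_genes Total genes.
#' @param replicates Replicates per genotype class, named by class label.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline mean count.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @param n_allele,n_nil,n_interaction,n_spe_f288,n_spe_f271 Genes per
#'   planted category; the remainder is null.
#' @param lfc_allele,lfc_nil,lfc_interaction Absolute log2 effect sizes
#'   (signs are drawn per gene).
#' @param spe_mean Mean count of SPE genes in their expressed allele class.
#' @param lib_factor_range Per-sample depth factors are drawn log-uniform in
#'   this range, so TMM has composition/depth variation to undo.
#' @param traits Trait names for the coupled phenotypes.
#' @param genes_per_trait Number of allele-category genes linearly coupled
#'   to each trait.
#' @param trait_noise_sd Gaussian noise SD added to each trait value.
#' @param n_promoters,utr_range Promoter count and (uniform) 5' UTR length
#'   range for the promoter generator.
#' @param planted_motif IUPAC motif planted near the TSS.
#' @param plant_fraction Fraction of promoters receiving the planted motif.
#' @param plant_center,plant_sd Gaussian placement (TSS-relative start) of
#'   the planted motif.
#' @param n_decoy_motifs Random unplanted 6-mers added to the motif library.
#' @param n_terms Annotation terms; term `T01` is enriched in
#'   `enriched_category` genes.
#' @param enriched_category Gene category carrying the enriched term.
#' @param p_in,p_out Probability that the enriched term is assigned to a
#'   category gene / background gene.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       replicates = c("1^F271" = 2, "1^F288" = 1,
                                      "2^F271" = 2, "2^F288" = 2),
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       dispersion = 0.1,
                       n_allele = 100, n_nil = 100, n_interaction = 100,
                       n_spe_f288 = 10, n_spe_f271 = 10,
                       lfc_allele = 2, lfc_nil = 2, lfc_interaction = 2,
                       spe_mean = 25,
                       lib_factor_range = c(0.7, 1.4),
                       traits = TRAIT_NAMES, genes_per_trait = 10,
                       trait_noise_sd = 0.25,
                       n_promoters = 200, utr_range = c(10, 150),
                       planted_motif = "CATGTG", plant_fraction = 0.6,
                       plant_center = -50, plant_sd = 10,
                       n_decoy_motifs = 9,
                       n_terms = 20, enriched_category = "allele",
                       p_in = 0.9, p_out = 0.05) {
  cfg <- as.list(environment())
  n_planted <- n_allele + n_nil + n_interaction + n_spe_f288 + n_spe_f271
  if (n_planted > n_genes) abort("planted categories exceed n_genes")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (baseline_sdlog < 0 || trait_noise_sd < 0 || plant_sd <= 0) {
    abort("variance parameters must be positive")
  }
  if (spe_mean <= 0) abort("spe_mean must be positive")
  if (!setequal(names(replicates), NIL_CLASSES) || any(replicates < 1)) {
    abort("replicates must name all four genotype classes with >= 1 sample")
  }
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    abort("annotation probabilities must lie in [0, 1]")
  }
  if (plant_fraction < 0 || plant_fraction > 1) {
    abort("plant_fraction must lie in [0, 1]")
  }
  validate_motifs(tibble(name = "planted", pattern = planted_motif))
  structure(cfg, class = "sim_config")
}

sim_design <- function(config) {
  reps <- config$replicates[NIL_CLASSES]
  purrr::map_dfr(NIL_CLASSES, function(cl) {
    pair <- as.integer(substr(cl, 1, 1))
    allele <- sub(".*\\^", "", cl)
    r <- seq_len(reps[[cl]])
    tibble(sample_id = sprintf("p%d_%s_r%d", pair, allele, r),
           nil_pair = pair, allele = allele, replicate = r)
  }) |> validate_design()
}

#' Simulate NIL RNA-seq counts with planted effects
#'
#' Draws a gene-by-sample count matrix under the configured design:
#' `counts[g, s] ~ NB(mean = libfactor_s * mu_g(class_s), dispersion)`.
#' Category assignment is a deterministic partition of the gene index, so
#' realized category sizes equal the configured sizes exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical config + seed give identical output.
#' @return A list with elements `counts` (tibble, one column per sample),
#'   `design` (tibble) and `truth` (tibble with `gene_id`, `category`,
#'   `lfc` - the signed planted allele log2 fold change, `baseline`).
#' @export
simulate_counts <- function(config = sim_config(), seed = 1) {
  design <- sim_design(config)
  withr::with_seed(seed, {
    n <- config$n_genes
    gene_id <- sprintf("G%05d", seq_len(n))
    category <- rep("null", n)
    sizes <- c(allele = config$n_allele, nil = config$n_nil,
               interaction = config$n_interaction,
               spe_f288 = config$n_spe_f288, spe_f271 = config$n_spe_f271)
    at <- 0
    for (cat in names(sizes)) {
      category[at + seq_len(sizes[[cat]])] <- cat
      at <- at + sizes[[cat]]
    }
    baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
    sign <- sample(c(-1, 1), n, replace = TRUE)
    lfc <- numeric(n)
    lfc[category == "allele"] <- config$lfc_allele * sign[category == "allele"]
    lfc[category == "interaction"] <-
      config$lfc_interaction * sign[category == "interaction"]
    lfc_nil <- numeric(n)
    lfc_nil[category == "nil"] <- config$lfc_nil * sign[category == "nil"]

    # per-gene mean per genotype class
    mu <- matrix(baseline, n, 4, dimnames = list(gene_id, NIL_CLASSES))
    f288 <- grepl("F288", NIL_CLASSES)
    pair2 <- startsWith(NIL_CLASSES, "2")
    mu[, f288] <- mu[, f288] * 2^lfc                     # allele + interaction base
    mu[category == "interaction", f288 & pair2] <-
      baseline[category == "interaction"]                # interaction: pair-1 only
    mu[, pair2] <- mu[, pair2] * 2^lfc_nil               # NIL main effect
    mu[category == "spe_f288", ] <-
      rep(ifelse(f288, config$spe_mean, 0), each = config$n_spe_f288)
    mu[category == "spe_f271", ] <-
      rep(ifelse(f288, 0, config$spe_mean), each = config$n_spe_f271)

    lib_factor <- exp(runif(nrow(design), log(config$lib_factor_range[1]),
                            log(config$lib_factor_range[2])))
    counts <- matrix(0L, n, nrow(design),
                     dimnames = list(gene_id, design$sample_id))
    for (s in seq_len(nrow(design))) {
      m <- lib_factor[s] * mu[, design$class[s]]
      counts[, s] <- if (config$dispersion > 0) {
        rnbinom(n, mu = m, size = 1 / config$dispersion)
      } else {
        rpois(n, m)
      }
    }
    list(counts = matrix_to_counts(counts),
         design = design,
         truth = tibble(gene_id = gene_id, category = category, lfc = lfc,
                        lfc_nil = lfc_nil, baseline = baseline))
  })
}

#' Simulate traits linearly coupled to gene expression
#'
#' Each trait is a linear combination of the genotype-class mean
#' log-expression of a designated gene set, plus Gaussian noise, emulating
#' phenotypes driven by the expression of introgression-responsive genes.
#' By default coupled genes are taken from the `allele` category of `truth`
#' in blocks of `genes_per_trait`, with alternating coefficient signs.
#'
#' @param truth Truth tibble from [simulate_counts()].
#' @param expr_means Tibble `gene_id` + one column per genotype class, e.g.
#'   from [genotype_means()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param coupling Optional explicit coupling tibble with columns `trait`,
#'   `gene_id`, `coef` overriding the default choice.
#' @return A list with `traits` (long tibble `class`, `trait`, `value`) and
#'   `coupling` (the coefficients used).
#' @export
simulate_traits <- function(truth, expr_means, config = sim_config(),
                            seed = 1, coupling = NULL) {
  if (is.null(coupling)) {
    pool <- truth$gene_id[truth$category == "allele"]
    need <- config$genes_per_trait * length(config$traits)
    if (length(pool) < need) {
      abort("not enough allele-category genes to couple all traits")
    }
    # degradability and hemicellulose respond positively to upregulated
    # genes, cellulose and lignin negatively; each gene contributes with
    # its own planted direction so the trait tracks the allele pattern
    trait_sign <- rep_len(c(1, 1, -1, -1), length(config$traits))
    gene_sign <- setNames(ifelse(truth$lfc == 0, 1, sign(truth$lfc)),
                          truth$gene_id)
    coupling <- purrr::map_dfr(seq_along(config$traits), function(i) {
      g <- pool[(i - 1) * config$genes_per_trait + seq_len(config$genes_per_trait)]
      tibble(trait = config$traits[i], gene_id = g,
             coef = trait_sign[i] * unname(gene_sign[g]))
    })
  }
  missing <- setdiff(coupling$gene_id, truth$gene_id)
  if (length(missing) > 0) {
    abort(paste0("coupled gene absent from truth: ", missing[1]))
  }
  if (!all(coupling$gene_id %in% expr_means$gene_id)) {
    abort("coupled gene absent from expression matrix")
  }
  em <- as.matrix(expr_means[-1])
  rownames(em) <- expr_means$gene_id
  withr::with_seed(seed, {
    traits <- purrr::map_dfr(unique(coupling$trait), function(tr) {
      cp <- coupling[coupling$trait == tr, ]
      val <- drop(crossprod(em[cp$gene_id, , drop = FALSE], cp$coef)) +
        rnorm(ncol(em), 0, config$trait_noise_sd)
      tibble(class = colnames(em), trait = tr, value = unname(val))
    })
    list(traits = validate_traits(traits), coupling = coupling)
  })
}

#' Simulate promoters with a positionally planted motif
#'
#' Background sequence is i.i.d. uniform over ACGT; in a `plant_fraction` of
#' promoters the planted motif overwrites the sequence at a position drawn
#' from a Gaussian centred at `plant_center` (TSS-relative), emulating a
#' preferentially located motif.  Decoy 6-mers occur at background rates
#' only.
#'
#' @inheritParams simulate_counts
#' @return A list with `promoters` (tibble `gene_id`, `sequence`,
#'   `utr_length`, `upstream_length`, `truncated`, `strand`), `motifs`
#'   (library with the planted motif first) and `truth` (planted positions;
#'   `NA` for unplanted promoters).
#' @export
simulate_promoters <- function(config = sim_config(), seed = 1) {
  withr::with_seed(seed, {
    n <- config$n_promoters
    motif <- toupper(config$planted_motif)
    k <- nchar(motif)
    utr <- sample(seq(config$utr_range[1], config$utr_range[2]), n, replace = TRUE)
    if (any(1000 + utr < k)) abort("motif longer than promoter")
    seqs <- vapply(1000 + utr, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, "")
    n_plant <- round(config$plant_fraction * n)
    pos <- rep(NA_integer_, n)
    if (n_plant > 0) {
      p <- as.integer(round(rnorm(n_plant, config$plant_center, config$plant_sd)))
      p <- pmin(pmax(p, -1000L), utr[seq_len(n_plant)] - k)  # keep motif inside
      idx <- p + 1001L  # axis -> 1-based string index
      for (i in seq_len(n_plant)) {
        substr(seqs[i], idx[i], idx[i] + k - 1L) <- motif
      }
      pos[seq_len(n_plant)] <- p
    }
    decoys <- character(0)
    while (length(decoys) < config$n_decoy_motifs) {
      cand <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
      if (!cand %in% c(decoys, motif)) decoys <- c(decoys, cand)
    }
    gene_id <- sprintf("P%04d", seq_len(n))
    list(
      promoters = tibble(gene_id = gene_id, sequence = seqs,
                         utr_length = as.integer(utr),
                         upstream_length = 1000L, truncated = FALSE,
                         strand = rep_len(c("+", "-"), n)),
      motifs = tibble(name = c("planted", sprintf("decoy%02d", seq_along(decoys))),
                      pattern = c(motif, decoys)),
      truth = tibble(gene_id = gene_id, planted_position = pos))
  })
}

#' Simulate gene-to-term annotations with one enriched term
#'
#' Term `T01` is assigned to genes of `enriched_category` with probability
#' `p_in` and to all other genes with probability `p_out`; the remaining
#' terms are assigned to every gene independently with probability `p_out`.
#'
#' @inheritParams simulate_traits
#' @param seed Integer seed.
#' @return A long annotation tibble (`gene_id`, `term`).
#' @export
simulate_annotations <- function(truth, config = sim_config(), seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(truth)
    terms <- sprintf("T%02d", seq_len(config$n_terms))
    in_cat <- truth$category == config$enriched_category
    rows <- purrr::map_dfr(seq_along(terms), function(j) {
      p <- if (j == 1) ifelse(in_cat, config$p_in, config$p_out) else config$p_out
      hit <- runif(n) < p
      tibble(gene_id = truth$gene_id[hit], term = terms[j])
    })
    validate_annotations(rows)
  })
}
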