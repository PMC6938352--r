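#' Configuration for the end-to-end synthetic pipeline
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @param alpha_de BH cut-off for the stepwise DE.
#' @param alpha_cor Significance level of the correlation t rule.
#' @param network_threshold |PCC| edge threshold.
#' @param plm_bin_width PLM bin width in bases.
#' @param sim A [sim_config()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, alpha_de = 0.05,
                            alpha_cor = 0.05, network_threshold = 0.995,
                            plm_bin_width = 10, sim = sim_config()) {
  for (th in c(alpha_de, alpha_cor, network_threshold)) {
    if (!is.numeric(th) || th <= 0 || th >= 1) {
      abort("thresholds must lie in (0, 1)")
    }
  }
  if ((1000 - 300) %% plm_bin_width != 0) {
    abort("plm_bin_width must divide the 700-base background span")
  }
  if (!inherits(sim, "sim_config")) abort("sim must be a sim_config()")
  seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = seed, alpha_de = alpha_de,
                 alpha_cor = alpha_cor,
                 network_threshold = network_threshold,
                 plm_bin_width = plm_bin_width, sim = sim),
            class = "pipeline_config")
}

#' Run the full synthetic-study pipeline
#'
#' Executes the stages in dependency order: simulate (counts, design,
#' traits, promoters, motifs, annotations, truth written as plain text),
#' stepwise DE, SPE calling, gene-trait correlation on the final DE genes,
#' co-expression network with module summary, PLM screen, and enrichment of
#' the final DE list.  Analysis stages re-read their inputs from the files
#' the simulate stage wrote, so every generated format round-trips through
#' the package readers.  Identical config + seed give byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return A manifest tibble (`stage`, `file`, `md5`), invisibly also
#'   written to `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  manifest <- list()
  note <- function(stage, files) {
    manifest[[stage]] <<- tibble(stage = stage, file = basename(files),
                                 md5 = unname(tools::md5sum(files)))
  }
  seeds <- config$seed + 0:3  # counts, traits, promoters, annotations

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  ## 1. simulate ------------------------------------------------------
  run_stage("simulate", {
    sim <- simulate_counts(config$sim, seed = seeds[1])
    write_counts(sim$counts, path("counts.tsv"))
    readr::write_tsv(sim$design, path("design.tsv"), progress = FALSE)
    readr::write_tsv(sim$truth, path("truth.tsv"), progress = FALSE)
    em <- genotype_means(cpm_log2(sim$counts), sim$design)
    tr <- simulate_traits(sim$truth, em, config$sim, seed = seeds[2])
    readr::write_tsv(tr$traits, path("traits.tsv"), progress = FALSE)
    prom <- simulate_promoters(config$sim, seed = seeds[3])
    withr::with_seed(seeds[3], write_promoter_files(
      prom$promoters, path("promoters.fasta"), path("promoters.gff3")))
    readr::write_tsv(prom$motifs, path("motifs.tsv"), progress = FALSE)
    ann <- simulate_annotations(sim$truth, config$sim, seed = seeds[4])
    readr::write_tsv(ann, path("annotations.tsv"), progress = FALSE)
    note("simulate", path(c("counts.tsv", "design.tsv", "truth.tsv",
                            "traits.tsv", "promoters.fasta",
                            "promoters.gff3", "motifs.tsv",
                            "annotations.tsv")))
  })

  counts <- read_counts(path("counts.tsv"))
  design <- read_design(path("design.tsv"))

  ## 2. stepwise DE ---------------------------------------------------
  de <- run_stage("de", {
    de <- run_stepwise(counts, design, alpha = config$alpha_de)
    readr::write_tsv(de$tests, path("de_tests.tsv"), progress = FALSE)
    readr::write_tsv(de$genes, path("de_genes.tsv"), progress = FALSE)
    note("de", path(c("de_tests.tsv", "de_genes.tsv")))
    de
  })

  ## 3. SPE -----------------------------------------------------------
  run_stage("spe", {
    spe <- detect_spe(counts, design)
    readr::write_tsv(spe, path("spe.tsv"), progress = FALSE)
    note("spe", path("spe.tsv"))
  })

  ## 4. correlate -----------------------------------------------------
  cors <- run_stage("correlate", {
    em <- genotype_means(cpm_log2(counts), design)
    genes <- de$genes$gene_id
    if (length(genes) < 2) {
      warn("fewer than two final DE genes; correlating all genes")
      genes <- em$gene_id
    }
    traits <- read_traits(path("traits.tsv"))
    cors <- correlate_genes_traits(em[em$gene_id %in% genes, ], traits,
                                   alpha = config$alpha_cor)
    readr::write_tsv(cors, path("correlations.tsv"), progress = FALSE)
    note("correlate", path("correlations.tsv"))
    cors
  })

  ## 5. network -------------------------------------------------------
  run_stage("network", {
    em <- genotype_means(cpm_log2(counts), design)
    genes <- unique(cors$gene_id)
    net <- build_network(em, genes = genes,
                         threshold = config$network_threshold)
    export_network(net, graphml = path("network.graphml"),
                   edges_tsv = path("edges.tsv"))
    readr::write_tsv(net$nodes, path("modules.tsv"), progress = FALSE)
    readr::write_tsv(module_summary(net, cors),
                     path("module_summary.tsv"), progress = FALSE)
    note("network", path(c("network.graphml", "edges.tsv", "modules.tsv",
                           "module_summary.tsv")))
  })

  ## 6. PLM -----------------------------------------------------------
  run_stage("plm", {
    prom <- suppressMessages(
      read_promoters(path("promoters.fasta"), path("promoters.gff3")))
    motifs <- read_motifs(path("motifs.tsv"))
    plm <- suppressMessages(
      run_plm(prom, motifs, bin_width = config$plm_bin_width))
    readr::write_tsv(plm, path("plm.tsv"), progress = FALSE)
    note("plm", path("plm.tsv"))
  })

  ## 7. enrichment ----------------------------------------------------
  run_stage("enrich", {
    ann <- read_annotations(path("annotations.tsv"))
    res <- enrich(de$genes$gene_id, ann, alpha = config$alpha_de)
    readr::write_tsv(res, path("enrichment.tsv"), progress = FALSE)
    note("enrich", path("enrichment.tsv"))
  })

  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, path("manifest.tsv"), progress = FALSE)
  manifest
}
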