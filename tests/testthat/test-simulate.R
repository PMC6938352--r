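test_that("the generator is deterministic and honors category sizes exactly", {
  cfg <- sim_config(n_genes = 300, n_allele = 25, n_nil = 20,
                    n_interaction = 15, n_spe_f288 = 5, n_spe_f271 = 5)
  a <- simulate_counts(cfg, seed = 3)
  b <- simulate_counts(cfg, seed = 3)
  expect_identical(a, b)
  expect_equal(as.vector(table(a$truth$category)[c("allele", "nil", "interaction",
                                                   "spe_f288", "spe_f271", "null")]),
               c(25L, 20L, 15L, 5L, 5L, 230L))
  expect_false(identical(a$counts, simulate_counts(cfg, seed = 4)$counts))
})

test_that("null genes scatter around their baseline and SPE genes are structural zeros", {
  cfg <- sim_config(n_genes = 500, n_allele = 0, n_nil = 0, n_interaction = 0,
                    n_spe_f288 = 20, n_spe_f271 = 20, dispersion = 0.1,
                    lib_factor_range = c(1, 1))
  sim <- simulate_counts(cfg, seed = 21)
  m <- as.matrix(sim$counts[-1])
  f271 <- grepl("F271", names(sim$counts)[-1])

  spe288 <- sim$truth$category == "spe_f288"
  expect_true(all(m[spe288, f271] == 0))
  expect_true(all(m[sim$truth$category == "spe_f271", !f271] == 0))

  nulls <- which(sim$truth$category == "null")
  mu <- sim$truth$baseline[nulls]
  se <- sqrt((mu + 0.1 * mu^2) / 7)
  dev <- abs(rowMeans(m[nulls, ]) - mu) / se
  # per-gene sample mean within 3 SE of baseline for almost all genes
  expect_gt(mean(dev < 3), 0.99)
})

test_that("planted allele effects reproduce the configured fold change", {
  cfg <- sim_config(n_genes = 200, n_allele = 200, n_nil = 0,
                    n_interaction = 0, n_spe_f288 = 0, n_spe_f271 = 0,
                    lfc_allele = 3, baseline_meanlog = log(100),
                    baseline_sdlog = 0, dispersion = 0.05,
                    lib_factor_range = c(1, 1))
  sim <- simulate_counts(cfg, seed = 13)
  m <- as.matrix(sim$counts[-1])
  f288 <- !grepl("F271", colnames(m))
  up <- sim$truth$lfc > 0
  ratio <- rowMeans(m[up, f288]) / rowMeans(m[up, !f288])
  expect_gt(median(ratio), 6)
  expect_lt(median(ratio), 10)
  down <- sim$truth$lfc < 0
  ratio_dn <- rowMeans(m[down, !f288]) / rowMeans(m[down, f288])
  expect_gt(median(ratio_dn), 6)
  expect_lt(median(ratio_dn), 10)
})

test_that("noise-free traits are exactly (anti)linear in their coupled gene", {
  cfg <- sim_config(n_genes = 50, n_allele = 10, n_nil = 0, n_interaction = 0,
                    n_spe_f288 = 0, n_spe_f271 = 0, trait_noise_sd = 0,
                    genes_per_trait = 1, traits = c("IVNDFD", "Hcell/NDF"))
  sim <- simulate_counts(cfg, seed = 2)
  em <- genotype_means(cpm_log2(sim$counts), sim$design)
  tr <- simulate_traits(sim$truth, em, cfg, seed = 2)
  for (i in 1:2) {
    cp <- tr$coupling[i, ]
    gene <- unlist(em[em$gene_id == cp$gene_id, -1])
    trait <- tr$traits$value[tr$traits$trait == cp$trait]
    expect_equal(unname(cor(gene, trait)), sign(cp$coef), tolerance = 1e-12)
  }
  expect_error(
    simulate_traits(sim$truth, em, cfg, seed = 1,
                    coupling = tibble::tibble(trait = "IVNDFD",
                                              gene_id = "nope", coef = 1)),
    "absent from truth")
})

test_that("trait noise calibrated near the threshold matches a direct Monte-Carlo estimate", {
  # single coupled gene, noise sized so |PCC| straddles 0.95 at n = 4
  withr::local_seed(31)
  gene <- c(0, 0, 4, 4)  # allele pattern over the four classes
  noise_sd <- 0.8
  sig <- replicate(400, {
    trait <- gene + rnorm(4, 0, noise_sd)
    abs(cor(gene, trait)) > 0.95
  })
  cfg <- sim_config(n_genes = 20, n_allele = 1, n_nil = 0, n_interaction = 0,
                    n_spe_f288 = 0, n_spe_f271 = 0, genes_per_trait = 1,
                    traits = "IVNDFD", trait_noise_sd = noise_sd)
  truth <- tibble::tibble(gene_id = "G00001", category = "allele",
                          lfc = 2, lfc_nil = 0, baseline = 100)
  em <- counts_tbl(matrix(gene, 1, 4,
                          dimnames = list(NULL, c("1^F271", "1^F288",
                                                  "2^F271", "2^F288"))),
                   gene_ids = "G00001")
  calls <- vapply(1:400, function(s) {
    tr <- simulate_traits(truth, em, cfg, seed = s)
    abs(cor(unlist(em[1, -1]), tr$traits$value)) > 0.95
  }, TRUE)
  # binomial 3-sigma agreement between generator calls and the direct oracle
  p_hat <- mean(sig)
  expect_lt(abs(mean(calls) - p_hat),
            3 * sqrt(p_hat * (1 - p_hat) * 2 / 400) + 0.01)
})

test_that("promoter generator plants motifs where asked and keeps clean backgrounds", {
  cfg0 <- sim_config(n_promoters = 200, plant_fraction = 0, utr_range = c(50, 50))
  bg <- simulate_promoters(cfg0, seed = 17)
  occ <- scan_motif(bg$promoters, "CATGTG")
  lambda <- (1050 - 6 + 1) * (1 / 4)^6
  se <- sqrt(lambda / 200)
  expect_lt(abs(nrow(occ) / 200 - lambda), 3 * se)

  cfg1 <- sim_config(n_promoters = 50, plant_fraction = 1, plant_sd = 1e-9,
                     plant_center = -50)
  planted <- simulate_promoters(cfg1, seed = 18)
  expect_true(all(planted$truth$planted_position == -50))
  expect_true(all(vapply(planted$promoters$sequence,
                         function(s) substr(s, 951, 956) == "CATGTG", TRUE)))

  expect_true(all(planted$promoters$utr_length >= 10))
  expect_equal(nrow(run_plm(planted$promoters[1:5, ],
                            planted$motifs[1, ]) |> suppressMessages()), 1)
})

test_that("annotation generator concentrates the enriched term where told", {
  cfg <- sim_config(n_genes = 400, n_allele = 40, n_nil = 0, n_interaction = 0,
                    n_spe_f288 = 0, n_spe_f271 = 0, p_in = 1, p_out = 0)
  truth <- simulate_counts(cfg, seed = 5)$truth
  ann <- simulate_annotations(truth, cfg, seed = 5)
  t01 <- ann$gene_id[ann$term == "T01"]
  expect_setequal(t01, truth$gene_id[truth$category == "allele"])

  # p_in = p_out: no signal, enrichment p roughly uniform over repeats
  cfg2 <- sim_config(n_genes = 300, n_allele = 30, n_nil = 0, n_interaction = 0,
                     n_spe_f288 = 0, n_spe_f271 = 0, p_in = 0.2, p_out = 0.2,
                     n_terms = 5)
  ps <- vapply(1:40, function(s) {
    ann <- simulate_annotations(truth[1:300, ], cfg2, seed = s)
    res <- suppressWarnings(
      enrich(truth$gene_id[truth$category == "allele"], ann))
    res$p[res$term == "T01"]
  }, 0)
  # no signal: enrichment p far from systematically small over repeats
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps < 0.1), 0.3)
})
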