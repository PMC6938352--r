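#' Estimate the common negative-binomial dispersion
#'
#' Maximizes the summed NB profile (adjusted) likelihood over genes for one
#' shared dispersion, via edgeR.  Seven samples barely support gene-wise
#' estimation, so the common value is the default for all fits; tagwise
#' shrinkage toward the common value is available with a configurable prior
#' weight.
#'
#' @param counts Counts tibble; all-zero gene rows must be filtered first.
#' @param design Design tibble ([read_design()]).
#' @param formula Model formula in `allele` / `nil_pair`.
#' @param factors Optional [tmm_factors()] output.
#' @param subsample Cap on the number of genes used (evenly spaced,
#'   deterministic); `Inf` uses all genes.
#' @param tagwise If `TRUE`, return per-gene dispersions shrunk toward the
#'   common value.
#' @param prior_df Prior degrees of freedom for the shrinkage.
#' @return A single dispersion, or a per-gene vector when `tagwise = TRUE`.
#' @export
estimate_dispersion <- function(counts, design, formula = ~ allele * nil_pair,
                                factors = NULL, subsample = Inf,
                                tagwise = FALSE, prior_df = 10) {
  design <- align_design(counts, design)
  m <- counts_matrix(counts)
  if (any(rowSums(m) == 0)) abort("filter all-zero gene rows before dispersion estimation")
  X <- model.matrix(formula, data = design)
  if (nrow(X) - ncol(X) < 1) abort("no residual degrees of freedom")
  keep <- if (is.finite(subsample) && subsample < nrow(m)) {
    unique(round(seq(1, nrow(m), length.out = subsample)))
  } else {
    seq_len(nrow(m))
  }
  factors <- factors %||% tmm_factors(counts)
  offset <- log(factors$eff_lib_size[match(colnames(m), factors$sample_id)])
  common <- edgeR::estimateGLMCommonDisp(m[keep, , drop = FALSE], X,
                                         offset = offset)
  if (!tagwise) return(common)
  tw <- edgeR::estimateGLMTagwiseDisp(m, X, offset = offset,
                                      dispersion = common,
                                      prior.df = prior_df, trend = FALSE)
  setNames(tw, rownames(m))
}

#' Fit per-gene negative-binomial GLMs
#'
#' Fits `log mu = offset + X beta` per gene at fixed dispersion (edgeR's
#' Levenberg-damped IRLS).  Coefficients are on the natural-log scale;
#' deviance is twice the saturated-minus-fitted log-likelihood, so nested
#' fits can be compared with [nb_lrt()].
#'
#' @param counts Counts tibble.
#' @param design_matrix Numeric model matrix (rows = samples in count
#'   column order); must be full rank.
#' @param dispersion NB dispersion (scalar or per-gene).
#' @param offset Per-sample log effective library sizes; computed from TMM
#'   factors when `NULL`.
#' @return An object of class `nb_fit` with elements `gene_id`,
#'   `coefficients`, `fitted`, `deviance`, `df_residual`, `design`,
#'   `offset`, `dispersion`.
#' @export
nb_fit <- function(counts, design_matrix, dispersion, offset = NULL) {
  m <- counts_matrix(counts)
  if (qr(design_matrix)$rank < ncol(design_matrix)) {
    abort("design matrix is rank deficient")
  }
  offset <- offset %||% {
    f <- tmm_factors(counts)
    log(f$eff_lib_size[match(colnames(m), f$sample_id)])
  }
  fit <- edgeR::glmFit(m, design = design_matrix, dispersion = dispersion,
                       offset = offset, prior.count = 0)
  structure(list(gene_id = rownames(m),
                 coefficients = fit$coefficients,
                 fitted = fit$fitted.values,
                 deviance = unname(fit$deviance),
                 df_residual = nrow(design_matrix) - ncol(design_matrix),
                 design = design_matrix,
                 offset = offset,
                 dispersion = dispersion,
                 counts = m),
            class = "nb_fit")
}

#' Per-gene NB log-likelihood of a fit
#'
#' Recovered from the deviance as `ll = ll_saturated - deviance / 2`, with
#' the saturated log-likelihood evaluated at `mu = y`.
#'
#' @param fit An [nb_fit()] object.
#' @return Named numeric vector of log-likelihoods.
#' @export
nb_loglik <- function(fit) {
  y <- fit$counts
  phi <- rep_len(fit$dispersion, nrow(y))
  ll_sat <- vapply(seq_len(nrow(y)), function(g) {
    mu <- pmax(y[g, ], 1e-10)
    if (phi[g] > 0) {
      sum(stats::dnbinom(y[g, ], mu = mu, size = 1 / phi[g], log = TRUE))
    } else {
      sum(stats::dpois(y[g, ], mu, log = TRUE))
    }
  }, 0)
  setNames(ll_sat - fit$deviance / 2, fit$gene_id)
}

#' Likelihood-ratio test between nested NB fits
#'
#' Statistic = reduced deviance - full deviance, referred to a chi-squared
#' distribution with `df` degrees of freedom (the canonical edgeR-era GLM
#' test).  Small negative statistics from convergence noise are clamped to
#' zero; larger ones signal non-nested models and raise an error.
#'
#' @param full,reduced [nb_fit()] objects on the same counts, offsets and
#'   dispersion.
#' @param df Degrees of freedom; defaults to the difference in model ranks.
#' @return A tibble `gene_id`, `stat`, `df`, `p`.
#' @export
nb_lrt <- function(full, reduced, df = NULL) {
  if (!identical(full$gene_id, reduced$gene_id)) {
    abort("fits cover different genes")
  }
  df <- df %||% (ncol(full$design) - ncol(reduced$design))
  if (df < 1) abort("reduced model is not nested in full")
  stat <- reduced$deviance - full$deviance
  # the IRLS converges on relative deviance change ~1e-6; smaller negative
  # discrepancies are numerical noise, anything beyond signals a bad pair
  tol <- -1e-6 * pmax(1, abs(reduced$deviance))
  if (any(stat < tol)) {
    abort(paste0("negative LRT statistic for gene ",
                 full$gene_id[which(stat < tol)[1]],
                 "; models non-nested or not converged"))
  }
  stat <- pmax(stat, 0)
  tibble(gene_id = full$gene_id, stat = stat, df = df,
         p = pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, capped at one and monotone in rank.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Set algebra of the four-step procedure
#'
#' Pure intersection logic: per pair, step III removes from the pair's
#' allele-DE set (step II) any gene significant for the NIL main effect or
#' the allele x NIL interaction in the joint model (step I); the final set
#' is the intersection of the two step III sets.
#'
#' @param step1_interaction,step1_nil Character vectors of genes significant
#'   for the interaction / NIL term in the joint model.
#' @param step2_pair1,step2_pair2 Per-pair allele-DE gene sets.
#' @return A list with `step3_pair1`, `step3_pair2`, `final`.
#' @export
stepwise_sets <- function(step1_interaction, step1_nil,
                          step2_pair1, step2_pair2) {
  drop <- union(step1_interaction, step1_nil)
  s3_1 <- setdiff(step2_pair1, drop)
  s3_2 <- setdiff(step2_pair2, drop)
  list(step3_pair1 = s3_1, step3_pair2 = s3_2,
       final = intersect(s3_1, s3_2))
}

#' Four-step introgression-specific differential expression
#'
#' Step I fits `~ allele * nil_pair` over all samples and tests the
#' interaction (full vs additive) and the NIL main effect (additive vs
#' allele-only) by likelihood-ratio tests, BH-adjusted within each term
#' family.  Step II fits `~ allele` within each NIL pair and records the
#' per-pair allele-DE sets.  Step III removes from each pair's set the
#' genes with significant NIL or interaction effects, and the final set is
#' the intersection across pairs: genes whose expression responds to the
#' introgressed allele identically in both genetic backgrounds.  Direction
#' (Up/Down in F288 relative to F271) comes from the sign of the allele
#' log2 fold change and must agree across pairs, else `"discordant"`.
#'
#' @param counts Counts tibble; all-zero gene rows are dropped.
#' @param design Design tibble covering both NIL pairs.
#' @param alpha BH-adjusted significance cut-off applied at every step.
#' @param dispersion Common NB dispersion; estimated from the data when
#'   `NULL`.
#' @param dispersion_subsample Gene cap passed to [estimate_dispersion()].
#' @return An object of class `stepwise_de`: list with `tests` (long tibble
#'   of every LRT: `gene_id`, `term`, `lfc`, `stat`, `df`, `p`, `p_adj`),
#'   `sets` (the step gene sets), `genes` (per final gene: direction and
#'   per-pair log2 fold changes), `alpha`, `dispersion`, `n_filtered`.
#' @export
run_stepwise <- function(counts, design, alpha = 0.05, dispersion = NULL,
                         dispersion_subsample = Inf) {
  design <- align_design(counts, design)
  m <- counts_matrix(counts)
  keep <- rowSums(m) > 0
  n_filtered <- sum(!keep)
  counts <- counts[keep, ]
  m <- m[keep, , drop = FALSE]

  factors <- tmm_factors(counts)
  offset <- log(factors$eff_lib_size[match(colnames(m), factors$sample_id)])
  dispersion <- dispersion %||%
    estimate_dispersion(counts, design, factors = factors,
                        subsample = dispersion_subsample)

  dd <- dplyr::mutate(design,
                      allele = factor(.data$allele, levels = ALLELES),
                      nil_pair = factor(.data$nil_pair, levels = c(1, 2)))
  X_full <- model.matrix(~ allele * nil_pair, dd)
  X_add <- model.matrix(~ allele + nil_pair, dd)
  X_allele <- model.matrix(~ allele, dd)

  fit_full <- nb_fit(counts, X_full, dispersion, offset)
  fit_add <- nb_fit(counts, X_add, dispersion, offset)
  fit_allele <- nb_fit(counts, X_allele, dispersion, offset)

  t_int <- nb_lrt(fit_full, fit_add) |>
    dplyr::mutate(term = "interaction",
                  lfc = fit_full$coefficients[, "alleleF288:nil_pair2"] / log(2))
  t_nil <- nb_lrt(fit_add, fit_allele) |>
    dplyr::mutate(term = "nil",
                  lfc = fit_add$coefficients[, "nil_pair2"] / log(2))

  pair_test <- function(pair) {
    in_pair <- dd$nil_pair == pair
    sub <- counts[c(TRUE, in_pair)]
    dsub <- dd[in_pair, ]
    Xa <- model.matrix(~ allele, dsub)
    X0 <- Xa[, 1, drop = FALSE]
    f1 <- nb_fit(sub, Xa, dispersion, offset[in_pair])
    f0 <- nb_fit(sub, X0, dispersion, offset[in_pair])
    nb_lrt(f1, f0) |>
      dplyr::mutate(term = paste0("allele_pair", pair),
                    lfc = f1$coefficients[, "alleleF288"] / log(2))
  }
  t_p1 <- pair_test(1)
  t_p2 <- pair_test(2)

  tests <- dplyr::bind_rows(t_int, t_nil, t_p1, t_p2) |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "term", "lfc", "stat", "df", "p", "p_adj")

  sig <- split(tests$gene_id[tests$p_adj <= alpha], tests$term[tests$p_adj <= alpha])
  sets <- stepwise_sets(sig[["interaction"]] %||% character(0),
                        sig[["nil"]] %||% character(0),
                        sig[["allele_pair1"]] %||% character(0),
                        sig[["allele_pair2"]] %||% character(0))
  sets <- c(list(step1_interaction = sig[["interaction"]] %||% character(0),
                 step1_nil = sig[["nil"]] %||% character(0),
                 step2_pair1 = sig[["allele_pair1"]] %||% character(0),
                 step2_pair2 = sig[["allele_pair2"]] %||% character(0)),
            sets)

  lfc1 <- setNames(t_p1$lfc, t_p1$gene_id)[sets$final]
  lfc2 <- setNames(t_p2$lfc, t_p2$gene_id)[sets$final]
  direction <- ifelse(sign(lfc1) != sign(lfc2), "discordant",
                      ifelse(lfc1 > 0, "Up", "Down"))
  genes <- tibble(gene_id = sets$final, direction = direction,
                  lfc_pair1 = unname(lfc1), lfc_pair2 = unname(lfc2))

  structure(list(tests = tests, sets = sets, genes = genes, alpha = alpha,
                 dispersion = dispersion, n_filtered = n_filtered),
            class = "stepwise_de")
}

#' @export
print.stepwise_de <- function(x, ...) {
  cat("Four-step introgression-specific DE\n")
  cat(sprintf("  dispersion %.4f, alpha %.3g, %d all-zero genes dropped\n",
              x$dispersion, x$alpha, x$n_filtered))
  cat(sprintf("  step II: %d (pair 1), %d (pair 2); step III: %d / %d; final: %d (%d Up, %d Down)\n",
              length(x$sets$step2_pair1), length(x$sets$step2_pair2),
              length(x$sets$step3_pair1), length(x$sets$step3_pair2),
              nrow(x$genes), sum(x$genes$direction == "Up"),
              sum(x$genes$direction == "Down")))
  invisible(x)
}

#' Call single pattern expression (SPE) genes
#'
#' A gene is SPE_F288 when it is unmeasurable (count <= `max_silent`) in
#' every F271 sample of both pairs and measurable (count >= `min_expressed`)
#' in every F288 sample; SPE_F271 is symmetric.
#'
#' @param counts Counts tibble.
#' @param design Design tibble.
#' @param max_silent Largest count still treated as silence.
#' @param min_expressed Smallest count treated as expression.
#' @return A tibble `gene_id`, `pattern` (`SPE_F288` / `SPE_F271` /
#'   `none`), `max_silent_count`, `min_expressed_count` (NA for `none`).
#' @export
detect_spe <- function(counts, design, max_silent = 0, min_expressed = 1) {
  design <- align_design(counts, design)
  m <- counts_matrix(counts)
  f271 <- design$allele == "F271"
  max271 <- apply(m[, f271, drop = FALSE], 1, max)
  min271 <- apply(m[, f271, drop = FALSE], 1, min)
  max288 <- apply(m[, !f271, drop = FALSE], 1, max)
  min288 <- apply(m[, !f271, drop = FALSE], 1, min)
  spe288 <- max271 <= max_silent & min288 >= min_expressed
  spe271 <- max288 <= max_silent & min271 >= min_expressed
  pattern <- unname(ifelse(spe288, "SPE_F288", ifelse(spe271, "SPE_F271", "none")))
  tibble(gene_id = rownames(m), pattern = pattern,
         max_silent_count = unname(ifelse(spe288, max271,
                                          ifelse(spe271, max288, NA))),
         min_expressed_count = unname(ifelse(spe288, min288,
                                             ifelse(spe271, min271, NA))))
}
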