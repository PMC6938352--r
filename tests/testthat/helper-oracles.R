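# Independent brute-force oracles, kept free of the package's code paths.

# doubly trimmed (30% M / 5% A), inverse-variance weighted mean of gene-wise
# log2 ratios against a reference column, rescaled to geometric mean 1
oracle_tmm <- function(m, ref) {
  lib <- colSums(m)
  f <- vapply(seq_len(ncol(m)), function(j) {
    obs <- m[, j]
    refc <- m[, ref]
    nO <- lib[j]
    nR <- lib[ref]
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    fj <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
    if (is.na(fj)) fj <- 0
    2^fj
  }, 0)
  f / exp(mean(log(f)))
}

# direct NB pmf evaluation via the lgamma form of the density
oracle_nb_loglik <- function(y, mu, phi) {
  r <- 1 / phi
  sum(lgamma(y + r) - lgamma(r) - lfactorial(y) +
        r * log(r / (r + mu)) + y * log(mu / (r + mu)))
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# naive sliding-window IUPAC scan; returns 1-based start indices
naive_scan <- function(sequence, pattern) {
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(length(s) - length(p) + 1)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (!s[i + j - 1] %in% IUPAC_SETS[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# union-find connected components; returns membership list of sorted vectors
uf_components <- function(gene_ids, edges) {
  parent <- stats::setNames(gene_ids, gene_ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$gene_a[i]); rb <- find(edges$gene_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(gene_ids, find, "")
  touched <- unique(c(edges$gene_a, edges$gene_b))
  comp <- split(gene_ids, roots)
  comp <- comp[vapply(comp, function(g) any(g %in% touched), TRUE)]
  unname(lapply(comp, sort))
}

# exact combinatorial upper tail
exact_hyper_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# ordinary least squares through the normal equations
ols_normal_eq <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
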