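# Independent oracles, coded naively and kept separate from the package
# implementations they check.

# Exact HWE p by full enumeration of heterozygote counts with fixed allele
# counts (probabilities via choose(), not shared code).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n - n_A
  if (n_A == 0 || n_a == 0) return(1)
  rare <- min(n_A, n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  # P(het = h) = n! 2^h / (nAA! h! naa!) / (2n)! * nA! na! ... use ratios
  pr <- sapply(hets, function(h) {
    haa <- (n_A - h) / 2
    hbb <- (n_a - h) / 2
    if (n_A >= n_a) { tmp <- haa; haa <- hbb; hbb <- tmp }
    exp(lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
          h * log(2) + lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_Aa]
  sum(pr[pr <= p_obs + 1e-12])
}

# Dense-matrix GLS scan oracle: explicit inverse of V = sa2 K + se2 I.
gls_scan_oracle <- function(y, X, K, G, sa2, se2) {
  n <- length(y)
  V <- sa2 * K + se2 * diag(n)
  Vi <- solve(V)
  p <- qr(X)$rank
  t(sapply(seq_len(ncol(G)), function(j) {
    A <- cbind(X, G[, j])
    AtVi <- t(A) %*% Vi
    C <- solve(AtVi %*% A)
    b <- C %*% AtVi %*% y
    k <- ncol(A)
    se <- sqrt(C[k, k])
    tt <- b[k] / se
    c(effect = b[k], se = se,
      p = 2 * stats::pt(abs(tt), df = n - p - 1, lower.tail = FALSE))
  }))
}

# Naive O(n^3) PCIT reference: explicit loop over ordered conditioning
# nodes with the trio-mean tolerance, same skip rules as documented.
pcit_oracle <- function(r) {
  n <- nrow(r)
  sig <- matrix(TRUE, n, n)
  diag(sig) <- FALSE
  if (n < 3) return(sig)
  fop <- function(a, b, c) (a - b * c) / sqrt((1 - b^2) * (1 - c^2))
  for (x in seq_len(n - 1)) {
    for (y in (x + 1):n) {
      for (z in seq_len(n)) {
        if (z == x || z == y) next
        rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
        if (max(abs(c(rxy, rxz, ryz))) >= 1 - 1e-12) next
        tol <- (fop(rxy, rxz, ryz) / rxy +
                fop(rxz, rxy, ryz) / rxz +
                fop(ryz, rxy, rxz) / ryz) / 3
        if (!is.finite(tol)) next
        if (abs(rxy) <= abs(tol * rxz) && abs(rxy) <= abs(tol * ryz)) {
          sig[x, y] <- sig[y, x] <- FALSE
        }
      }
    }
  }
  sig
}

# Hypergeometric upper tail by direct enumeration with choose().
hyper_enum_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Brute-force SNP annotation: scan every gene interval.
annotate_oracle <- function(pos, chrom, genes, window) {
  t(mapply(function(p, ch) {
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) return(c(NA_character_, "intergenic"))
    d <- pmax(0, g$start - p, p - g$end)
    o <- order(d, g$gene_id)
    best <- o[1]
    cat_ <- if (d[best] == 0) "within_gene"
      else if (d[best] <= window) "near_gene" else "intergenic"
    c(if (cat_ == "intergenic") NA_character_ else g$gene_id[best], cat_)
  }, pos, chrom))
}

# A deliberately tiny half-sib genotype simulator for oracle-side checks
# (independent of simulate_genotypes()).
random_genotypes <- function(n, m, seed) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(seq_len(m), each = n)]),
              nrow = n)
  rownames(X) <- sprintf("a%03d", seq_len(n))
  colnames(X) <- sprintf("s%04d", seq_len(m))
  X
}

random_corr <- function(n, seed, p = NULL) {
  set.seed(seed)
  p <- p %||% sample(3:8, 1)
  stats::cor(t(matrix(rnorm(n * p), n, p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
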