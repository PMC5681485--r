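sim_small <- function(seed, n = 200, m = 400, h2 = 0.5, n_sires = 20) {
  cfg <- sim_config(n_animals = n, n_sires = n_sires, n_snps = m, n_traits = 1,
                    heritabilities = h2, n_qtl = 0, missing_pheno_rate = 0,
                    seed = seed)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  list(g = g, y = ph$phenotypes$trait_1, X = cg_design(ph$phenotypes$cg),
       K = stabilize(compute_grm(g)))
}

test_that("an identity kinship yields the flat-likelihood diagnostic", {
  set.seed(1)
  y <- rnorm(50)
  X <- matrix(1, 50, 1)
  expect_warning(
    vc <- estimate_variance_components(y, X, diag(50)),
    "flat"
  )
  expect_false(vc$identifiable)
})

test_that("profile REML beats a dense grid over log(delta)", {
  d <- sim_small(seed = 3, n = 30, m = 120, n_sires = 3)
  vc <- estimate_variance_components(d$y, d$X, d$K)
  # independent profile evaluation at 1,000 grid points
  eg <- eigen(d$K$K, symmetric = TRUE)
  ys <- crossprod(eg$vectors, d$y)
  Xs <- crossprod(eg$vectors, vc$X)
  n <- length(d$y); p <- ncol(vc$X)
  ldXtX <- determinant(crossprod(vc$X))$modulus
  prof <- function(ld) {
    w <- 1 / (pmax(eg$values, 0) + exp(ld))
    fit <- stats::lm.fit(Xs * sqrt(w), ys * sqrt(w))
    s2 <- sum(fit$residuals^2) / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) - sum(log(w)) +
              determinant(crossprod(Xs * sqrt(w)))$modulus - ldXtX)
  }
  grid_best <- max(vapply(seq(-10, 10, length.out = 1000), prof, numeric(1)))
  expect_gte(vc$loglik, grid_best - 1e-6)
})

test_that("pseudo-heritability is the variance-component ratio", {
  expect_equal(pseudo_heritability(list(sigma_a2 = 2, sigma_e2 = 2)), 0.5)
  expect_equal(pseudo_heritability(list(sigma_a2 = 0, sigma_e2 = 1)), 0)
  expect_equal(pseudo_heritability(list(sigma_a2 = 0.38, sigma_e2 = 0.62)), 0.38)
  expect_error(pseudo_heritability(list(sigma_a2 = 0, sigma_e2 = 0)), "undefined")
})

test_that("with identity covariance the scan reduces to the OLS slope", {
  y <- c(1, 2, 3, 4)
  X <- matrix(1, 4, 1)
  suppressWarnings(vc <- estimate_variance_components(y, X, diag(4)))
  sc <- emmax_scan(y, X, vc, matrix(c(0, 1, 1, 2), 4, 1))
  expect_equal(sc$effect, 1.5, tolerance = 1e-10)  # = 3/2 hand-computed
})

test_that("scan matches the dense-matrix GLS oracle on small instances", {
  for (seed in 1:4) {
    d <- sim_small(seed = seed, n = 40, m = 25, n_sires = 5)
    vc <- estimate_variance_components(d$y, d$X, d$K)
    G <- impute_genotypes(d$g)
    got <- emmax_scan(d$y, vc$X, vc, G)
    want <- gls_scan_oracle(d$y, vc$X, d$K$K, G, vc$sigma_a2, vc$sigma_e2)
    ok <- !got$degenerate
    expect_equal(got$effect[ok], unname(want[ok, "effect"]), tolerance = 1e-8)
    expect_equal(got$p_value[ok], unname(want[ok, "p"]), tolerance = 1e-8)
  }
})

test_that("p-values are invariant to rescaling K and y", {
  d <- sim_small(seed = 6, n = 100, m = 150, n_sires = 10)
  G <- impute_genotypes(d$g)
  vc1 <- estimate_variance_components(d$y, d$X, d$K$K)
  p1 <- emmax_scan(d$y, vc1$X, vc1, G)$p_value
  vc2 <- estimate_variance_components(2.5 * d$y, d$X, 3 * d$K$K)
  p2 <- emmax_scan(2.5 * d$y, vc2$X, vc2, G)$p_value
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("in the sigma_a2 -> 0 limit the scan equals fixed-variance OLS", {
  d <- sim_small(seed = 8, n = 80, m = 100, n_sires = 8)
  G <- impute_genotypes(d$g)
  vc <- estimate_variance_components(d$y, d$X, d$K$K)
  vc$delta <- 1e8                      # force the no-heritability limit
  vc$sigma_a2 <- vc$sigma_e2 / vc$delta
  got <- emmax_scan(d$y, vc$X, vc, G)
  # OLS with the residual variance held fixed at sigma_e2 (the limit of
  # the fixed-covariance GLS test), coded independently via lm machinery
  qx <- qr(d$X)
  yt <- qr.resid(qx, d$y)
  Gt <- qr.resid(qx, G)
  beta <- colSums(Gt * yt) / colSums(Gt^2)
  se <- sqrt(vc$sigma_e2 / colSums(Gt^2))
  p <- 2 * pt(abs(beta / se), df = length(d$y) - ncol(d$X) - 1,
              lower.tail = FALSE)
  expect_equal(got$p_value, unname(p), tolerance = 1e-6)
})

test_that("monomorphic SNPs are flagged with p = 1 and zero effect", {
  d <- sim_small(seed = 9, n = 60, m = 30, n_sires = 6)
  vc <- estimate_variance_components(d$y, d$X, d$K$K)
  G <- impute_genotypes(d$g)
  G[, 5] <- 2
  sc <- emmax_scan(d$y, vc$X, vc, G)
  expect_true(sc$degenerate[5])
  expect_equal(sc$p_value[5], 1)
  expect_equal(sc$effect[5], 0)
})

test_that("multitrait runner handles duplicates, missingness and planted QTL", {
  cfg <- sim_config(n_animals = 250, n_sires = 20, n_snps = 500, n_traits = 2,
                    heritabilities = c(0.4, 0.4), n_qtl = 1,
                    pleiotropy_block_size = 2, qtl_effect_sd = 0.5,
                    missing_pheno_rate = 0.1, seed = 10)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  ph$phenotypes$trait_2b <- ph$phenotypes$trait_2
  res <- run_multitrait_gwas(ph$phenotypes, g)
  t2 <- dplyr::filter(res$gwas, trait == "trait_2")
  t2b <- dplyr::filter(res$gwas, trait == "trait_2b")
  expect_equal(t2$p_value, t2b$p_value)
  expect_equal(t2$effect, t2b$effect)
  # a ~0.5 SD-per-allele QTL dominates its trait's scan
  k1 <- dplyr::filter(res$gwas, trait == "trait_1")
  expect_equal(k1$snp_id[which.min(k1$p_value)], ph$truth$qtl_ids)
  # per-trait N honours missingness
  expect_true(all(res$trait_summary$n < cfg$n_animals))
  expect_error(
    suppressWarnings(run_multitrait_gwas(ph$phenotypes, g, min_n = 10000)),
    "enough non-missing"
  )
})

test_that("constant phenotypes and non-PSD kinship raise clear errors", {
  expect_error(
    estimate_variance_components(rep(1, 20), matrix(1, 20, 1), diag(20)),
    "constant"
  )
  K <- diag(20); K[1, 2] <- K[2, 1] <- 2  # indefinite
  set.seed(2)
  expect_error(
    estimate_variance_components(rnorm(20), matrix(1, 20, 1), K),
    "stabilize"
  )
})
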