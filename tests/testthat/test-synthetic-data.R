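test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_animals = 60, n_sires = 6, n_snps = 120, n_traits = 4,
                    n_qtl = 4, pleiotropy_block_size = 2, seed = 7)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$X, g2$X)
  expect_identical(g1$map, g2$map)
  p1 <- simulate_phenotypes(g1, cfg)
  p2 <- simulate_phenotypes(g2, cfg)
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_identical(p1$truth$qtl_effects, p2$truth$qtl_effects)
  gm1 <- make_gene_models(g1$map, p1$truth$qtl_ids, seed = 7)
  gm2 <- make_gene_models(g2$map, p2$truth$qtl_ids, seed = 7)
  expect_identical(as.data.frame(gm1), as.data.frame(gm2))
  t1 <- make_term_annotation(gm1, seed = 7)
  t2 <- make_term_annotation(gm2, seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(t1, f1); write_gmt(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate MAF range pins every simulated frequency", {
  cfg <- sim_config(n_animals = 400, n_sires = 40, n_snps = 50,
                    maf_range = c(0.3, 0.3), n_traits = 2,
                    n_qtl = 0, seed = 3)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$maf == 0.3))
  # realized frequencies concentrate around the target
  expect_lt(abs(mean(colMeans(g$X) / 2) - 0.3), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_sires = 100, n_animals = 50), "n_sires")
  expect_error(sim_config(heritabilities = rep(1.2, 10)), "heritabilities")
  expect_error(sim_config(n_qtl = 10, n_snps = 5), "n_qtl")
  # planted QTL variance exceeding a trait's heritability is caught
  cfg <- sim_config(n_animals = 100, n_sires = 10, n_snps = 200, n_traits = 2,
                    heritabilities = c(0.05, 0.05), n_qtl = 10,
                    pleiotropy_block_size = 2, qtl_effect_sd = 0.3, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_phenotypes(g, cfg), "exceeds heritability")
})

test_that("single-sire offspring are measurably related; unrelated are not", {
  # centring must use the founder frequencies: a GRM centred on in-sample
  # frequencies averages to ~0 off-diagonal by construction, so it cannot
  # show that *everyone* in a single family is related
  founder_grm <- function(cfg) {
    g <- simulate_genotypes(cfg)
    Z <- sweep(g$X, 2, 2 * g$maf)
    (Z %*% t(Z)) / (2 * sum(g$maf * (1 - g$maf)))
  }
  off1 <- founder_grm(sim_config(n_animals = 200, n_sires = 1, n_snps = 2000,
                                 n_traits = 1, n_qtl = 0, seed = 5))
  off2 <- founder_grm(sim_config(n_animals = 200, n_sires = 200, n_snps = 2000,
                                 n_traits = 1, n_qtl = 0, seed = 5))
  m1 <- mean(off1[upper.tri(off1)])
  m2 <- mean(off2[upper.tri(off2)])
  expect_gt(m1, m2 + 0.1)  # half-sibs ~0.25 vs ~0
})

test_that("offspring-sire relationship is near 0.5 on the GRM scale", {
  cfg <- sim_config(n_animals = 150, n_sires = 10, n_snps = 2500,
                    n_traits = 1, n_qtl = 0, seed = 9)
  g <- simulate_genotypes(cfg)
  K <- compute_grm(rbind(g$sire_X, g$X))$K
  ns <- nrow(g$sire_X)
  rel <- mapply(function(i, sire) K[match(sire, rownames(g$sire_X)), ns + i],
                seq_len(nrow(g$X)), g$sires)
  expect_lt(abs(mean(rel) - 0.5), 0.1)
})

test_that("zero heritability makes a trait genotype-independent", {
  cfg <- sim_config(n_animals = 300, n_sires = 25, n_snps = 800, n_traits = 1,
                    heritabilities = 0, n_qtl = 0, missing_pheno_rate = 0,
                    seed = 2)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  K <- stabilize(compute_grm(g))
  vc <- estimate_variance_components(ph$phenotypes$trait_1,
                                     cg_design(ph$phenotypes$cg), K)
  expect_lt(pseudo_heritability(vc), 0.12)
})

test_that("qtl_effect_sd = 0 leaves no QTL variance", {
  cfg <- sim_config(n_animals = 80, n_sires = 8, n_snps = 200, n_traits = 3,
                    n_qtl = 5, pleiotropy_block_size = 2, qtl_effect_sd = 0,
                    seed = 4)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  expect_true(all(ph$truth$qtl_effects == 0))
})

test_that("realized phenotypic variance tracks the unit target", {
  # variance after removing contemporary-group means, averaged over seeds
  devs <- sapply(1:10, function(s) {
    cfg <- sim_config(n_animals = 1000, n_sires = 74, n_snps = 600,
                      n_traits = 2, heritabilities = c(0.38, 0.5),
                      n_qtl = 4, pleiotropy_block_size = 2,
                      missing_pheno_rate = 0, seed = s)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)$phenotypes
    sapply(c("trait_1", "trait_2"), function(tr) {
      r <- stats::residuals(stats::lm(ph[[tr]] ~ ph$cg))
      var(r)
    })
  })
  expect_lt(abs(mean(devs) - 1), 0.1)
})

test_that("gene placement hits the requested in/near fractions exactly", {
  cfg <- sim_config(n_animals = 10, n_sires = 2, n_snps = 2000,
                    n_traits = 1, n_qtl = 0, seed = 6)
  g <- simulate_genotypes(cfg)
  gm <- make_gene_models(g$map, fraction_in_gene = 0.4,
                         fraction_near_gene = 0.1, seed = 6)
  ann <- annotate_snps(g$map$snp_id, g$map, gm, window = 2500)
  expect_lt(abs(mean(ann$category == "within_gene") - 0.4), 0.02)
  expect_lt(abs(mean(ann$category == "near_gene") - 0.1), 0.02)
  # genes never overlap
  by_chr <- split(gm, gm$chrom)
  for (b in by_chr) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
})

test_that("extreme gene fractions give all-genic and all-intergenic panels", {
  cfg <- sim_config(n_animals = 10, n_sires = 2, n_snps = 300, n_traits = 1,
                    n_qtl = 0, seed = 8)
  g <- simulate_genotypes(cfg)
  gm_all <- make_gene_models(g$map, fraction_in_gene = 1,
                             fraction_near_gene = 0, seed = 8)
  ann <- annotate_snps(g$map$snp_id, g$map, gm_all, window = 2500)
  expect_true(all(ann$category == "within_gene"))
  gm_none <- make_gene_models(g$map, fraction_in_gene = 0,
                              fraction_near_gene = 0, window = 0, seed = 8)
  expect_equal(nrow(gm_none), 0)
})

test_that("the planted causal term is the most enriched for QTL genes", {
  cfg <- sim_config(n_animals = 10, n_sires = 2, n_snps = 600, n_traits = 4,
                    n_qtl = 8, pleiotropy_block_size = 2, seed = 11)
  g <- simulate_genotypes(cfg)
  set.seed(1)
  qtl <- sample(g$map$snp_id, 8)
  gm <- make_gene_models(g$map, qtl_ids = qtl, seed = 11)
  ann <- annotate_snps(qtl, g$map, gm, window = 0)
  qtl_genes <- unique(ann$gene_id[!is.na(ann$gene_id)])
  terms <- make_term_annotation(gm, qtl_gene_ids = qtl_genes, seed = 11)
  expect_true(all(lengths(terms) > 0))
  enr <- hypergeometric_enrichment(qtl_genes, gm$gene_id, terms)
  expect_equal(enr$term[1], "causal_process")
  expect_equal(min(enr$p_value), enr$p_value[enr$term == "causal_process"])
})
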