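test_that("SNP annotation matches a brute-force interval scan", {
  set.seed(5)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:15), chrom = rep(c("chr1", "chr2"), c(8, 7)),
    start = c(sort(sample.int(5e5, 8)) * 2, sort(sample.int(5e5, 7)) * 2),
    strand = "+"
  )
  genes$end <- genes$start + sample(500:3000, 15)
  class(genes) <- c("gene_models", class(genes))
  map <- tibble::tibble(
    snp_id = sprintf("s%03d", 1:200),
    chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
    pos = sample.int(1.2e6, 200)
  )
  ann <- annotate_snps(map$snp_id, map, genes, window = 2500)
  oracle <- annotate_oracle(map$pos, map$chrom, genes, window = 2500)
  expect_equal(ann$category, unname(oracle[, 2]))
  expect_equal(ann$gene_id, unname(oracle[, 1]))
})

test_that("annotation boundaries and strand sub-categories are exact", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start = c(10000, 50000), end = c(12000, 52000), strand = c("+", "-")
  )
  class(genes) <- c("gene_models", class(genes))
  map <- tibble::tibble(
    snp_id = paste0("s", 1:6), chrom = "chr1",
    pos = c(10000, 7500, 7499, 14500, 52400, 49000)
  )
  ann <- annotate_snps(map$snp_id, map, genes, window = 2500)
  expect_equal(ann$category,
               c("within_gene", "near_gene", "intergenic", "near_gene",
                 "near_gene", "near_gene"))
  expect_equal(ann$distance[1], 0)
  expect_equal(ann$distance[2], 2500)
  # strand-aware: before a + gene is upstream; after a - gene is upstream
  expect_equal(ann$subcategory[2], "upstream")
  expect_equal(ann$subcategory[4], "downstream")
  expect_equal(ann$subcategory[5], "upstream")
  expect_equal(ann$subcategory[6], "downstream")
  # unknown chromosome -> intergenic with a warning
  map2 <- tibble::tibble(snp_id = "sX", chrom = "chrZ", pos = 100)
  expect_warning(ann2 <- annotate_snps("sX", map2, genes), "absent")
  expect_equal(ann2$category, "intergenic")
})

test_that("hypergeometric p equals exhaustive enumeration on small universes", {
  # the worked case: universe 20, term 5, list 5, full overlap
  terms <- structure(list(t1 = paste0("g", 1:5)), class = "term_sets")
  res <- hypergeometric_enrichment(paste0("g", 1:5), paste0("g", 1:20), terms)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 15504, tolerance = 1e-6)
  # random small instances vs choose() enumeration
  set.seed(7)
  for (i in 1:25) {
    N <- sample(8:30, 1)
    uni <- paste0("g", 1:N)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    term <- sample(uni, K)
    lst <- sample(uni, n)
    k <- length(intersect(term, lst))
    if (k == 0) next
    res <- hypergeometric_enrichment(lst, uni,
                                     structure(list(t = term), class = "term_sets"))
    expect_equal(res$p_value, hyper_enum_oracle(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("fold enrichment and FDR behave as printed in annotation charts", {
  # FE = (10/100)/(20/2000) = 10
  set.seed(1)
  uni <- paste0("g", 1:2000)
  lst <- paste0("g", 1:100)
  term <- paste0("g", c(1:10, 1001:1010))
  res <- hypergeometric_enrichment(
    lst, uni, structure(list(t = term), class = "term_sets")
  )
  expect_equal(res$fold_enrichment, 10)
  expect_equal(res$count, 10L)
  expect_equal(res$percent, 10)
  # BH is monotone along the p-ranking
  terms <- structure(
    lapply(1:20, function(i) sample(uni, 50)), class = "term_sets"
  )
  names(terms) <- paste0("t", 1:20)
  res2 <- hypergeometric_enrichment(lst, uni, terms)
  expect_true(all(diff(res2$fdr) >= -1e-12))
  expect_true(all(res2$fdr >= res2$p_value - 1e-12))
  expect_error(hypergeometric_enrichment(character(0), uni, terms), "non-empty")
  expect_error(hypergeometric_enrichment("absent", uni, terms), "outside")
})

test_that("null gene lists are calibrated across terms", {
  set.seed(11)
  uni <- paste0("g", 1:400)
  terms <- structure(
    setNames(lapply(1:30, function(i) sample(uni, sample(20:80, 1))),
             paste0("t", 1:30)),
    class = "term_sets"
  )
  hits <- replicate(400, {
    lst <- sample(uni, 40)
    res <- hypergeometric_enrichment(lst, uni, terms)
    sum(res$p_value < 0.05)
  })
  # discreteness makes the test slightly conservative; 5% is the ceiling
  expect_lt(abs(mean(hits) / 30 - 0.05), 0.02)
})

test_that("cluster enrichment scores are -log10 geometric means", {
  expect_equal(cluster_enrichment_score(c(0.05, 0.05)), -log10(0.05))
  expect_equal(round(cluster_enrichment_score(c(0.05, 0.05)), 3), 1.301)
  expect_equal(cluster_enrichment_score(0.1), 1)
  expect_equal(cluster_enrichment_score(c(0.01, 1)), 1)
  expect_error(cluster_enrichment_score(numeric(0)), "empty")
  expect_error(cluster_enrichment_score(c(0.5, 0)), "0, 1")
})

test_that("kappa agreement reproduces the hand-worked cases", {
  gl <- paste0("g", 1:4)
  terms <- structure(
    list(a = c("g1", "g2"), b = c("g1", "g2"), c = c("g3", "g4")),
    class = "term_sets"
  )
  K <- kappa_matrix(terms, gl)
  expect_equal(K["a", "b"], 1)          # identical membership
  expect_equal(K["a", "c"], -1)         # perfectly complementary
  expect_equal(K, t(K))
  expect_true(all(diag(K) == 1))
  # random independent memberships have near-zero mean kappa
  set.seed(13)
  gl2 <- paste0("g", 1:40)
  kaps <- replicate(500, {
    tt <- structure(list(x = sample(gl2, 20), y = sample(gl2, 20)),
                    class = "term_sets")
    kappa_matrix(tt, gl2)[1, 2]
  })
  expect_lt(abs(mean(kaps)), 0.02)
})

test_that("kappa grouping forms single-linkage components above threshold", {
  gl <- paste0("g", 1:12)
  terms <- structure(
    list(
      a1 = paste0("g", 1:5), a2 = paste0("g", 1:6), a3 = paste0("g", 2:5),
      b1 = paste0("g", 8:12), b2 = paste0("g", 8:11)
    ),
    class = "term_sets"
  )
  enr <- tibble::tibble(
    term = names(terms), p_value = c(0.01, 0.002, 0.03, 0.04, 0.001)
  )
  K <- kappa_matrix(terms, gl)
  gr <- group_terms(K, enr, threshold = 0.3)
  expect_equal(nrow(gr), 2)
  expect_setequal(unlist(gr$members[gr$representative == "a2"]),
                  c("a1", "a2", "a3"))
  # the representative always carries the group's minimum p
  expect_equal(gr$min_p,
               sapply(gr$members, function(m) min(enr$p_value[enr$term %in% m])))
  expect_equal(gr$representative[1], "b2")
  # an impossible threshold isolates every term
  gr1 <- group_terms(K, enr, threshold = 1)
  expect_equal(nrow(gr1), length(terms) - sum(K["a1", "a2"] > 1))
  expect_true(all(gr1$n_terms == 1))
})
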