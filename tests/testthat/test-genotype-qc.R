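test_that("HWE chi-square test handles perfect equilibrium and extremes", {
  expect_equal(hwe_test(25, 50, 25, method = "chi2"), 1)
  expect_lt(hwe_test(50, 0, 50, method = "chi2"), 1e-4)
  expect_lt(hwe_test(50, 0, 50, method = "exact"), 1e-4)
  expect_equal(hwe_test(100, 0, 0), 1)  # monomorphic convention
  expect_error(hwe_test(0, 0, 0), "total")
  expect_error(hwe_test(-1, 2, 3), ">= 0")
})

test_that("exact HWE p-values equal full enumeration", {
  cases <- list(c(5, 0, 5), c(3, 4, 3), c(10, 2, 1), c(0, 10, 0),
                c(57, 14, 50), c(20, 30, 12))
  for (cs in cases) {
    expect_equal(
      hwe_test(cs[1], cs[2], cs[3], method = "exact"),
      hwe_enum_oracle(cs[1], cs[2], cs[3]),
      tolerance = 1e-10
    )
  }
})

test_that("exact and chi-square tests converge and agree at the QC cut", {
  set.seed(2)
  diff_at <- function(n) {
    mean(replicate(150, {
      cnt <- drop(stats::rmultinom(1, n, c(0.25, 0.5, 0.25)))
      abs(hwe_test(cnt[1], cnt[2], cnt[3], "exact") -
            hwe_test(cnt[1], cnt[2], cnt[3], "chi2"))
    }))
  }
  d600 <- diff_at(600)
  d2400 <- diff_at(2400)
  expect_lt(d2400, d600)        # chi-square approximation improves with n
  expect_lt(d2400, 0.02)
  # both methods make the same keep/remove call at the 1e-4 threshold
  # for clean and strongly violating SNPs
  for (i in 1:50) {
    cnt <- drop(stats::rmultinom(1, 500, c(0.25, 0.5, 0.25)))
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3], "exact") < 1e-4,
                 hwe_test(cnt[1], cnt[2], cnt[3], "chi2") < 1e-4)
  }
  expect_true(hwe_test(170, 160, 170, "exact") < 1e-4)
  expect_true(hwe_test(170, 160, 170, "chi2") < 1e-4)
})

make_qc_fixture <- function() {
  # 40 animals x 10 SNPs: SNPs 1-2 at MAF 0.025 (2/80 alleles), SNP 3 at
  # call rate 0.90, the rest clean at MAF 0.5 in perfect HWE
  n <- 40
  clean <- rep(c(0, 1, 1, 2), n / 4)
  X <- sapply(1:10, function(j) clean)
  X[, 1] <- c(rep(1, 2), rep(0, n - 2))
  X[, 2] <- c(rep(1, 2), rep(0, n - 2))
  X[1:4, 3] <- NA
  rownames(X) <- sprintf("a%02d", 1:n)
  genotypes(X, tibble::tibble(
    snp_id = sprintf("s%02d", 1:10), chrom = "chr1", pos = 1000 * (1:10)
  ))
}

test_that("QC removes exactly the planted low-MAF and low-call-rate SNPs", {
  g <- make_qc_fixture()
  out <- apply_qc(g, qc_thresholds(maf_min = 0.05, snp_call_rate_min = 0.95,
                                   hwe_p_min = 1e-4,
                                   sample_call_rate_min = 0.9))
  rep <- qc_report(out)
  expect_equal(ncol(out$X), 7)
  expect_setequal(rep$removed$maf, c("s01", "s02"))
  expect_equal(rep$removed$snp_call_rate, "s03")
  expect_equal(rep$n_snps_in, rep$n_snps_out +
                 length(unique(unlist(rep$removed[c("snp_call_rate", "maf", "hwe")]))))
})

test_that("all-zero thresholds are the identity filter", {
  g <- make_qc_fixture()
  out <- apply_qc(g, qc_thresholds(hwe_p_min = 0, maf_min = 0,
                                   snp_call_rate_min = 0,
                                   sample_call_rate_min = 0))
  expect_identical(out$X, g$X)
})

test_that("planted HWE violations are caught by the HWE filter alone", {
  set.seed(42)
  n <- 300
  m <- 30
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  bad <- c(4, 17, 25)
  for (j in bad) X[, j] <- 2 * rbinom(n, 1, 0.4)  # selfing-like: no hets
  rownames(X) <- sprintf("a%03d", 1:n)
  g <- genotypes(X, tibble::tibble(
    snp_id = sprintf("s%02d", 1:m), chrom = "chr1", pos = 500 * (1:m)
  ))
  rep <- qc_report(apply_qc(g))
  expect_setequal(rep$removed$hwe, sprintf("s%02d", bad))
  expect_length(rep$removed$maf, 0)
})

test_that("QC is idempotent and MAF is bounded by one half", {
  cfg <- sim_config(n_animals = 120, n_sires = 10, n_snps = 300, n_traits = 1,
                    n_qtl = 0, maf_range = c(0.02, 0.5),
                    geno_missing_rate = 0.03, seed = 13)
  g <- simulate_genotypes(cfg)
  once <- apply_qc(g)
  twice <- apply_qc(once)
  expect_identical(twice$X, once$X)
  expect_equal(qc_report(twice)$n_snps_in, qc_report(twice)$n_snps_out)
  st <- snp_stats(g, hwe_method = "chi2")
  expect_true(all(st$maf <= 0.5))
})

test_that("removing every SNP raises an explicit empty-panel error", {
  g <- make_qc_fixture()
  expect_error(apply_qc(g, qc_thresholds(maf_min = 0.6)), "empty panel")
})
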