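#' Marker and sample quality-control thresholds
#'
#' Defaults follow standard 50k-chip practice: SNPs deviating from
#' Hardy-Weinberg equilibrium at P < 1e-4 are removed, as are SNPs with
#' minor allele frequency below 5% or call rate below 95%, and samples with
#' call rate below 95%.
#'
#' @param hwe_p_min remove SNPs with HWE p-value below this.
#' @param maf_min remove SNPs with minor allele frequency below this.
#' @param snp_call_rate_min remove SNPs with call rate below this.
#' @param sample_call_rate_min remove samples with call rate below this.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-4, maf_min = 0.05,
                          snp_call_rate_min = 0.95,
                          sample_call_rate_min = 0.95) {
  th <- list(
    hwe_p_min = hwe_p_min, maf_min = maf_min,
    snp_call_rate_min = snp_call_rate_min,
    sample_call_rate_min = sample_call_rate_min
  )
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(sprintf("%s must be a single value in [0, 1]", nm))
    }
  }
  structure(th, class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' The exact test sums, over all heterozygote counts compatible with the
#' observed allele counts (same parity), the probabilities of tables no more
#' probable than the observed one. The chi-square variant is the 1-df
#' goodness-of-fit test against expected HWE counts. A monomorphic SNP
#' returns p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @param method `"exact"` (default) or `"chi2"`.
#' @return A single p-value.
#' @export
#' @examples
#' hwe_test(25, 50, 25)           # perfect HWE, p = 1
#' hwe_test(50, 0, 50)            # extreme disequilibrium
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chi2")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) abort("total genotype count must be > 0")
  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  if (n_A == 0 || n_a == 0) return(1)  # monomorphic
  if (method == "chi2") {
    p <- n_A / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
    return(pchisq(stat, df = 1, lower.tail = FALSE))
  }
  # exact: enumerate heterozygote counts with the parity of n_A
  rare <- min(n_A, n_a)
  het_vals <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_Aa = h | n, n_A) up to a shared constant
  logp <- vapply(het_vals, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (max(n_A, n_a) - h) / 2
    h * log(2) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het_vals)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Apply marker and sample quality control
#'
#' Filter order: sample call rate, then SNP call rate, then minor allele
#' frequency, then Hardy-Weinberg equilibrium (statistics for each SNP
#' filter are recomputed on the surviving samples). Every removal is listed
#' with its reason in the attached report.
#'
#' @param geno a [genotypes] object.
#' @param thresholds a [qc_thresholds] object.
#' @param hwe_method HWE test variant, `"exact"` or `"chi2"`.
#' @return The filtered [genotypes] object, with a `qc_report` attached as
#'   attribute `"qc_report"` (also retrievable via [qc_report()]).
#' @export
apply_qc <- function(geno, thresholds = qc_thresholds(),
                     hwe_method = c("exact", "chi2")) {
  hwe_method <- match.arg(hwe_method)
  stopifnot(inherits(geno, "genotypes"))
  th <- thresholds
  X <- geno$X
  n_samples_in <- nrow(X)
  n_snps_in <- ncol(X)

  sample_cr <- rowMeans(!is.na(X))
  drop_samples <- rownames(X)[sample_cr < th$sample_call_rate_min]
  keep_s <- setdiff(rownames(X), drop_samples)
  X2 <- X[keep_s, , drop = FALSE]
  geno2 <- geno
  geno2$X <- X2
  if (!is.null(geno2$sires)) {
    geno2$sires <- geno$sires[match(keep_s, rownames(X))]
  }

  st <- snp_stats(geno2, hwe_method = hwe_method)
  drop_cr <- st$snp_id[st$call_rate < th$snp_call_rate_min]
  st1 <- st[!(st$snp_id %in% drop_cr), ]
  drop_maf <- st1$snp_id[st1$maf < th$maf_min]
  st2 <- st1[!(st1$snp_id %in% drop_maf), ]
  drop_hwe <- st2$snp_id[st2$hwe_p < th$hwe_p_min]

  drop_snps <- c(drop_cr, drop_maf, drop_hwe)
  keep <- setdiff(geno2$map$snp_id, drop_snps)
  if (length(keep) == 0) abort("QC removed every SNP: empty panel")

  j <- match(keep, geno2$map$snp_id)
  out <- geno2
  out$X <- geno2$X[, j, drop = FALSE]
  out$map <- geno2$map[j, ]

  report <- structure(
    list(
      n_snps_in = n_snps_in, n_snps_out = length(keep),
      n_samples_in = n_samples_in, n_samples_out = nrow(out$X),
      removed = list(
        sample_call_rate = drop_samples,
        snp_call_rate = drop_cr,
        maf = drop_maf,
        hwe = drop_hwe
      ),
      snp_stats = st,
      thresholds = th
    ),
    class = "qc_report"
  )
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report from a filtered genotype set
#' @param geno output of [apply_qc()].
#' @return The `qc_report` object.
#' @export
qc_report <- function(geno) attr(geno, "qc_report")

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> samples %d -> %d; SNPs %d -> %d\n",
    x$n_samples_in, x$n_samples_out, x$n_snps_in, x$n_snps_out
  ))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed by %-17s %d\n", paste0(nm, ":"), length(x$removed[[nm]])))
  }
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  bind_rows(imap(
    x$removed,
    function(ids, f) tibble(filter = f, id = as.character(ids))
  ))
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble(
    n_snps_in = x$n_snps_in, n_snps_out = x$n_snps_out,
    n_samples_in = x$n_samples_in, n_samples_out = x$n_samples_out
  )
}
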