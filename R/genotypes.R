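#' Genotype container
#'
#' A light wrapper around an animals-by-SNPs additive genotype matrix
#' (`0/1/2`, `NA` for missing) and its marker map. All downstream stages
#' (QC, GRM, association scans) consume this object.
#'
#' @param X numeric matrix, animals in rows, SNPs in columns, entries in
#'   `{0, 1, 2, NA}`; row names are animal ids, column names SNP ids.
#' @param map data frame with columns `snp_id`, `chrom`, `pos` (base pairs,
#'   1-based) in the column order of `X`.
#' @param sires optional character vector of sire ids, one per animal.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(X, map, sires = NULL) {
  stopifnot(is.matrix(X), nrow(map) == ncol(X))
  map <- as_tibble(map)
  if (!all(c("snp_id", "chrom", "pos") %in% names(map))) {
    abort("map must have columns snp_id, chrom, pos")
  }
  bad <- X[!is.na(X) & !(X %in% 0:2)]
  if (length(bad) > 0) abort("genotype codes must be 0, 1, 2 or NA")
  colnames(X) <- map$snp_id
  if (is.null(rownames(X))) rownames(X) <- sprintf("animal_%04d", seq_len(nrow(X)))
  structure(
    list(X = X, map = map, sires = sires),
    class = "genotypes"
  )
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf(
    "<genotypes> %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
    nrow(x$X), ncol(x$X), length(unique(x$map$chrom)),
    100 * mean(is.na(x$X))
  ))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$X)

n_animals <- function(g) nrow(g$X)
n_snps <- function(g) ncol(g$X)

#' Per-SNP summary statistics
#'
#' Minor allele frequency, call rate and Hardy-Weinberg p-value per SNP,
#' computed on non-missing calls only.
#'
#' @param geno a [genotypes] object.
#' @param hwe_method `"exact"` or `"chi2"`, passed to [hwe_test()].
#' @return A tibble with one row per SNP: `snp_id`, `maf`, `call_rate`, `hwe_p`.
#' @export
snp_stats <- function(geno, hwe_method = c("exact", "chi2")) {
  hwe_method <- match.arg(hwe_method)
  X <- geno$X
  n_obs <- colSums(!is.na(X))
  p <- colSums(X, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  maf <- pmin(p, 1 - p)
  n_aa <- colSums(X == 0, na.rm = TRUE)
  n_ab <- colSums(X == 1, na.rm = TRUE)
  n_bb <- colSums(X == 2, na.rm = TRUE)
  hwe_p <- vapply(
    seq_len(ncol(X)),
    function(j) hwe_test(n_aa[j], n_ab[j], n_bb[j], method = hwe_method),
    numeric(1)
  )
  tibble(
    snp_id = geno$map$snp_id,
    maf = unname(maf),
    call_rate = unname(n_obs / nrow(X)),
    hwe_p = hwe_p
  )
}

#' Mean-impute missing genotypes
#'
#' Replaces missing calls by the per-SNP mean of observed calls (twice the
#' allele frequency). Used ahead of GRM construction and association scans;
#' never applied during QC.
#'
#' @param geno a [genotypes] object.
#' @return A numeric matrix with no missing values.
#' @export
impute_genotypes <- function(geno) {
  X <- geno$X
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}
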