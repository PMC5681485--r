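#' Genomic relationship matrix (VanRaden method 1)
#'
#' K = Z Z' / (2 * sum p (1 - p)), where Z is the genotype matrix centred by
#' twice the observed allele frequency of each SNP and p the observed
#' frequencies. Missing genotypes are mean-imputed per SNP before centring;
#' monomorphic SNPs contribute nothing and are counted.
#'
#' @param geno a [genotypes] object (or a plain 0/1/2 matrix).
#' @param method currently `"vanraden1"` only.
#' @return A `grm` object: list with `K` (n x n symmetric matrix),
#'   `ids`, `n_snps_used`, `method`.
#' @export
compute_grm <- function(geno, method = "vanraden1") {
  method <- match.arg(method, "vanraden1")
  X <- if (inherits(geno, "genotypes")) impute_genotypes(geno) else as.matrix(geno)
  if (nrow(X) < 2) abort("GRM needs at least 2 samples")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("all SNPs are monomorphic; GRM undefined")
  Xp <- X[, poly, drop = FALSE]
  pp <- p[poly]
  Z <- sweep(Xp, 2, 2 * pp)
  denom <- 2 * sum(pp * (1 - pp))
  K <- tcrossprod(Z) / denom
  K <- (K + t(K)) / 2
  structure(
    list(
      K = K, ids = rownames(X),
      n_snps_used = sum(poly), n_snps_skipped = sum(!poly),
      method = method
    ),
    class = "grm"
  )
}

#' Stabilize a GRM to positive semi-definiteness
#'
#' Adds `epsilon` to the diagonal only when the smallest eigenvalue is
#' negative; otherwise the input is returned unchanged. The adjustment is
#' recorded in the returned object.
#'
#' @param grm a `grm` object.
#' @param epsilon diagonal ridge to add when needed (default 1e-6).
#' @return The (possibly adjusted) `grm`, with `stabilized` and
#'   `epsilon_added` fields set.
#' @export
stabilize <- function(grm, epsilon = 1e-6) {
  stopifnot(inherits(grm, "grm"))
  ev_min <- min(eigen(grm$K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0) {
    grm$K <- grm$K + diag(epsilon - ev_min, nrow(grm$K))
    grm$stabilized <- TRUE
    grm$epsilon_added <- epsilon - ev_min
  } else {
    grm$stabilized <- FALSE
    grm$epsilon_added <- 0
  }
  grm
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf(
    "<grm> %d samples, %s, %d SNPs used (%d monomorphic skipped); mean diag %.3f\n",
    nrow(x$K), x$method, x$n_snps_used, x$n_snps_skipped %||% 0,
    mean(diag(x$K))
  ))
  invisible(x)
}

#' @export
tidy.grm <- function(x, ...) {
  ut <- which(upper.tri(x$K, diag = TRUE), arr.ind = TRUE)
  tibble(
    id1 = x$ids[ut[, 1]], id2 = x$ids[ut[, 2]],
    relationship = x$K[ut]
  )
}

#' @export
glance.grm <- function(x, ...) {
  ev <- eigen(x$K, symmetric = TRUE, only.values = TRUE)$values
  tibble(
    n_samples = nrow(x$K), n_snps_used = x$n_snps_used,
    mean_diag = mean(diag(x$K)), min_eigenvalue = min(ev)
  )
}
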