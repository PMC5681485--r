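#' Null-model variance components for the mixed model Y = Xb + g + e
#'
#' Fits g ~ N(0, sigma_a2 * K), e ~ N(0, sigma_e2 * I) by restricted (or
#' full) maximum likelihood, profiling the likelihood in the single variance
#' ratio delta = sigma_e2 / sigma_a2. The spectral decomposition K = U D U'
#' is computed once; the profile criterion is maximised by a coarse grid over
#' log(delta) in [-10, 10] followed by a bounded 1-D search in the bracketing
#' interval, so local optima on the profile are not missed.
#'
#' @param y numeric phenotype vector (no missing values; subset beforehand).
#' @param X fixed-effect design matrix (full column rank enforced by QR
#'   column dropping; pass an intercept-only matrix if no covariates).
#' @param K genomic relationship matrix (a `grm` object or plain symmetric
#'   matrix) conformable with `y`.
#' @param criterion `"REML"` (default) or `"ML"`.
#' @return An `emmax_vc` object with fields `sigma_a2`, `sigma_e2`, `delta`,
#'   `pseudo_h2`, `loglik`, `criterion`, `identifiable`, plus the cached
#'   rotation (`U`, `lambda`) reused by [emmax_scan()].
#' @export
estimate_variance_components <- function(y, X, K, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  if (inherits(K, "grm")) K <- K$K
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (anyNA(y)) abort("y contains missing values; subset animals first")
  if (sd(y) == 0) abort("phenotype is constant; variance components undefined")

  # drop rank-deficient columns once, before rotation
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  p <- ncol(X)

  eg <- eigen(K, symmetric = TRUE)
  lambda <- eg$values
  if (min(lambda) < -1e-6 * max(abs(lambda))) {
    abort("K is not positive semi-definite; run stabilize() on the GRM first")
  }
  lambda <- pmax(lambda, 0)
  U <- eg$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  ldXtX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  profile <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (lambda + delta)
    sw <- sqrt(w)
    Xw <- Xs * sw
    yw <- ys * sw
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    if (criterion == "REML") {
      s2 <- rss / (n - p)
      ldXWX <- determinant(crossprod(Xw), logarithm = TRUE)$modulus
      -0.5 * ((n - p) * (log(2 * pi * s2) + 1) - sum(log(w)) + ldXWX - ldXtX)
    } else {
      s2 <- rss / n
      -0.5 * (n * (log(2 * pi * s2) + 1) - sum(log(w)))
    }
  }

  grid <- seq(-10, 10, length.out = 64)
  ll_grid <- vapply(grid, profile, numeric(1))
  identifiable <- diff(range(ll_grid)) > 1e-6
  i <- which.max(ll_grid)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(profile, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  ld_hat <- if (opt$objective >= ll_grid[i]) opt$maximum else grid[i]
  ll_hat <- max(opt$objective, ll_grid[i])

  delta <- exp(ld_hat)
  w <- 1 / (lambda + delta)
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xs * sw, ys * sw)
  rss <- sum(fit$residuals^2)
  sigma_a2 <- rss / (if (criterion == "REML") n - p else n)
  sigma_e2 <- sigma_a2 * delta

  if (!identifiable) {
    warn("profile likelihood is flat in delta (is K proportional to the identity?); variance split is unidentifiable")
  }

  structure(
    list(
      sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, delta = delta,
      pseudo_h2 = 1 / (1 + delta), loglik = ll_hat, criterion = criterion,
      identifiable = identifiable, n = n, p = p,
      U = U, lambda = lambda, X = X
    ),
    class = "emmax_vc"
  )
}

#' Pseudo-heritability from fitted variance components
#'
#' The proportion of phenotypic variance captured by the GRM random effect,
#' sigma_a2 / (sigma_a2 + sigma_e2).
#'
#' @param vc an `emmax_vc` object (or a list with `sigma_a2`, `sigma_e2`).
#' @return A value in \[0, 1\].
#' @export
#' @examples
#' pseudo_heritability(list(sigma_a2 = 2, sigma_e2 = 2))  # 0.5
pseudo_heritability <- function(vc) {
  s <- vc$sigma_a2 + vc$sigma_e2
  if (s <= 0) abort("both variance components are zero; heritability undefined")
  vc$sigma_a2 / s
}

#' @export
print.emmax_vc <- function(x, ...) {
  cat(sprintf(
    "<emmax_vc> %s: sigma_a2 = %.4g, sigma_e2 = %.4g, pseudo-h2 = %.3f (n = %d)%s\n",
    x$criterion, x$sigma_a2, x$sigma_e2, pseudo_heritability(x), x$n,
    if (!x$identifiable) " [flat profile: unidentifiable]" else ""
  ))
  invisible(x)
}

#' @export
tidy.emmax_vc <- function(x, ...) {
  tibble(
    term = c("sigma_a2", "sigma_e2", "delta", "pseudo_h2"),
    estimate = c(x$sigma_a2, x$sigma_e2, x$delta, pseudo_heritability(x))
  )
}

#' @export
glance.emmax_vc <- function(x, ...) {
  tibble(
    sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2,
    pseudo_h2 = pseudo_heritability(x), logLik = x$loglik,
    criterion = x$criterion, n = x$n, identifiable = x$identifiable
  )
}

#' EMMAX association scan for one trait
#'
#' Generalized least squares of y on \[X | g\] for every SNP g, with the
#' phenotypic covariance sigma_a2 * K + sigma_e2 * I held fixed at the null
#' estimates (the EMMAX approximation). The SNP effect is the allele
#' substitution coefficient; its Wald statistic is referred to a t
#' distribution on n - rank(\[X|g\]) degrees of freedom. SNPs collinear with
#' the fixed effects (e.g. monomorphic in the analysed animals) get
#' effect 0, p = 1 and a `degenerate` flag.
#'
#' @param y,X phenotype and design used for `vc` (same animals, same order).
#' @param vc an `emmax_vc` from [estimate_variance_components()].
#' @param G numeric genotype matrix (animals x SNPs, no missing values;
#'   see [impute_genotypes()]), rows aligned with `y`.
#' @return A tibble: `snp_id`, `effect`, `se`, `p_value`, `n_used`,
#'   `degenerate`.
#' @export
emmax_scan <- function(y, X, vc, G) {
  stopifnot(inherits(vc, "emmax_vc"))
  n <- vc$n
  G <- as.matrix(G)
  stopifnot(length(y) == n, nrow(G) == n)
  sw <- sqrt(1 / (vc$lambda + vc$delta))
  yw <- drop(crossprod(vc$U, y)) * sw
  Xw <- crossprod(vc$U, vc$X) * sw
  Gw <- crossprod(vc$U, G) * sw
  qx <- qr(Xw)
  yt <- qr.resid(qx, yw)
  Gt <- qr.resid(qx, Gw)
  Sgg <- colSums(Gt^2)
  Sgy <- drop(crossprod(Gt, yt))
  degenerate <- Sgg < 1e-10 * n
  beta <- ifelse(degenerate, 0, Sgy / Sgg)
  se <- ifelse(degenerate, NA_real_, sqrt(vc$sigma_a2 / Sgg))
  df <- n - vc$p - 1
  pval <- ifelse(degenerate, 1, 2 * pt(abs(beta / se), df = df, lower.tail = FALSE))
  tibble(
    snp_id = colnames(G) %||% sprintf("snp_%05d", seq_len(ncol(G))),
    effect = unname(beta), se = unname(se),
    p_value = pmin(unname(pval), 1), n_used = n,
    degenerate = unname(degenerate)
  )
}

#' Naive ordinary least squares scan (no relatedness correction)
#'
#' Per-SNP linear regression of y on \[X | g\] with the residual variance
#' re-estimated per SNP. Provided as the uncorrected baseline against which
#' the mixed model's control of family structure is judged (genomic-control
#' lambda).
#'
#' @inheritParams emmax_scan
#' @param X fixed-effect design matrix.
#' @return A tibble like [emmax_scan()]'s.
#' @export
ols_scan <- function(y, X, G) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  G <- as.matrix(G)
  n <- length(y)
  qx <- qr(X)
  p <- qx$rank
  yt <- qr.resid(qx, y)
  Gt <- qr.resid(qx, G)
  Sgg <- colSums(Gt^2)
  Sgy <- drop(crossprod(Gt, yt))
  Syy <- sum(yt^2)
  degenerate <- Sgg < 1e-10 * n
  beta <- ifelse(degenerate, 0, Sgy / Sgg)
  df <- n - p - 1
  rss <- pmax(Syy - beta^2 * Sgg, 0)
  se <- ifelse(degenerate, NA_real_, sqrt(rss / df / Sgg))
  pval <- ifelse(degenerate, 1, 2 * pt(abs(beta / se), df = df, lower.tail = FALSE))
  tibble(
    snp_id = colnames(G) %||% sprintf("snp_%05d", seq_len(ncol(G))),
    effect = unname(beta), se = unname(se),
    p_value = pmin(unname(pval), 1), n_used = n,
    degenerate = unname(degenerate)
  )
}

#' Genomic-control inflation factor
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the median of the chi-square(1) distribution. Values near 1
#' indicate well-calibrated tests; values well above 1 indicate confounding
#' (e.g. uncorrected family structure).
#'
#' @param p vector of two-sided p-values.
#' @return The inflation factor lambda.
#' @export
gc_lambda <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Contemporary-group design matrix
#'
#' Intercept plus treatment-coded contemporary-group dummies (one level
#' dropped); full column rank after dropping unused levels.
#'
#' @param cg vector of contemporary-group labels.
#' @return A numeric design matrix.
#' @export
cg_design <- function(cg) {
  cg <- droplevels(factor(cg))
  if (nlevels(cg) <= 1) {
    matrix(1, length(cg), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~cg)
  }
}

#' Mixed-model association scans for every trait
#'
#' For each trait column: animals with a missing value for that trait are
#' excluded, contemporary groups are fit as fixed class effects, variance
#' components are re-estimated on that trait's animals under the null, and
#' every SNP is scored by [emmax_scan()]. Per-trait significant-SNP counts
#' at p < 0.05 / 0.01 / 0.001 are tabulated.
#'
#' @param phenotypes data frame with columns `animal_id`, `cg`, and one
#'   column per trait (missing values allowed).
#' @param geno a [genotypes] object.
#' @param K optional precomputed [compute_grm()] result; computed from
#'   `geno` when `NULL`.
#' @param traits trait column names to analyse (default: all columns other
#'   than `animal_id` and `cg`).
#' @param min_n traits with fewer non-missing animals are skipped with a
#'   warning (default 30).
#' @param criterion passed to [estimate_variance_components()].
#' @return A `gwas_result`: list with `gwas` (tibble keyed by snp/trait),
#'   `vc` (per-trait `emmax_vc`), and `trait_summary` (per-trait n,
#'   pseudo-h2 and significance counts).
#' @export
run_multitrait_gwas <- function(phenotypes, geno, K = NULL, traits = NULL,
                                min_n = 30, criterion = "REML") {
  stopifnot(inherits(geno, "genotypes"))
  phenotypes <- as_tibble(phenotypes)
  if (!all(c("animal_id", "cg") %in% names(phenotypes))) {
    abort("phenotypes must have columns animal_id and cg")
  }
  traits <- traits %||% setdiff(names(phenotypes), c("animal_id", "cg"))
  if (length(traits) == 0) abort("no trait columns to analyse")
  G <- impute_genotypes(geno)
  idx <- match(phenotypes$animal_id, rownames(G))
  if (anyNA(idx)) abort("phenotype animal_id values missing from genotypes")
  if (is.null(K)) K <- compute_grm(geno)
  Km <- if (inherits(K, "grm")) K$K else K

  vc_list <- list()
  rows <- list()
  summ <- list()
  for (tr in traits) {
    y_all <- phenotypes[[tr]]
    use <- which(!is.na(y_all))
    if (length(use) < min_n) {
      warn(sprintf("trait %s skipped: only %d non-missing animals", tr, length(use)))
      next
    }
    ai <- idx[use]
    y <- y_all[use]
    X <- cg_design(phenotypes$cg[use])
    vc <- estimate_variance_components(y, X, Km[ai, ai], criterion = criterion)
    sc <- emmax_scan(y, vc$X, vc, G[ai, , drop = FALSE])
    vc_list[[tr]] <- vc
    rows[[tr]] <- mutate(sc, trait = tr)
    summ[[tr]] <- tibble(
      trait = tr, n = length(use), pseudo_h2 = pseudo_heritability(vc),
      n_p05 = sum(sc$p_value < 0.05), n_p01 = sum(sc$p_value < 0.01),
      n_p001 = sum(sc$p_value < 0.001)
    )
  }
  if (length(rows) == 0) abort("no trait had enough non-missing animals")
  gwas <- bind_rows(rows) |>
    left_join(geno$map, by = "snp_id") |>
    select("snp_id", "chrom", "pos", "trait", "effect", "se",
           "p_value", "n_used", "degenerate")
  structure(
    list(gwas = gwas, vc = vc_list, trait_summary = bind_rows(summ)),
    class = "gwas_result"
  )
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf(
    "<gwas_result> %d SNPs x %d traits (%d tests)\n",
    length(unique(x$gwas$snp_id)), nrow(x$trait_summary), nrow(x$gwas)
  ))
  print(x$trait_summary)
  invisible(x)
}

#' @export
tidy.gwas_result <- function(x, ...) x$gwas

#' @export
glance.gwas_result <- function(x, ...) x$trait_summary
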