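#' Simulate multi-trait phenotypes with planted pleiotropic QTL
#'
#' For each trait t:
#' y_t = CG effect + sum_q beta_qt * g_q + polygenic_t + residual,
#' on the phenotypic-SD scale (genetic + residual variance = 1; contemporary
#' -group effects sit on top as fixed effects). Each planted QTL affects the
#' key trait (trait 1) plus one contiguous block of
#' `pleiotropy_block_size - 1` other traits, with effect sizes scaled so
#' every QTL contributes exactly `qtl_effect_sd^2` of variance per affected
#' trait; signs are coherent within a block (a per-block direction pattern
#' times a per-QTL sign), which is the correlated-effect structure the
#' AWM/PCIT stages are designed to detect. The polygenic term is genomic
#' (a genome-wide random-effect vector through the observed genotypes), with
#' one latent factor shared by the traits of a block (correlation ~0.4) so
#' trait correlations arise only through shared QTL and shared polygenic
#' factors. Its variance is scaled so total genetic variance equals the
#' requested heritability. Missing phenotypes are MCAR per trait.
#'
#' @param geno output of [simulate_genotypes()].
#' @param config the same [sim_config].
#' @return A list: `phenotypes` (tibble: `animal_id`, `cg`, `trait_*`) and
#'   `truth` (a `ground_truth` list: `qtl_ids`, `qtl_trait_map`,
#'   `qtl_effects`, `true_h2`, `cg_effects`, `blocks`).
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(geno, "genotypes"), inherits(config, "sim_config"))
  cfg <- config
  set.seed(stage_seed(cfg$seed, 2L))
  X <- impute_genotypes(geno)
  n <- nrow(X)
  T <- cfg$n_traits
  h2 <- rep_len(cfg$heritabilities, T)
  trait_names <- paste0("trait_", seq_len(T))

  # trait blocks: non-key traits in contiguous blocks; every QTL hits the
  # key trait plus its block
  tpb <- max(cfg$pleiotropy_block_size - 1L, 0L)
  if (T > 1 && tpb > 0) {
    nb <- ceiling((T - 1) / tpb)
    blocks <- split(2:T, rep(seq_len(nb), each = tpb, length.out = T - 1))
  } else {
    nb <- 0L
    blocks <- list()
  }

  # QTL: common-enough SNPs so planted signals are detectable
  beta <- matrix(0, cfg$n_qtl, T, dimnames = list(NULL, trait_names))
  qtl_ids <- character(0)
  qtl_block <- integer(0)
  if (cfg$n_qtl > 0) {
    sds <- apply(X, 2, sd)
    freq <- colMeans(X) / 2
    eligible <- which(pmin(freq, 1 - freq) >= 0.1 & sds > 0)
    if (length(eligible) < cfg$n_qtl) eligible <- which(sds > 0)
    if (length(eligible) < cfg$n_qtl) {
      abort("not enough polymorphic SNPs to place the requested QTL")
    }
    qtl_idx <- sort(sample(eligible, cfg$n_qtl))
    qtl_ids <- geno$map$snp_id[qtl_idx]
    qtl_block <- if (nb > 0) rep_len(seq_len(nb), cfg$n_qtl) else rep(0L, cfg$n_qtl)
    dir_block <- matrix(sample(c(-1, 1), max(nb, 1) * T, replace = TRUE), ncol = T)
    sgn_qtl <- sample(c(-1, 1), cfg$n_qtl, replace = TRUE)
    for (q in seq_len(cfg$n_qtl)) {
      affected <- c(1L, if (qtl_block[q] > 0) blocks[[qtl_block[q]]])
      b <- max(qtl_block[q], 1L)
      beta[q, affected] <- sgn_qtl[q] * dir_block[b, affected] *
        cfg$qtl_effect_sd / sds[qtl_idx[q]]
    }
  }

  v_qtl <- if (cfg$n_qtl > 0) {
    colSums(matrix(beta != 0, cfg$n_qtl, T)) * cfg$qtl_effect_sd^2
  } else {
    rep(0, T)
  }
  v_poly <- h2 - v_qtl
  if (any(v_poly < -1e-12)) {
    abort(sprintf(
      "planted QTL variance exceeds heritability for trait(s): %s",
      paste(trait_names[v_poly < -1e-12], collapse = ", ")
    ))
  }
  v_poly <- pmax(v_poly, 0)
  if (any(v_poly > 0) || any(v_qtl > 0)) {
    if (all(apply(X, 2, sd) == 0)) {
      abort("no polymorphic SNPs: requested genetic variance is unattainable")
    }
  }

  # genomic polygenic factors, standardized to unit sample variance
  rho_shared <- 0.4
  genomic_factor <- function() {
    u <- drop(X %*% rnorm(ncol(X)))
    if (sd(u) == 0) abort("degenerate genotypes: polygenic factor undefined")
    (u - mean(u)) / sd(u)
  }
  f_block <- lapply(seq_len(max(nb, 1)), function(b) genomic_factor())
  f_key <- genomic_factor()
  poly <- matrix(0, n, T)
  block_of_trait <- integer(T)
  if (nb > 0) for (b in seq_len(nb)) block_of_trait[blocks[[b]]] <- b
  for (t in seq_len(T)) {
    shared <- if (t == 1L || block_of_trait[t] == 0) f_key else f_block[[block_of_trait[t]]]
    u <- sqrt(rho_shared) * shared + sqrt(1 - rho_shared) * genomic_factor()
    poly[, t] <- u / sd(u)
  }

  cg <- factor(sample(rep_len(seq_len(cfg$n_contemporary_groups), n)),
               labels = sprintf("cg_%02d", seq_len(cfg$n_contemporary_groups)))
  cg_eff <- matrix(
    rnorm(cfg$n_contemporary_groups * T, 0, cfg$cg_effect_sd),
    nrow = cfg$n_contemporary_groups, dimnames = list(levels(cg), trait_names)
  )

  qtl_part <- if (cfg$n_qtl > 0) {
    X[, match(qtl_ids, geno$map$snp_id), drop = FALSE] %*% beta
  } else {
    matrix(0, n, T)
  }
  Y <- cg_eff[as.integer(cg), , drop = FALSE] + qtl_part +
    sweep(poly, 2, sqrt(v_poly), `*`) +
    matrix(rnorm(n * T), n, T) %*% diag(sqrt(1 - h2), T)
  colnames(Y) <- trait_names

  if (cfg$missing_pheno_rate > 0) {
    Y[matrix(runif(n * T) < cfg$missing_pheno_rate, n, T)] <- NA_real_
  }

  qtl_trait_map <- if (cfg$n_qtl > 0) {
    setNames(
      lapply(seq_len(cfg$n_qtl), function(q) trait_names[beta[q, ] != 0]),
      qtl_ids
    )
  } else {
    list()
  }
  rownames(beta) <- qtl_ids

  truth <- structure(
    list(
      qtl_ids = qtl_ids, qtl_trait_map = qtl_trait_map,
      qtl_effects = beta, true_h2 = setNames(h2, trait_names),
      cg_effects = cg_eff,
      blocks = blocks, qtl_block = setNames(qtl_block, qtl_ids)
    ),
    class = "ground_truth"
  )
  list(
    phenotypes = dplyr::bind_cols(
      tibble(animal_id = rownames(X), cg = as.character(cg)),
      as_tibble(as.data.frame(Y))
    ),
    truth = truth
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d QTL over %d traits; h2 in [%.2f, %.2f]\n",
    length(x$qtl_ids), length(x$true_h2), min(x$true_h2), max(x$true_h2)
  ))
  invisible(x)
}
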