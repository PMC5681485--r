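#' Configuration for the synthetic half-sib study generator
#'
#' The defaults emulate, at one quarter scale, the design of a multi-trait
#' beef-cattle meat-quality study: a paternal half-sib population (the full
#' design had 155 sires for 2,110 animals, i.e. ~14 offspring per sire, kept
#' here as 37 sires for 500 animals), contemporary groups fit as fixed class
#' effects, a 50k-style SNP panel scaled to 5,000 markers, and a panel of
#' correlated traits with heritabilities spanning 0.17-0.67. Trait 1 plays
#' the role of the key phenotype (Warner-Bratzler shear force in the
#' original design, h2 = 0.38); pleiotropic QTL each affect the key trait
#' plus a block of other traits, which is exactly the signal the
#' AWM/PCIT machinery is designed to recover.
#'
#' Each QTL contributes `qtl_effect_sd^2` of phenotypic variance to every
#' trait it affects (effects are scaled by 1/sd(genotype), with random
#' sign shared within a trait block), so power is controlled directly.
#' The defaults place 15 QTL in three blocks of five; each QTL explains
#' ~2.4% of variance per affected trait, giving ~0.9 power at nominal
#' p < 0.05 with n = 500, so each block keeps enough members through the
#' AWM funnel (expected >= 4 of 5) to form a detectable co-association
#' cluster while the key trait's summed QTL variance (15 x 2.4% = 36%)
#' stays within its heritability.
#'
#' @param n_animals number of phenotyped, genotyped offspring.
#' @param n_sires number of sires (offspring are assigned round-robin).
#' @param n_snps,n_chromosomes marker panel size and layout.
#' @param maf_range range of simulated minor allele frequencies, in (0, 0.5].
#' @param n_traits number of trait columns.
#' @param heritabilities per-trait narrow-sense heritability in \[0, 1\];
#'   recycled/validated against `n_traits`.
#' @param n_qtl number of planted QTL.
#' @param pleiotropy_block_size traits affected per QTL (the key trait plus
#'   `pleiotropy_block_size - 1` block members).
#' @param qtl_effect_sd per-QTL, per-trait effect size on the phenotypic-SD
#'   scale (each QTL explains `qtl_effect_sd^2` of variance per trait).
#' @param n_contemporary_groups,cg_effect_sd fixed-effect structure.
#' @param missing_pheno_rate per-trait probability a phenotype is missing
#'   (missing completely at random), in \[0, 1).
#' @param geno_missing_rate probability a genotype call is missing.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_animals = 500,
                       n_sires = 37,
                       n_snps = 5000,
                       n_chromosomes = 5,
                       maf_range = c(0.05, 0.5),
                       n_traits = 10,
                       heritabilities = NULL,
                       n_qtl = 15,
                       pleiotropy_block_size = 4,
                       qtl_effect_sd = 0.155,
                       n_contemporary_groups = 8,
                       cg_effect_sd = 0.5,
                       missing_pheno_rate = 0.1,
                       geno_missing_rate = 0,
                       seed = 1) {
  if (is.null(heritabilities)) {
    heritabilities <- default_h2(n_traits)
  }
  cfg <- list(
    n_animals = n_animals, n_sires = n_sires, n_snps = n_snps,
    n_chromosomes = n_chromosomes, maf_range = maf_range,
    n_traits = n_traits, heritabilities = heritabilities,
    n_qtl = n_qtl, pleiotropy_block_size = pleiotropy_block_size,
    qtl_effect_sd = qtl_effect_sd,
    n_contemporary_groups = n_contemporary_groups,
    cg_effect_sd = cg_effect_sd,
    missing_pheno_rate = missing_pheno_rate,
    geno_missing_rate = geno_missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

# trait 1 is the key phenotype at the study's key-trait h2; the rest span
# the low-to-high range of the trait panel
default_h2 <- function(n_traits) {
  if (n_traits == 1) return(0.38)
  round(c(0.38, seq(0.17, 0.67, length.out = n_traits - 1)), 3)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_sires > n_animals) abort("n_sires must be <= n_animals")
    if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
        maf_range[1] <= 0 || maf_range[2] > 0.5) {
      abort("maf_range must be within (0, 0.5] with min <= max")
    }
    if (length(heritabilities) == 1) {
      cfg$heritabilities <- rep(heritabilities, n_traits)
    }
    if (length(cfg$heritabilities) != n_traits) {
      abort("heritabilities must have length n_traits (or 1)")
    }
    if (any(cfg$heritabilities < 0 | cfg$heritabilities > 1)) {
      abort("heritabilities must lie in [0, 1]")
    }
    if (n_qtl > n_snps) abort("n_qtl must be <= n_snps")
    if (pleiotropy_block_size < 1 ||
        (n_qtl > 0 && pleiotropy_block_size > n_traits)) {
      abort("pleiotropy_block_size must be in [1, n_traits]")
    }
    if (missing_pheno_rate < 0 || missing_pheno_rate >= 1) {
      abort("missing_pheno_rate must be in [0, 1)")
    }
    if (geno_missing_rate < 0 || geno_missing_rate >= 1) {
      abort("geno_missing_rate must be in [0, 1)")
    }
    structure(cfg, class = "sim_config")
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d animals (%d sires), %d SNPs on %d chromosomes, %d traits, %d QTL (block size %d), seed %d\n",
    x$n_animals, x$n_sires, x$n_snps, x$n_chromosomes, x$n_traits,
    x$n_qtl, x$pleiotropy_block_size, x$seed
  ))
  invisible(x)
}

# deterministic per-stage seed expansion from the single config seed:
# stage k uses seed * 31 + k (kept within 32-bit integer range)
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 31 + k) %% .Machine$integer.max)
}
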