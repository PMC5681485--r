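#' Simulate half-sib genotypes
#'
#' Sire genotypes are drawn per SNP from Binomial(2, MAF); each offspring
#' receives one allele sampled from its sire (transmitted with probability
#' sire_genotype / 2) and one allele drawn from the population frequency.
#' This reproduces paternal half-sib relatedness (sire-offspring 0.5,
#' half-sib 0.25 expected relationship) without linkage disequilibrium
#' beyond family structure. Marker positions are laid out along
#' `n_chromosomes` chromosomes with exponentially distributed gaps
#' (mean 30 kb, 50k-chip-like spacing).
#'
#' @param config a [sim_config].
#' @return A [genotypes] object for the offspring, with extra fields
#'   `sires` (sire id per offspring), `sire_X` (sire genotype matrix) and
#'   `maf` (simulated population frequencies) for validation.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(stage_seed(cfg$seed, 1L))
  m <- cfg$n_snps
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])

  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i) {
    cumsum(1 + stats::rexp(length(i), rate = 1 / 30000))
  }), use.names = FALSE)
  pos <- as.integer(round(pos))
  map <- tibble(
    snp_id = sprintf("snp_%05d", seq_len(m)),
    chrom = paste0("chr", chrom), pos = pos
  )

  sire_X <- matrix(
    rbinom(cfg$n_sires * m, 2, rep(maf, each = cfg$n_sires)),
    nrow = cfg$n_sires
  )
  rownames(sire_X) <- sprintf("sire_%03d", seq_len(cfg$n_sires))

  sire_of <- rep_len(seq_len(cfg$n_sires), cfg$n_animals)
  # paternal allele: Bernoulli(sire genotype / 2); maternal: Bernoulli(maf)
  pat_p <- sire_X[sire_of, , drop = FALSE] / 2
  pat <- matrix(rbinom(length(pat_p), 1, pat_p), nrow = cfg$n_animals)
  mat <- matrix(
    rbinom(cfg$n_animals * m, 1, rep(maf, each = cfg$n_animals)),
    nrow = cfg$n_animals
  )
  X <- pat + mat
  rownames(X) <- sprintf("animal_%04d", seq_len(cfg$n_animals))

  if (cfg$geno_missing_rate > 0) {
    miss <- matrix(
      runif(length(X)) < cfg$geno_missing_rate, nrow = nrow(X)
    )
    X[miss] <- NA_integer_
  }

  g <- genotypes(X, map, sires = rownames(sire_X)[sire_of])
  g$sire_X <- sire_X
  g$maf <- maf
  g
}
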