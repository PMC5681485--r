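# Hand-built GWAS fixture: 10 SNPs x 4 traits (key = wbsf) with printed
# p-values, plus a tiny gene map exercising the 2,500 bp boundary.
awm_fixture <- function() {
  snps <- sprintf("s%02d", 1:10)
  map <- tibble::tibble(
    snp_id = snps, chrom = "chr1",
    pos = c(500, 1500, 4000, 9501, 12500, 20000, 26000, 30000, 41000, 55000)
  )
  key_p <- c(0.01, 0.20, 0.02, 0.04, 0.30, 0.001, 0.04, 0.90, 0.03, 0.049)
  other_p <- rbind(
    c(0.01, 0.02, 0.90),  # s01: 2 other hits
    c(0.50, 0.60, 0.70),  # s02
    c(0.90, 0.90, 0.90),  # s03: 0 other hits
    c(0.04, 0.90, 0.90),  # s04: 1 other hit
    c(0.01, 0.01, 0.01),  # s05
    c(0.02, 0.03, 0.04),  # s06: 3 other hits
    c(0.01, 0.90, 0.04),  # s07: 2 other hits
    c(0.01, 0.01, 0.90),  # s08
    c(0.03, 0.02, 0.01),  # s09: 3 other hits
    c(0.90, 0.01, 0.02)   # s10: 2 other hits
  )
  gwas <- dplyr::bind_rows(lapply(1:4, function(t) {
    tibble::tibble(
      snp_id = snps, chrom = map$chrom, pos = map$pos,
      trait = c("wbsf", "t2", "t3", "t4")[t],
      effect = round(seq(-0.9, 0.9, length.out = 10), 2) * t,
      se = 0.1,
      p_value = if (t == 1) key_p else other_p[, t - 1],
      n_used = 100L, degenerate = FALSE
    )
  }))
  # genes: s01 inside [400,600]; s03 at exactly start-2500 of [6500,7000];
  # s04 at exactly end+2501 of [6500,7000] -> dropped; s06 inside
  # [19000,21000]; s07 at end+2500 of [22000,23500]; s09/s10 far from all
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    chrom = "chr1",
    start = c(400, 6500, 19000, 22000),
    end = c(600, 7000, 21000, 23500),
    strand = c("+", "+", "-", "+")
  )
  class(genes) <- c("gene_models", class(genes))
  list(map = map, gwas = gwas, genes = genes)
}
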