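#' Association Weight Matrix configuration
#'
#' The AWM selects SNPs through a fixed funnel: (1) nominal significance
#' for the key phenotype, (2) nominal significance for at least
#' `min_other_traits` of the remaining phenotypes (the pleiotropy filter),
#' (3) location within a gene or within `gene_window_bp` of one. The kept
#' SNPs' per-trait allele-substitution effects form the matrix handed to
#' PCIT.
#'
#' `min_other_traits` defaults to 2, counting traits other than the key
#' one; `include_key_trait_column` controls whether the key trait
#' contributes a column of its own (on by default; turn off to reproduce a
#' traits-minus-one column layout).
#'
#' @param key_trait key phenotype column name.
#' @param key_p_threshold,other_p_threshold nominal p-value cut-offs
#'   (default 0.05 each).
#' @param min_other_traits minimum number of *other* traits a SNP must be
#'   associated with (default 2).
#' @param gene_window_bp gene proximity window in bp (default 2500).
#' @param standardize_columns z-score each effect column over the selected
#'   rows (default TRUE).
#' @param include_key_trait_column keep the key trait's effect column
#'   (default TRUE).
#' @return An `awm_config` list.
#' @export
awm_config <- function(key_trait,
                       key_p_threshold = 0.05,
                       other_p_threshold = 0.05,
                       min_other_traits = 2,
                       gene_window_bp = 2500,
                       standardize_columns = TRUE,
                       include_key_trait_column = TRUE) {
  if (key_p_threshold <= 0 || key_p_threshold > 1 ||
      other_p_threshold <= 0 || other_p_threshold > 1) {
    abort("p-value thresholds must lie in (0, 1]")
  }
  if (gene_window_bp < 0) abort("gene_window_bp must be >= 0")
  structure(
    list(
      key_trait = key_trait, key_p_threshold = key_p_threshold,
      other_p_threshold = other_p_threshold,
      min_other_traits = min_other_traits,
      gene_window_bp = gene_window_bp,
      standardize_columns = standardize_columns,
      include_key_trait_column = include_key_trait_column
    ),
    class = "awm_config"
  )
}

gwas_table <- function(gwas) {
  if (inherits(gwas, "gwas_result")) gwas$gwas else as_tibble(gwas)
}

#' Select SNPs nominally associated with the key phenotype
#'
#' @param gwas a `gwas_result` or its tibble (`snp_id`, `trait`,
#'   `p_value`, ...).
#' @param config an [awm_config].
#' @return SNP ids with key-trait p below the threshold, ordered by p
#'   ascending.
#' @export
select_key_snps <- function(gwas, config) {
  g <- gwas_table(gwas)
  k <- filter(g, .data$trait == config$key_trait)
  if (nrow(k) == 0) abort(sprintf("key trait '%s' absent from GWAS table", config$key_trait))
  k <- arrange(filter(k, .data$p_value < config$key_p_threshold), .data$p_value)
  k$snp_id
}

#' Count other-trait associations per SNP
#'
#' For each selected SNP, the number of phenotypes other than the key one
#' with p below `other_p_threshold`.
#'
#' @inheritParams select_key_snps
#' @param snp_ids SNPs selected by [select_key_snps()].
#' @return A tibble (`snp_id`, `n_other`) in the input SNP order, with the
#'   across-SNP mean count as attribute `"mean_other"`.
#' @export
count_other_trait_hits <- function(gwas, snp_ids, config) {
  if (length(snp_ids) == 0) abort("snp_ids is empty")
  g <- gwas_table(gwas)
  o <- filter(
    g, .data$snp_id %in% snp_ids, .data$trait != config$key_trait,
    .data$p_value < config$other_p_threshold
  )
  tab <- table(factor(o$snp_id, levels = snp_ids))
  out <- tibble(snp_id = snp_ids, n_other = as.integer(tab[snp_ids]))
  attr(out, "mean_other") <- mean(out$n_other)
  out
}

#' Keep SNPs associated with enough other phenotypes
#'
#' @param counts output of [count_other_trait_hits()].
#' @param config an [awm_config].
#' @return Surviving SNP ids (input order preserved).
#' @export
filter_by_pleiotropy <- function(counts, config) {
  counts$snp_id[counts$n_other >= config$min_other_traits]
}

#' Keep SNPs inside or near a gene
#'
#' A SNP is kept iff its position falls in
#' `[gene start - window, gene end + window]` for some gene (1-based,
#' inclusive). The mapping records whether the SNP is within the gene
#' (distance 0) or near it, and the nearest gene (ties broken by smaller
#' distance, then lexicographically smaller gene id).
#'
#' @param snp_ids candidate SNP ids.
#' @param map marker map (`snp_id`, `chrom`, `pos`).
#' @param gene_models a `gene_models` tibble.
#' @param window proximity window in bp.
#' @return A tibble (`snp_id`, `gene_id`, `distance`, `location`), one row
#'   per kept SNP, in genome order.
#' @export
filter_by_gene_proximity <- function(snp_ids, map, gene_models, window = 2500) {
  ann <- annotate_snps(snp_ids, map, gene_models, window = window)
  kept <- filter(ann, .data$category != "intergenic")
  select(
    rename(kept, location = "category"),
    "snp_id", "gene_id", "distance", "location"
  )
}

#' Assemble the Association Weight Matrix
#'
#' Runs the full selection funnel (key-trait filter, pleiotropy filter,
#' gene-proximity filter) and assembles the selected-SNP x trait matrix of
#' allele-substitution effects, optionally z-scoring each trait column over
#' the selected rows. Rows are in genome order; columns follow the GWAS
#' table's trait order.
#'
#' @param gwas a `gwas_result` or GWAS tibble covering all traits.
#' @param map marker map (`snp_id`, `chrom`, `pos`); taken from the GWAS
#'   table's `chrom`/`pos` columns if `NULL`.
#' @param gene_models a `gene_models` tibble, or `NULL` to skip the
#'   proximity filter.
#' @param config an [awm_config].
#' @return An `awm` object: `matrix` (SNP x trait effects), `row_info`
#'   (snp, chrom, pos, gene, location, n_other), `traits`, `funnel`
#'   (per-stage SNP counts), `config`.
#' @export
build_awm <- function(gwas, config, map = NULL, gene_models = NULL) {
  g <- gwas_table(gwas)
  if (is.null(map)) {
    map <- dplyr::distinct(select(g, "snp_id", "chrom", "pos"))
  }
  key <- select_key_snps(g, config)
  funnel <- tibble(stage = "key_trait_p", n = length(key))
  if (length(key) == 0) abort("no SNP passes the key-trait threshold")

  counts <- count_other_trait_hits(g, key, config)
  pleio <- filter_by_pleiotropy(counts, config)
  funnel <- bind_rows(funnel, tibble(stage = "pleiotropy", n = length(pleio)))
  if (length(pleio) == 0) abort("no SNP passes the pleiotropy filter")

  if (!is.null(gene_models)) {
    mapping <- filter_by_gene_proximity(
      pleio, map, gene_models, window = config$gene_window_bp
    )
    kept <- mapping$snp_id
  } else {
    mapping <- tibble(
      snp_id = pleio, gene_id = NA_character_,
      distance = NA_real_, location = NA_character_
    )
    kept <- pleio
  }
  funnel <- bind_rows(funnel, tibble(stage = "gene_proximity", n = length(kept)))
  if (length(kept) == 0) abort("no SNP is within the gene window")

  traits <- unique(g$trait)
  if (!config$include_key_trait_column) traits <- setdiff(traits, config$key_trait)

  eff <- tidyr::pivot_wider(
    filter(g, .data$snp_id %in% kept, .data$trait %in% traits),
    id_cols = "snp_id", names_from = "trait", values_from = "effect"
  )
  miss_col <- names(eff)[-1][colSums(is.na(eff[-1])) > 0]
  if (length(miss_col) > 0) {
    warn(sprintf("dropping trait column(s) with missing effects: %s",
                 paste(miss_col, collapse = ", ")))
    eff <- eff[, !(names(eff) %in% miss_col)]
    traits <- setdiff(traits, miss_col)
  }

  # genome order
  ord <- map[match(eff$snp_id, map$snp_id), ]
  o <- order(match(ord$chrom, unique(map$chrom)), ord$pos)
  eff <- eff[o, ]
  M <- as.matrix(eff[, traits, drop = FALSE])
  rownames(M) <- eff$snp_id
  if (config$standardize_columns) {
    M <- scale(M)
    attr(M, "scaled:center") <- NULL
    attr(M, "scaled:scale") <- NULL
  }

  row_info <- left_join(
    tibble(snp_id = rownames(M)),
    left_join(mapping, counts, by = "snp_id"),
    by = "snp_id"
  )
  row_info <- left_join(row_info, map, by = "snp_id") |>
    select("snp_id", "chrom", "pos", "gene_id", "distance", "location", "n_other")

  structure(
    list(matrix = M, row_info = row_info, traits = traits,
         funnel = funnel, config = config),
    class = "awm"
  )
}

#' @export
print.awm <- function(x, ...) {
  cat(sprintf(
    "<awm> %d SNPs x %d traits (key: %s)%s\n",
    nrow(x$matrix), ncol(x$matrix), x$config$key_trait,
    if (x$config$standardize_columns) ", columns standardized" else ""
  ))
  cat("  funnel:",
      paste(sprintf("%s=%d", x$funnel$stage, x$funnel$n), collapse = " -> "),
      "\n")
  invisible(x)
}

#' @export
tidy.awm <- function(x, ...) {
  as_tibble(x$matrix, rownames = "snp_id") |>
    tidyr::pivot_longer(-"snp_id", names_to = "trait", values_to = "effect") |>
    left_join(x$row_info, by = "snp_id")
}

#' @export
glance.awm <- function(x, ...) {
  tibble(
    n_snps = nrow(x$matrix), n_traits = ncol(x$matrix),
    key_trait = x$config$key_trait,
    n_key = x$funnel$n[x$funnel$stage == "key_trait_p"],
    n_pleiotropic = x$funnel$n[x$funnel$stage == "pleiotropy"],
    n_gene_proximal = x$funnel$n[x$funnel$stage == "gene_proximity"]
  )
}

#' Write an AWM and its row metadata as TSV
#' @param awm an `awm` object.
#' @param path effects TSV path; the row metadata sidecar is written next
#'   to it as `<path>.rows.tsv`.
#' @return `path`, invisibly.
#' @export
write_awm <- function(awm, path) {
  readr::write_tsv(as_tibble(awm$matrix, rownames = "snp_id"), path)
  readr::write_tsv(awm$row_info, paste0(path, ".rows.tsv"))
  invisible(path)
}
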