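#' Annotate SNPs against gene models
#'
#' Deterministic nearest-gene assignment by interval arithmetic
#' (GenomicRanges): a SNP inside a gene is `within_gene` (distance 0), a
#' SNP within `window` bp of a gene boundary is `near_gene`, anything else
#' `intergenic`. Ties go to the smaller distance, then the
#' lexicographically smaller gene id. For near-gene SNPs the sub-category
#' is `upstream`/`downstream` relative to the nearest gene's strand. SNPs
#' on chromosomes absent from the gene models are intergenic, with a
#' warning.
#'
#' @param snp_ids SNPs to annotate.
#' @param map marker map (`snp_id`, `chrom`, `pos`).
#' @param gene_models a `gene_models` tibble (1-based inclusive).
#' @param window proximity window in bp (default 2500).
#' @return A tibble: `snp_id`, `gene_id`, `distance`, `category`,
#'   `subcategory`.
#' @export
annotate_snps <- function(snp_ids, map, gene_models, window = 2500) {
  map <- as_tibble(map)
  rows <- map[match(snp_ids, map$snp_id), ]
  if (anyNA(rows$snp_id)) {
    abort(sprintf("SNPs absent from the marker map: %s",
                  paste(head(snp_ids[is.na(rows$snp_id)], 5), collapse = ", ")))
  }
  if (nrow(gene_models) == 0) {
    return(tibble(
      snp_id = snp_ids, gene_id = NA_character_, distance = NA_real_,
      category = "intergenic", subcategory = NA_character_
    ))
  }
  off_chrom <- setdiff(unique(rows$chrom), unique(gene_models$chrom))
  if (length(off_chrom) > 0) {
    warn(sprintf("chromosome(s) absent from gene models, SNPs set intergenic: %s",
                 paste(off_chrom, collapse = ", ")))
  }
  gm <- arrange(as_tibble(gene_models), .data$gene_id)
  gr_genes <- gene_models_to_granges(gm)
  gr_snps <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$pos, width = 1)
  )
  suppressWarnings({
    hits <- GenomicRanges::distanceToNearest(gr_snps, gr_genes, select = "all")
  })
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # distanceToNearest() counts adjacent ranges as distance 0; recompute the
  # base-pair distance (0 iff the SNP lies inside the gene) and break ties
  # by smaller distance then lexicographically smaller gene id
  td <- pmax(0, gm$start[sh] - rows$pos[qh], rows$pos[qh] - gm$end[sh])
  ord <- order(qh, td, gm$gene_id[sh])
  first <- ord[!duplicated(qh[ord])]
  gene_id <- rep(NA_character_, length(snp_ids))
  distance <- rep(NA_real_, length(snp_ids))
  gene_id[qh[first]] <- gm$gene_id[sh[first]]
  distance[qh[first]] <- td[first]
  category <- dplyr::case_when(
    is.na(distance) ~ "intergenic",
    distance == 0 ~ "within_gene",
    distance <= window ~ "near_gene",
    TRUE ~ "intergenic"
  )
  gene_id[category == "intergenic"] <- NA_character_
  distance[category == "intergenic"] <- NA_real_

  subcat <- rep(NA_character_, length(snp_ids))
  near <- which(category == "near_gene")
  if (length(near) > 0) {
    gi <- match(gene_id[near], gm$gene_id)
    before <- rows$pos[near] < gm$start[gi]
    plus <- gm$strand[gi] != "-"
    subcat[near] <- ifelse(before == plus, "upstream", "downstream")
  }
  tibble(
    snp_id = snp_ids, gene_id = gene_id, distance = distance,
    category = category, subcategory = subcat
  )
}

#' Hypergeometric term enrichment
#'
#' For every term, the upper-tail hypergeometric probability of observing
#' at least the overlap between the gene list and the term within the
#' universe; Benjamini-Hochberg FDR across the tested terms; fold
#' enrichment FE = (count/list)/(term/universe). Term memberships are
#' intersected with the universe first; terms with zero overlap are
#' skipped. Results are sorted by p ascending.
#'
#' @param gene_list character vector of genes of interest (must be a
#'   subset of `universe`).
#' @param universe background gene set.
#' @param terms a `term_sets` list (term id -> gene ids).
#' @param p_max report terms with p below this (default 1: all).
#' @return An `enrichment_result` tibble: `term`, `count`, `list_size`,
#'   `term_size`, `universe_size`, `percent`, `p_value`,
#'   `fold_enrichment`, `fdr`.
#' @export
hypergeometric_enrichment <- function(gene_list, universe, terms, p_max = 1) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (length(gene_list) == 0 || length(universe) == 0) {
    abort("gene list and universe must be non-empty")
  }
  extra <- setdiff(gene_list, universe)
  if (length(extra) > 0) {
    abort(sprintf("gene list contains genes outside the universe (e.g. %s)",
                  extra[1]))
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- purrr::imap(terms, function(genes, nm) {
    g <- intersect(unique(genes), universe)
    K <- length(g)
    k <- length(intersect(g, gene_list))
    if (k == 0) return(NULL)
    tibble(
      term = nm, count = k, list_size = n, term_size = K, universe_size = N,
      percent = 100 * k / n,
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      fold_enrichment = (k / n) / (K / N)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(structure(
      tibble(
        term = character(0), count = integer(0), list_size = integer(0),
        term_size = integer(0), universe_size = integer(0),
        percent = numeric(0), p_value = numeric(0),
        fold_enrichment = numeric(0), fdr = numeric(0)
      ),
      class = c("enrichment_result", class(tibble()))
    ))
  }
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- arrange(filter(out, .data$p_value <= p_max), .data$p_value, .data$term)
  structure(out, class = c("enrichment_result", class(out)))
}

#' DAVID-style cluster enrichment score
#'
#' Minus log10 of the geometric mean of the member terms' p-values. A
#' score of 1.3 corresponds to a geometric-mean p of 0.05, the
#' conventional significance threshold for functional annotation
#' clusters.
#'
#' @param p member p-values, each in (0, 1].
#' @return The enrichment score.
#' @export
#' @examples
#' cluster_enrichment_score(c(0.05, 0.05))  # ~1.301
cluster_enrichment_score <- function(p) {
  if (length(p) == 0) abort("empty member set")
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  -mean(log10(p))
}

#' Cohen's kappa between term memberships
#'
#' Kappa on the binary gene-membership vectors of every term pair over the
#' analysed gene list: (P_obs - P_exp) / (1 - P_exp). When P_exp = 1 (both
#' terms cover all genes or none) kappa is set to 1 for identical vectors
#' and 0 otherwise.
#'
#' @param terms a `term_sets` list.
#' @param gene_list genes over which membership is evaluated.
#' @return A symmetric term-by-term kappa matrix.
#' @export
kappa_matrix <- function(terms, gene_list) {
  gene_list <- unique(gene_list)
  B <- vapply(terms, function(g) gene_list %in% g, logical(length(gene_list)))
  B <- matrix(B, nrow = length(gene_list),
              dimnames = list(gene_list, names(terms)))
  nz <- colSums(B) > 0
  if (sum(nz) < 2) abort("need at least 2 terms with non-empty membership on the gene list")
  B <- B[, nz, drop = FALSE]
  m <- ncol(B)
  n <- nrow(B)
  K <- matrix(1, m, m, dimnames = list(colnames(B), colnames(B)))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- B[, i]
      b <- B[, j]
      p_obs <- mean(a == b)
      pa <- mean(a)
      pb <- mean(b)
      p_exp <- pa * pb + (1 - pa) * (1 - pb)
      kap <- if (abs(1 - p_exp) < 1e-12) {
        if (all(a == b)) 1 else 0
      } else {
        (p_obs - p_exp) / (1 - p_exp)
      }
      K[i, j] <- K[j, i] <- kap
    }
  }
  K
}

#' Group enriched terms by kappa agreement
#'
#' Single-linkage connected components over the graph whose edges join
#' term pairs with kappa strictly above the threshold. Each group's
#' representative is its member with the smallest enrichment p-value; the
#' group score is the [cluster_enrichment_score()] of the members.
#'
#' @param kappa term-by-term kappa matrix from [kappa_matrix()].
#' @param enrichment an `enrichment_result` covering the terms.
#' @param threshold kappa threshold (default 0.3).
#' @return A `term_groups` tibble: `group`, `representative`, `n_terms`,
#'   `members`, `group_score`, `min_p`.
#' @export
group_terms <- function(kappa, enrichment, threshold = 0.3) {
  terms <- intersect(rownames(kappa), enrichment$term)
  if (length(terms) == 0) abort("no overlap between kappa matrix and enrichment terms")
  K <- kappa[terms, terms, drop = FALSE]
  A <- K > threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  p <- setNames(enrichment$p_value, enrichment$term)[terms]
  out <- bind_rows(lapply(sort(unique(comp)), function(cid) {
    mem <- terms[comp == cid]
    mp <- p[mem]
    tibble(
      representative = mem[order(mp, mem)][1],
      n_terms = length(mem),
      members = list(mem[order(mp, mem)]),
      group_score = cluster_enrichment_score(mp),
      min_p = min(mp)
    )
  }))
  out <- arrange(out, .data$min_p, .data$representative)
  out$group <- seq_len(nrow(out))
  structure(
    select(out, "group", "representative", "n_terms", "members",
           "group_score", "min_p"),
    class = c("term_groups", class(out))
  )
}

#' Write an enrichment table as TSV
#'
#' Column layout mirrors a functional-annotation chart: Term, Count, %,
#' P-value, FE (fold enrichment), FDR. The universe definition is recorded
#' in a header comment.
#'
#' @param enrichment an `enrichment_result`.
#' @param path output TSV.
#' @param universe_label one-line description of the background set.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path,
                             universe_label = "genes hosting >=1 post-QC SNP") {
  writeLines(sprintf("# universe: %s (n = %s)", universe_label,
                     enrichment$universe_size[1]), path)
  readr::write_tsv(
    select(as_tibble(enrichment), Term = "term", Count = "count",
           `%` = "percent", `P-value` = "p_value", FE = "fold_enrichment",
           FDR = "fdr"),
    path, append = TRUE, col_names = TRUE
  )
  invisible(path)
}
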