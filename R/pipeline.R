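#' Run the full co-association network analysis
#'
#' Orchestrates every stage end-to-end: synthetic data generation (or
#' loading of user-supplied files), marker/sample QC, GRM construction,
#' per-trait EMMAX scans, AWM assembly, PCIT edge significance, MCODE
#' clustering, SNP-to-gene annotation, and term enrichment with kappa
#' grouping. Exactly one of `sim`/`inputs` must be supplied. With a fixed
#' seed the run is bit-reproducible; the per-stage funnel counts are
#' recorded in the manifest.
#'
#' @param sim a [sim_config] describing a synthetic study, or `NULL`.
#' @param inputs a list of file paths (`plink_prefix`, `phenotypes`,
#'   `gff3`, `gmt` (optional)), or `NULL`.
#' @param qc a [qc_thresholds].
#' @param awm an [awm_config]; default keys on `trait_1`.
#' @param mcode an [mcode_params].
#' @param enrich_p_max report enriched terms at p below this (default 0.05).
#' @param kappa_threshold kappa grouping threshold (default 0.3).
#' @param hwe_method HWE variant for QC (`"chi2"` default here for speed on
#'   dense panels; `"exact"` available).
#' @param out_dir optional directory; when given, every stage's public
#'   artifact is written there (PLINK, TSV, GFF3, GMT, GraphML).
#' @param min_n minimum per-trait sample size (see [run_multitrait_gwas()]).
#' @return An `awmnet_pipeline` object with every stage result
#'   (`genotypes`, `qc_report`, `grm`, `gwas`, `awm`, `network`,
#'   `clusters`, `annotation`, `enrichment`, `term_groups`, `truth`) and a
#'   `manifest` tibble of per-stage counts.
#' @export
run_pipeline <- function(sim = sim_config(),
                         inputs = NULL,
                         qc = qc_thresholds(),
                         awm = awm_config("trait_1"),
                         mcode = mcode_params(),
                         enrich_p_max = 0.05,
                         kappa_threshold = 0.3,
                         hwe_method = c("chi2", "exact"),
                         out_dir = NULL,
                         min_n = 30) {
  hwe_method <- match.arg(hwe_method)
  if (!is.null(sim) && !is.null(inputs)) {
    abort("supply either a sim_config or file inputs, not both")
  }
  if (is.null(sim) && is.null(inputs)) abort("no inputs configured")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, n_in = n_in, n_out = n_out, detail = detail
    )
  }

  truth <- NULL
  if (!is.null(sim)) {
    geno <- simulate_genotypes(sim)
    ph <- simulate_phenotypes(geno, sim)
    phenotypes <- ph$phenotypes
    truth <- ph$truth
    gene_models <- make_gene_models(geno$map, qtl_ids = truth$qtl_ids,
                                    seed = sim$seed)
    qtl_genes <- qtl_host_genes(truth$qtl_ids, geno$map, gene_models)
    terms <- make_term_annotation(gene_models, qtl_gene_ids = qtl_genes,
                                  seed = sim$seed)
    note("simulate", NA_integer_, nrow(geno$X),
         sprintf("%d SNPs, %d traits", ncol(geno$X), sim$n_traits))
  } else {
    geno <- read_plink(inputs$plink_prefix)
    phenotypes <- read_phenotypes(inputs$phenotypes)
    gene_models <- read_gff3(inputs$gff3)
    terms <- if (!is.null(inputs$gmt)) read_gmt(inputs$gmt) else NULL
    note("load", NA_integer_, nrow(geno$X),
         sprintf("%d SNPs", ncol(geno$X)))
  }

  n_snps_raw <- ncol(geno$X)
  geno_qc <- apply_qc(geno, qc, hwe_method = hwe_method)
  qc_rep <- qc_report(geno_qc)
  note("qc", n_snps_raw, ncol(geno_qc$X),
       sprintf("samples %d -> %d", qc_rep$n_samples_in, qc_rep$n_samples_out))

  K <- stabilize(compute_grm(geno_qc))
  note("grm", ncol(geno_qc$X), nrow(K$K), K$method)

  gwas <- run_multitrait_gwas(phenotypes, geno_qc, K = K, min_n = min_n)
  note("gwas", ncol(geno_qc$X), nrow(gwas$gwas),
       sprintf("%d traits", nrow(gwas$trait_summary)))

  awm_obj <- build_awm(gwas, awm, map = geno_qc$map, gene_models = gene_models)
  note("awm", ncol(geno_qc$X), nrow(awm_obj$matrix),
       paste(sprintf("%s=%d", awm_obj$funnel$stage, awm_obj$funnel$n),
             collapse = " -> "))

  corr <- correlate_rows(awm_obj)
  mask <- pcit(corr)
  network <- build_network(awm_obj, corr, mask)
  note("pcit", nrow(awm_obj$matrix), igraph::vcount(network$graph),
       sprintf("%d edges", igraph::ecount(network$graph)))

  clusters <- annotation <- enrichment <- groups <- NULL
  skipped <- character(0)
  if (!network$empty) {
    clusters <- find_clusters(network, mcode)
    note("mcode", igraph::vcount(network$graph),
         length(cluster_nodes(clusters)),
         sprintf("%d clusters", length(clusters$clusters)))
    annotation <- annotate_snps(network$nodes$node, geno_qc$map, gene_models,
                                window = awm$gene_window_bp)
    note("annotate", igraph::vcount(network$graph),
         sum(!is.na(annotation$gene_id)), "nearest-gene assignment")
    if (!is.null(terms)) {
      universe <- snp_universe_genes(geno_qc$map, gene_models,
                                     window = awm$gene_window_bp)
      gene_list <- intersect(unique(annotation$gene_id[!is.na(annotation$gene_id)]),
                             universe)
      if (length(gene_list) > 0) {
        enrichment <- hypergeometric_enrichment(gene_list, universe, terms,
                                                p_max = 1)
        sig <- filter(enrichment, .data$p_value < enrich_p_max)
        note("enrich", length(terms), nrow(sig),
             sprintf("universe %d, list %d", length(universe), length(gene_list)))
        if (nrow(sig) >= 2) {
          kap <- kappa_matrix(terms[sig$term], gene_list)
          groups <- group_terms(kap, sig, threshold = kappa_threshold)
        }
      } else {
        skipped <- c(skipped, "enrichment: no network gene overlaps the universe")
      }
    } else {
      skipped <- c(skipped, "enrichment skipped: no term annotation (GMT) supplied")
    }
  } else {
    skipped <- c(skipped, "mcode/annotation/enrichment skipped: empty network")
  }

  res <- structure(
    list(
      genotypes = geno_qc, phenotypes = phenotypes, qc_report = qc_rep,
      grm = K, gwas = gwas, awm = awm_obj, network = network,
      clusters = clusters, annotation = annotation,
      enrichment = enrichment, term_groups = groups,
      truth = truth, gene_models = gene_models, terms = terms,
      manifest = bind_rows(manifest), skipped = skipped
    ),
    class = "awmnet_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

# genes hosting (or within window of) at least one QTL SNP
qtl_host_genes <- function(qtl_ids, map, gene_models, window = 0) {
  ann <- annotate_snps(qtl_ids, map, gene_models, window = max(window, 0))
  unique(ann$gene_id[!is.na(ann$gene_id) & ann$category == "within_gene"])
}

# enrichment universe: every gene hosting >= 1 post-QC SNP (within window)
snp_universe_genes <- function(map, gene_models, window = 2500) {
  ann <- annotate_snps(map$snp_id, map, gene_models, window = window)
  sort(unique(ann$gene_id[!is.na(ann$gene_id)]))
}

#' Fraction of planted QTL-hosting genes recovered in MCODE clusters
#'
#' Ground-truth check for synthetic runs: among genes hosting a planted
#' pleiotropic QTL (>= 2 affected traits), the fraction present in any
#' MCODE cluster of the pipeline result.
#'
#' @param pipeline an `awmnet_pipeline` run from a [sim_config].
#' @return A single fraction in \[0, 1\] (NA when there are no QTL genes).
#' @export
qtl_recovery <- function(pipeline) {
  stopifnot(inherits(pipeline, "awmnet_pipeline"))
  if (is.null(pipeline$truth)) abort("pipeline was not run on synthetic data")
  tr <- pipeline$truth
  pleio <- names(tr$qtl_trait_map)[lengths(tr$qtl_trait_map) >= 2]
  genes <- qtl_host_genes(pleio, pipeline$genotypes$map, pipeline$gene_models)
  if (length(genes) == 0) return(NA_real_)
  if (is.null(pipeline$clusters)) return(0)
  in_clusters <- pipeline$annotation$gene_id[
    pipeline$annotation$snp_id %in% cluster_nodes(pipeline$clusters)
  ]
  mean(genes %in% in_clusters)
}

write_pipeline <- function(res, out_dir) {
  p <- function(...) file.path(out_dir, ...)
  write_plink(res$genotypes, p("genotypes_postqc"))
  write_phenotypes(res$phenotypes, p("phenotypes.tsv"))
  readr::write_tsv(tidy(res$qc_report), p("qc_removals.tsv"))
  write_grm(res$grm, p("grm.tsv"))
  readr::write_tsv(res$gwas$gwas, p("gwas.tsv"))
  readr::write_tsv(res$gwas$trait_summary, p("trait_summary.tsv"))
  write_awm(res$awm, p("awm.tsv"))
  write_gff3(res$gene_models, p("gene_models.gff3"))
  if (!res$network$empty) {
    write_network(res$network, p("network.graphml"))
    write_network(res$network, p("network_edges.tsv"))
  }
  if (!is.null(res$clusters)) {
    readr::write_tsv(glance(res$clusters), p("clusters.tsv"))
    readr::write_tsv(tidy(res$clusters), p("cluster_nodes.tsv"))
  }
  if (!is.null(res$annotation)) {
    readr::write_tsv(res$annotation, p("snp_annotation.tsv"))
  }
  if (!is.null(res$terms)) write_gmt(res$terms, p("terms.gmt"))
  if (!is.null(res$enrichment)) {
    write_enrichment(res$enrichment, p("enrichment.tsv"))
  }
  if (!is.null(res$term_groups)) {
    tg <- mutate(res$term_groups,
                 members = purrr::map_chr(.data$members, paste, collapse = ","))
    readr::write_tsv(tg, p("term_groups.tsv"))
  }
  readr::write_tsv(res$manifest, p("manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.awmnet_pipeline <- function(x, ...) {
  cat("<awmnet_pipeline>\n")
  print(x$manifest)
  if (length(x$skipped) > 0) cat("  note:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Human-readable pipeline summary
#'
#' Prints the per-trait heritabilities and significance counts, the AWM
#' selection funnel, the cluster score table (network, score, nodes,
#' edges) and the top enriched terms.
#'
#' @param x an object with a report method.
#' @param ... passed on.
#' @export
report <- function(x, ...) UseMethod("report")

#' @rdname report
#' @param n_terms how many top enriched terms to show.
#' @export
report.awmnet_pipeline <- function(x, n_terms = 10, ...) {
  cat("== Per-trait GWAS summary ==\n")
  print(x$gwas$trait_summary, n = Inf)
  cat("\n== AWM selection funnel ==\n")
  print(x$awm$funnel)
  cat("\n== MCODE clusters ==\n")
  if (!is.null(x$clusters) && length(x$clusters$clusters) > 0) {
    print(select(x$clusters$summary, "network", "score", "nodes", "edges"))
  } else {
    cat("no clusters\n")
  }
  cat("\n== Top enriched terms ==\n")
  if (!is.null(x$enrichment) && nrow(x$enrichment) > 0) {
    print(head(as_tibble(x$enrichment), n_terms))
  } else {
    cat("enrichment not run\n")
  }
  invisible(x)
}

#' @export
glance.awmnet_pipeline <- function(x, ...) {
  tibble(
    n_snps_postqc = ncol(x$genotypes$X),
    n_animals = nrow(x$genotypes$X),
    n_traits = nrow(x$gwas$trait_summary),
    n_awm_snps = nrow(x$awm$matrix),
    n_network_nodes = igraph::vcount(x$network$graph),
    n_network_edges = igraph::ecount(x$network$graph),
    n_clusters = if (is.null(x$clusters)) 0L else length(x$clusters$clusters),
    n_enriched_terms = if (is.null(x$enrichment)) 0L else
      sum(x$enrichment$p_value < 0.05)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys `sim`, `qc`, `awm`, `mcode` and scalar options map to the
#' corresponding constructor arguments of [run_pipeline()]; an `inputs`
#' key gives file paths instead of `sim`.
#'
#' @param path YAML file.
#' @return A named list of arguments for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$inputs)) {
    args$inputs <- y$inputs
    args$sim <- NULL
  } else {
    args$sim <- do.call(sim_config, y$sim %||% list())
  }
  if (!is.null(y$qc)) args$qc <- do.call(qc_thresholds, y$qc)
  if (!is.null(y$awm)) args$awm <- do.call(awm_config, y$awm)
  if (!is.null(y$mcode)) args$mcode <- do.call(mcode_params, y$mcode)
  for (k in c("enrich_p_max", "kappa_threshold", "out_dir", "min_n")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  args
}
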