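#' Correlations among AWM rows
#'
#' Pearson correlation between every pair of AWM rows across the trait
#' columns — the co-association measure on which PCIT operates. Constant
#' rows (zero variance across traits) are excluded with a warning before
#' correlation.
#'
#' @param awm an `awm` object or a plain numeric matrix (rows = SNPs).
#' @return A symmetric correlation matrix with unit diagonal, node ids as
#'   dimnames.
#' @export
correlate_rows <- function(awm) {
  M <- if (inherits(awm, "awm")) awm$matrix else as.matrix(awm)
  if (ncol(M) < 3) abort("need at least 3 trait columns to correlate rows")
  keep <- apply(M, 1, sd) > 0
  if (!all(keep)) {
    warn(sprintf("excluding %d constant AWM row(s) before correlation",
                 sum(!keep)))
    M <- M[keep, , drop = FALSE]
  }
  r <- cor(t(M))
  diag(r) <- 1
  r
}

#' First-order partial correlation
#'
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)): the
#' correlation between x and y once their common dependence on z is
#' removed. Returns `NA` (a sentinel the caller must handle) when either
#' conditioning correlation has magnitude 1.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations.
#' @return The partial correlation, or `NA` when undefined.
#' @export
#' @examples
#' first_order_partial(0.5, 0, 0)        # 0.5: conditioning changes nothing
#' first_order_partial(0.9, 0.9, 0.9)    # 0.09 / 0.19
first_order_partial <- function(r_xy, r_xz, r_yz) {
  d2 <- (1 - r_xz^2) * (1 - r_yz^2)
  out <- (r_xy - r_xz * r_yz) / sqrt(d2)
  out[d2 <= .Machine$double.eps] <- NA_real_
  out
}

#' PCIT edge significance
#'
#' For every trio (x, y, z) the three first-order partial correlations are
#' computed and the information-theoretic tolerance is the mean of the
#' three partial-to-direct ratios,
#' eps = (r_xy.z/r_xy + r_xz.y/r_xz + r_yz.x/r_yz) / 3.
#' The trio flags edge (x, y) as non-significant when
#' |r_xy| <= |eps * r_xz| and |r_xy| <= |eps * r_yz|; an edge is
#' significant iff no trio flags it. Trios whose partials are undefined
#' (a conditioning correlation within 1e-12 of +/-1, or a zero direct
#' correlation making a ratio non-finite) are skipped. With fewer than 3
#' nodes every edge is retained vacuously.
#'
#' The implementation vectorizes over z (one matrix sweep per conditioning
#' node) and is outcome-identical to the naive O(n^3) triple loop.
#'
#' @param corr symmetric correlation matrix from [correlate_rows()].
#' @return A logical significance mask (symmetric, `FALSE` diagonal).
#' @export
pcit <- function(corr) {
  r <- as.matrix(corr)
  n <- nrow(r)
  stopifnot(ncol(r) == n)
  if (max(abs(r - t(r))) > 1e-8) abort("correlation matrix must be symmetric")
  sig <- matrix(TRUE, n, n)
  diag(sig) <- FALSE
  if (n < 3) {
    dimnames(sig) <- dimnames(r)
    return(sig)
  }
  near_one <- abs(r) >= 1 - 1e-12
  one_minus_sq <- pmax(1 - r^2, 0)
  for (z in seq_len(n)) {
    rz <- r[, z]
    M1 <- matrix(rz, n, n)        # M1[x, y] = r_xz
    M2 <- t(M1)                   # M2[x, y] = r_yz
    dz <- sqrt(one_minus_sq[, z]) # sqrt(1 - r_xz^2)
    pc_xy_z <- (r - M1 * M2) / outer(dz, dz)
    den_xy <- sqrt(one_minus_sq)  # sqrt(1 - r_xy^2), elementwise
    pc_xz_y <- (M1 - r * M2) / (den_xy * matrix(dz, n, n, byrow = TRUE))
    pc_yz_x <- (M2 - r * M1) / (den_xy * matrix(dz, n, n))
    tol <- (pc_xy_z / r + pc_xz_y / M1 + pc_yz_x / M2) / 3
    flag <- abs(r) <= abs(tol * M1) & abs(r) <= abs(tol * M2)
    # a trio only exists for distinct x, y, z; skip undefined trios
    flag[!is.finite(tol)] <- FALSE
    flag[near_one[, z], ] <- FALSE
    flag[, near_one[, z]] <- FALSE
    flag[near_one] <- FALSE
    flag[z, ] <- FALSE
    flag[, z] <- FALSE
    diag(flag) <- FALSE
    sig <- sig & !flag
  }
  sig <- sig & t(sig)
  dimnames(sig) <- dimnames(r)
  sig
}

#' Build the co-association network from significant edges
#'
#' Keeps edges flagged significant by [pcit()], weighted by the direct
#' correlation; isolated nodes are dropped. Node labels carry the mapped
#' gene ids from the AWM row metadata for downstream annotation.
#'
#' @param awm the `awm` object the correlations came from (or `NULL`).
#' @param corr correlation matrix from [correlate_rows()].
#' @param mask significance mask from [pcit()].
#' @return A `coassoc_network`: list with `graph` (igraph), `edges`
#'   (tibble: `node_a`, `node_b`, `weight`), `nodes` (tibble with mapped
#'   genes), and `empty` flag. An empty network is returned with a warning
#'   rather than an error so pipelines can skip downstream stages.
#' @export
build_network <- function(awm, corr, mask) {
  stopifnot(all(dim(corr) == dim(mask)))
  ids <- rownames(corr) %||% sprintf("node_%04d", seq_len(nrow(corr)))
  ut <- which(upper.tri(mask) & mask, arr.ind = TRUE)
  edges <- tibble(
    node_a = ids[ut[, 1]], node_b = ids[ut[, 2]],
    weight = corr[ut]
  )
  if (nrow(edges) == 0) {
    warn("PCIT retained no edge: empty co-association network")
    return(structure(
      list(graph = igraph::make_empty_graph(directed = FALSE),
           edges = edges, nodes = tibble(node = character(0)), empty = TRUE),
      class = "coassoc_network"
    ))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- tibble(node = igraph::V(g)$name)
  if (inherits(awm, "awm")) {
    nodes <- left_join(nodes, awm$row_info, by = c(node = "snp_id"))
    igraph::V(g)$gene_id <- nodes$gene_id
  }
  structure(
    list(graph = g, edges = edges, nodes = nodes, empty = FALSE),
    class = "coassoc_network"
  )
}

#' @export
print.coassoc_network <- function(x, ...) {
  if (x$empty) {
    cat("<coassoc_network> empty (no significant edges)\n")
  } else {
    cat(sprintf(
      "<coassoc_network> %d nodes, %d edges; mean |weight| %.3f\n",
      igraph::vcount(x$graph), igraph::ecount(x$graph),
      mean(abs(x$edges$weight))
    ))
  }
  invisible(x)
}

#' @export
tidy.coassoc_network <- function(x, ...) x$edges

#' @export
glance.coassoc_network <- function(x, ...) {
  tibble(
    n_nodes = igraph::vcount(x$graph), n_edges = igraph::ecount(x$graph),
    empty = x$empty
  )
}

#' Export a network for Cytoscape
#'
#' Writes the edge list as TSV and/or the graph as GraphML.
#'
#' @param network a `coassoc_network`.
#' @param path output file; format chosen by extension (`.graphml` or
#'   `.tsv`).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    readr::write_tsv(network$edges, path)
  }
  invisible(path)
}
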