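#' MCODE parameters
#'
#' Defaults follow the original molecular-complex-detection publication:
#' vertex weight percentage 0.2, haircut on, fluff off, minimum core
#' degree 2.
#'
#' @param vertex_weight_percentage admit a neighbour into a growing
#'   cluster if its weight is at least `(1 - vwp)` times the seed weight.
#' @param haircut remove singly-connected vertices from each cluster
#'   (retain the cluster's 2-core).
#' @param fluff add boundary neighbours whose neighbourhood density
#'   exceeds `fluff_density_threshold`.
#' @param fluff_density_threshold see `fluff`.
#' @param k_core_min core degree used by the haircut step.
#' @param max_depth maximum breadth-first search depth from the seed.
#' @return An `mcode_params` list.
#' @export
mcode_params <- function(vertex_weight_percentage = 0.2,
                         haircut = TRUE,
                         fluff = FALSE,
                         fluff_density_threshold = 0.5,
                         k_core_min = 2,
                         max_depth = 100) {
  if (vertex_weight_percentage < 0 || vertex_weight_percentage > 1) {
    abort("vertex_weight_percentage must lie in [0, 1]")
  }
  structure(
    list(
      vertex_weight_percentage = vertex_weight_percentage,
      haircut = haircut, fluff = fluff,
      fluff_density_threshold = fluff_density_threshold,
      k_core_min = k_core_min, max_depth = max_depth
    ),
    class = "mcode_params"
  )
}

simple_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) return(0)
  n_edges / (n_nodes * (n_nodes - 1) / 2)
}

as_igraph <- function(network) {
  if (inherits(network, "coassoc_network")) network$graph
  else if (igraph::is_igraph(network)) network
  else abort("network must be a coassoc_network or an igraph graph")
}

#' MCODE vertex weights
#'
#' weight(v) = k_max * density of the highest k-core of v's closed
#' neighbourhood, where k_max is that core's degree. Isolated vertices
#' get weight 0.
#'
#' @param network a `coassoc_network` or igraph graph (simple,
#'   undirected).
#' @return A named numeric vector of weights.
#' @export
vertex_weights <- function(network) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name %||% as.character(seq_len(n))
  w <- setNames(numeric(n), ids)
  if (n == 0) return(w)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (v in seq_len(n)) {
    nb <- c(v, as.integer(adj[[v]]))
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) next
    hc <- igraph::induced_subgraph(sub, which(core == k))
    w[v] <- k * simple_density(igraph::vcount(hc), igraph::ecount(hc))
  }
  w
}

#' Score a cluster as density times node count
#'
#' Density uses the simple-graph maximum n(n-1)/2 edges.
#'
#' @param cluster a `cluster` (from [find_clusters()]) or an igraph
#'   subgraph with at least 2 nodes.
#' @return The MCODE score.
#' @export
score_cluster <- function(cluster) {
  if (inherits(cluster, "mcode_cluster")) {
    return(cluster$density * cluster$n_nodes)
  }
  g <- as_igraph(cluster)
  n <- igraph::vcount(g)
  if (n < 2) abort("cluster must have at least 2 nodes")
  simple_density(n, igraph::ecount(g)) * n
}

#' Find dense clusters by the MCODE procedure
#'
#' Vertices are weighted by [vertex_weights()]; clusters are grown
#' greedily from the highest-weight unassigned vertex, including, breadth
#' first, unassigned neighbours whose weight is at least
#' `seed_weight * (1 - vertex_weight_percentage)`. Each vertex joins at
#' most one cluster. The optional haircut retains the cluster's 2-core;
#' the optional fluff step adds boundary neighbours whose closed
#' neighbourhood density exceeds the fluff threshold (fluffed vertices may
#' appear in more than one cluster). Clusters with fewer than 3 nodes are
#' discarded. Results are ranked by score (density x nodes) descending,
#' ties broken by node count then seed id; all internal ties break
#' lexicographically by node id, so output is deterministic.
#'
#' @param network a `coassoc_network` or igraph graph.
#' @param params an [mcode_params].
#' @return An `mcode_clusters` object: list of clusters (each with
#'   `nodes`, `seed`, `n_nodes`, `n_edges`, `density`, `score`, `rank`)
#'   plus a `summary` tibble.
#' @export
find_clusters <- function(network, params = mcode_params()) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  out <- list()
  if (n > 0) {
    ids <- igraph::V(g)$name %||% as.character(seq_len(n))
    igraph::V(g)$name <- ids
    w <- vertex_weights(g)
    order_seeds <- order(-w, ids)
    assigned <- rep(FALSE, n)
    adj <- igraph::adjacent_vertices(g, igraph::V(g))
    for (s in order_seeds) {
      if (assigned[s]) next
      thr <- w[s] * (1 - params$vertex_weight_percentage)
      members <- s
      assigned[s] <- TRUE
      frontier <- s
      depth <- 0
      while (length(frontier) > 0 && depth < params$max_depth) {
        nxt <- integer(0)
        for (v in frontier) {
          for (u in as.integer(adj[[v]])) {
            if (!assigned[u] && w[u] >= thr) {
              assigned[u] <- TRUE
              members <- c(members, u)
              nxt <- c(nxt, u)
            }
          }
        }
        frontier <- nxt
        depth <- depth + 1
      }
      keep <- sort(members)
      if (params$haircut && length(keep) > 1) {
        sub <- igraph::induced_subgraph(g, keep)
        core <- igraph::coreness(sub)
        keep <- keep[core >= params$k_core_min]
      }
      if (params$fluff && length(keep) > 0) {
        boundary <- setdiff(unique(unlist(lapply(keep, function(v) as.integer(adj[[v]])))), keep)
        add <- boundary[vapply(boundary, function(b) {
          nb <- c(b, as.integer(adj[[b]]))
          sub <- igraph::induced_subgraph(g, nb)
          simple_density(igraph::vcount(sub), igraph::ecount(sub)) >
            params$fluff_density_threshold
        }, logical(1))]
        keep <- sort(c(keep, add))
      }
      if (length(keep) < 3) next
      sub <- igraph::induced_subgraph(g, keep)
      nn <- igraph::vcount(sub)
      ne <- igraph::ecount(sub)
      dens <- simple_density(nn, ne)
      out[[length(out) + 1]] <- structure(
        list(
          nodes = ids[keep], seed = ids[s], n_nodes = nn, n_edges = ne,
          density = dens, score = dens * nn
        ),
        class = "mcode_cluster"
      )
    }
  }
  if (length(out) > 0) {
    o <- order(
      -vapply(out, `[[`, numeric(1), "score"),
      -vapply(out, `[[`, numeric(1), "n_nodes"),
      vapply(out, `[[`, character(1), "seed")
    )
    out <- out[o]
    for (i in seq_along(out)) out[[i]]$rank <- i
  }
  summary <- if (length(out) > 0) {
    bind_rows(lapply(out, function(cl) {
      tibble(
        network = cl$rank, score = cl$score, nodes = cl$n_nodes,
        edges = cl$n_edges, density = cl$density, seed = cl$seed
      )
    }))
  } else {
    tibble(
      network = integer(0), score = numeric(0), nodes = integer(0),
      edges = integer(0), density = numeric(0), seed = character(0)
    )
  }
  structure(list(clusters = out, summary = summary, params = params),
            class = "mcode_clusters")
}

#' @export
print.mcode_clusters <- function(x, ...) {
  cat(sprintf("<mcode_clusters> %d cluster(s)\n", length(x$clusters)))
  if (length(x$clusters) > 0) {
    print(select(x$summary, "network", "score", "nodes", "edges"))
  } else {
    cat("  no clusters\n")
  }
  invisible(x)
}

#' @export
print.mcode_cluster <- function(x, ...) {
  cat(sprintf(
    "<mcode_cluster> %d nodes, %d edges, density %.3f, score %.3f (seed %s)\n",
    x$n_nodes, x$n_edges, x$density, x$score, x$seed
  ))
  invisible(x)
}

#' @export
tidy.mcode_clusters <- function(x, ...) {
  bind_rows(lapply(x$clusters, function(cl) {
    tibble(network = cl$rank, node = cl$nodes, seed = cl$seed)
  }))
}

#' @export
glance.mcode_clusters <- function(x, ...) x$summary

#' All node ids assigned to any cluster
#' @param x an `mcode_clusters` object.
#' @return Character vector of node ids.
#' @export
cluster_nodes <- function(x) {
  unique(unlist(lapply(x$clusters, `[[`, "nodes")))
}
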