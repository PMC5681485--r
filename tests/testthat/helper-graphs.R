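clique_plus_background <- function() {
  g <- igraph::disjoint_union(
    igraph::make_full_graph(10), igraph::make_full_graph(8),
    igraph::make_empty_graph(50, directed = FALSE)
  )
  igraph::V(g)$name <- sprintf("v%02d", seq_len(igraph::vcount(g)))
  g
}

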