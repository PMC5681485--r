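#' Simulate gene models over a marker map
#'
#' Places non-overlapping gene intervals so that a requested fraction of
#' SNPs falls inside a gene and a further fraction falls within `window`
#' bp of one; all remaining SNPs are guaranteed farther than `window` from
#' every gene. QTL SNPs are hosted inside genes first, so downstream
#' annotation can recover them.
#'
#' Placement runs in two phases. First, SNPs are designated in/near/
#' intergenic under a feasibility rule: a hosted SNP's gene is confined
#' between the midpoints to its neighbouring SNPs (so genes never
#' overlap), and must stay more than `window` bp clear of any
#' intergenic-designated SNP; candidates are drawn (and topped up) until
#' the quotas are met or no feasible candidate remains. QTL hosts are
#' forced: an intergenic neighbour closer than `window` is excused from
#' the clearance guarantee instead of blocking the QTL (such "shadow"
#' SNPs are rare and recorded). Second, each host's gene interval is drawn
#' inside its feasible span, which by construction cannot fail.
#'
#' @param map marker map tibble (`snp_id`, `chrom`, `pos`).
#' @param qtl_ids SNP ids to host inside genes preferentially.
#' @param fraction_in_gene fraction of SNPs inside a gene (default 0.5).
#' @param fraction_near_gene fraction within `window` of a gene but outside
#'   all genes (default 0.08).
#' @param window proximity window in bp (default 2500).
#' @param gene_length_range gene lengths drawn uniformly from this range.
#' @param seed integer seed.
#' @return A `gene_models` tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 1-based inclusive) with attribute `"designation"`: a tibble
#'   of each SNP's intended category (`in_gene` / `near_gene` /
#'   `intergenic` / `shadow`).
#' @export
make_gene_models <- function(map, qtl_ids = character(0),
                             fraction_in_gene = 0.5,
                             fraction_near_gene = 0.08,
                             window = 2500,
                             gene_length_range = c(2000, 10000),
                             seed = 1) {
  map <- as_tibble(map)
  if (nrow(map) == 0) abort("marker map is empty")
  if (fraction_in_gene + fraction_near_gene > 1) {
    abort("fraction_in_gene + fraction_near_gene must be <= 1")
  }
  set.seed(stage_seed(seed, 3L))
  m <- nrow(map)
  n_in <- round(fraction_in_gene * m)
  n_near <- round(fraction_near_gene * m)
  min_len <- 200

  ord <- order(match(map$chrom, unique(map$chrom)), map$pos)
  pos <- map$pos[ord]
  chrom <- map$chrom[ord]
  prev_i <- c(NA, seq_len(m - 1))
  next_i <- c(seq_len(m - 1) + 1, NA)
  prev_i[c(TRUE, chrom[-1] != chrom[-m])] <- NA
  next_i[c(chrom[-1] != chrom[-m], TRUE)] <- NA

  d <- rep("intergenic", m)
  is_qtl <- map$snp_id[ord] %in% qtl_ids

  blocks_in <- function(i) {
    # intergenic-designated neighbours closer than the window make an
    # in-gene host infeasible
    out <- integer(0)
    p <- prev_i[i]
    if (!is.na(p) && d[p] == "intergenic" && pos[i] - pos[p] <= window) out <- c(out, p)
    nx <- next_i[i]
    if (!is.na(nx) && d[nx] == "intergenic" && pos[nx] - pos[i] <= window) out <- c(out, nx)
    out
  }
  host_bounds <- function(i) {
    p <- prev_i[i]
    nx <- next_i[i]
    lo <- if (is.na(p)) max(1, pos[i] - 60000) else floor((pos[p] + pos[i]) / 2) + 1
    hi <- if (is.na(nx)) pos[i] + 60000 else floor((pos[i] + pos[nx]) / 2)
    # only intergenic neighbours demand window clearance; hosts and shadow
    # SNPs are already protected by the midpoint rule (genes never cross
    # the midpoint, so they cannot cover a neighbouring SNP)
    if (!is.na(p) && d[p] == "intergenic") lo <- max(lo, pos[p] + window + 1)
    if (!is.na(nx) && d[nx] == "intergenic") hi <- min(hi, pos[nx] - window - 1)
    c(lo, hi)
  }
  near_sides <- function(i) {
    # feasible gene-start/end windows on each side of a near host
    b <- host_bounds(i)
    right <- c(max(b[1], pos[i] + 1), min(pos[i] + window, b[2] - min_len + 1))
    left <- c(max(pos[i] - window, b[1] + min_len - 1), min(b[2], pos[i] - 1))
    list(right = right, left = left,
         ok = right[1] <= right[2] || left[1] <= left[2], bounds = b)
  }

  # phase 1a: force QTL hosts, excusing blocking intergenic neighbours
  for (i in which(is_qtl)[seq_len(min(sum(is_qtl), n_in))]) {
    for (b in blocks_in(i)) if (!is_qtl[b]) d[b] <- "shadow"
    d[i] <- "in_gene"
  }
  # phase 1b: top up the in-gene quota among feasible candidates. An
  # intergenic neighbour inside the window blocks a candidate, but close
  # intergenic SNPs can be promoted together (none of them then needs
  # clearance from the others), so blocked candidates are promoted with
  # the transitive closure of their blockers when the quota allows.
  repeat {
    need <- n_in - sum(d == "in_gene")
    if (need <= 0) break
    pool <- sample(which(d == "intergenic"))
    progress <- FALSE
    for (i in pool) {
      if (d[i] != "intergenic") next
      closure <- i
      frontier <- i
      while (length(frontier) > 0) {
        nb <- setdiff(unlist(lapply(frontier, blocks_in)), closure)
        closure <- c(closure, nb)
        frontier <- nb
      }
      if (length(closure) <= need) {
        d[closure] <- "in_gene"
        progress <- TRUE
        need <- need - length(closure)
        if (need == 0) break
      }
    }
    if (!progress || need == 0) break
  }
  # phase 1c: near-gene quota among candidates with room for a gene
  if (n_near > 0 && window >= 1) {
    repeat {
      need <- n_near - sum(d == "near_gene")
      if (need <= 0) break
      pool <- sample(which(d == "intergenic"))
      progress <- FALSE
      for (i in pool) {
        d[i] <- "near_gene"   # tentative: its own bounds treat it as host
        if (near_sides(i)$ok) {
          progress <- TRUE
          need <- need - 1
          if (need == 0) break
        } else {
          d[i] <- "intergenic"
        }
      }
      if (!progress || need == 0) break
    }
  }

  # phase 2: draw gene intervals inside each host's feasible span
  genes <- list()
  for (i in which(d %in% c("in_gene", "near_gene"))) {
    b <- host_bounds(i)
    L <- round(runif(1, gene_length_range[1], gene_length_range[2]))
    if (d[i] == "in_gene") {
      start <- max(b[1], pos[i] - sample.int(L, 1) + 1)
      end <- min(b[2], start + L - 1)
      start <- min(start, pos[i])
      end <- max(end, pos[i])
    } else {
      ns <- near_sides(i)
      sides <- sample(c("right", "left"))
      placed <- FALSE
      for (side in sides) {
        rng <- ns[[side]]
        if (rng[1] > rng[2]) next
        if (side == "right") {
          start <- rng[1] + sample.int(rng[2] - rng[1] + 1, 1) - 1
          end <- min(start + L - 1, b[2])
        } else {
          end <- rng[1] + sample.int(rng[2] - rng[1] + 1, 1) - 1
          start <- max(end - L + 1, b[1])
        }
        placed <- TRUE
        break
      }
      if (!placed) { d[i] <- "intergenic"; next }
    }
    genes[[length(genes) + 1]] <- tibble(
      chrom = chrom[i], start = as.integer(start), end = as.integer(end),
      host_snp = map$snp_id[ord[i]]
    )
  }

  out <- bind_rows(genes)
  if (nrow(out) > 0) {
    out <- arrange(out, match(.data$chrom, unique(map$chrom)), .data$start)
    out$gene_id <- sprintf("gene_%05d", seq_len(nrow(out)))
    out$strand <- sample(c("+", "-"), nrow(out), replace = TRUE)
    out <- select(out, "gene_id", "chrom", "start", "end", "strand", "host_snp")
  } else {
    out <- tibble(
      gene_id = character(0), chrom = character(0),
      start = integer(0), end = integer(0), strand = character(0),
      host_snp = character(0)
    )
  }
  desig <- tibble(snp_id = map$snp_id[ord], designation = d)
  attr(out, "designation") <- desig[match(map$snp_id, desig$snp_id), ]
  class(out) <- c("gene_models", class(out))
  out
}

#' Simulate term-to-gene annotation sets
#'
#' Generates random functional terms of varied sizes over the simulated
#' genes, plus one planted "causal" term enriched for QTL-hosting genes, so
#' that enrichment analysis has a known positive control. Empty terms are
#' dropped.
#'
#' @param gene_models a [make_gene_models()] result.
#' @param qtl_gene_ids gene ids hosting QTL (members of the causal term).
#' @param n_terms number of random background terms (default 50).
#' @param term_size_range term sizes drawn uniformly from this range.
#' @param causal_extra how many random non-QTL genes are mixed into the
#'   causal term (default 8) so it is enriched rather than identical to
#'   the QTL set.
#' @param seed integer seed.
#' @return A named list of gene-id character vectors of class `term_sets`,
#'   with per-term descriptions in attribute `"description"`. The causal
#'   term is named `"causal_process"`.
#' @export
make_term_annotation <- function(gene_models, qtl_gene_ids = character(0),
                                 n_terms = 50,
                                 term_size_range = c(5, 80),
                                 causal_extra = 8, seed = 1) {
  if (nrow(gene_models) < 1) abort("need at least one gene")
  set.seed(stage_seed(seed, 4L))
  genes <- gene_models$gene_id
  sizes <- sample(
    seq(term_size_range[1], min(term_size_range[2], length(genes))),
    n_terms, replace = TRUE
  )
  terms <- lapply(sizes, function(s) sort(sample(genes, s)))
  names(terms) <- sprintf("term_%03d", seq_len(n_terms))
  causal <- sort(unique(c(
    intersect(qtl_gene_ids, genes),
    sample(setdiff(genes, qtl_gene_ids), min(causal_extra, length(genes)))
  )))
  terms <- c(list(causal_process = causal), terms)
  terms <- terms[lengths(terms) > 0]
  attr(terms, "description") <- setNames(
    ifelse(names(terms) == "causal_process",
           "planted causal process", "random background term"),
    names(terms)
  )
  structure(terms, class = "term_sets")
}

#' @export
print.term_sets <- function(x, ...) {
  cat(sprintf(
    "<term_sets> %d terms; sizes %d-%d\n",
    length(x), min(lengths(x)), max(lengths(x))
  ))
  invisible(x)
}
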