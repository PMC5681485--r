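#' Write genotypes as PLINK text files
#'
#' Writes whitespace-delimited `.ped`/`.map` files. Alleles are coded
#' `A`/`B` (`A` = reference/major as simulated), missing calls as `0 0`.
#'
#' @param geno a [genotypes] object.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotypes"))
  map <- geno$map
  map_df <- data.frame(
    chrom = sub("^chr", "", map$chrom), snp_id = map$snp_id,
    cm = 0, pos = map$pos
  )
  utils::write.table(map_df, paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  X <- geno$X
  a1 <- matrix("A", nrow(X), ncol(X))
  a2 <- matrix("A", nrow(X), ncol(X))
  a1[X >= 1] <- "B"
  a2[X == 2] <- "B"
  a1[is.na(X)] <- "0"
  a2[is.na(X)] <- "0"
  alleles <- matrix("", nrow(X), 2 * ncol(X))
  alleles[, seq(1, 2 * ncol(X), by = 2)] <- a1
  alleles[, seq(2, 2 * ncol(X), by = 2)] <- a2
  fam <- geno$sires %||% rep("0", nrow(X))
  ped <- cbind(fam, rownames(X), "0", "0", "0", "-9", alleles)
  utils::write.table(ped, paste0(prefix, ".ped"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " "
  )
  invisible(prefix)
}

#' Read genotypes from PLINK text files
#'
#' Counts copies of the `B` allele, so codes match [write_plink()] output;
#' `0` alleles are treated as missing.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return A [genotypes] object.
#' @export
read_plink <- function(prefix) {
  map_df <- utils::read.table(paste0(prefix, ".map"),
    col.names = c("chrom", "snp_id", "cm", "pos"),
    colClasses = c("character", "character", "numeric", "integer")
  )
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  m <- nrow(map_df)
  if (ncol(ped) != 6 + 2 * m) abort("ped/map column mismatch")
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  X <- (a1 == "B") + (a2 == "B")
  X[a1 == "0" | a2 == "0"] <- NA
  storage.mode(X) <- "integer"
  rownames(X) <- ped[[2]]
  sires <- if (any(ped[[1]] != "0")) ped[[1]] else NULL
  chrom <- ifelse(grepl("^chr", map_df$chrom), map_df$chrom,
                  paste0("chr", map_df$chrom))
  genotypes(X, tibble(snp_id = map_df$snp_id, chrom = chrom, pos = map_df$pos),
            sires = sires)
}

#' Write / read a phenotype table as TSV
#'
#' Columns: `animal_id`, `cg`, then trait columns; missing values written
#' as `NA`.
#'
#' @param phenotypes tibble as produced by [simulate_phenotypes()].
#' @param path output file.
#' @return `path` / the phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                  col_types = readr::cols(
                    animal_id = readr::col_character(),
                    cg = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Write / read gene models as GFF3
#'
#' Genes are written as `gene` features, 1-based inclusive, via
#' rtracklayer.
#'
#' @param gene_models a `gene_models` tibble.
#' @param path GFF3 file path.
#' @return `path` / a `gene_models` tibble.
#' @export
write_gff3 <- function(gene_models, path) {
  gr <- gene_models_to_granges(gene_models)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- gene_models$gene_id
  S4Vectors::mcols(gr)$source <- "awmnet"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "gene"]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- sprintf("gene_%05d", seq_along(gr))
  out <- tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  class(out) <- c("gene_models", class(out))
  out
}

gene_models_to_granges <- function(gene_models) {
  GenomicRanges::GRanges(
    seqnames = gene_models$chrom,
    ranges = IRanges::IRanges(start = gene_models$start, end = gene_models$end),
    strand = ifelse(gene_models$strand %in% c("+", "-"), gene_models$strand, "*"),
    gene_id = gene_models$gene_id
  )
}

#' Write / read gene sets in GMT format
#'
#' One term per line: term id, description, then tab-separated gene ids.
#'
#' @param terms a named list of gene-id vectors (`term_sets`).
#' @param path GMT file path.
#' @return `path` / a `term_sets` list.
#' @export
write_gmt <- function(terms, path) {
  desc <- attr(terms, "description") %||%
    setNames(rep("na", length(terms)), names(terms))
  lines <- vapply(names(terms), function(nm) {
    paste(c(nm, desc[[nm]], terms[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- vapply(parts, `[`, character(1), 1)
  terms <- terms[lengths(terms) > 0]
  attr(terms, "description") <- setNames(
    vapply(parts, `[`, character(1), 2)[match(names(terms),
      vapply(parts, `[`, character(1), 1))],
    names(terms)
  )
  structure(terms, class = "term_sets")
}

#' Write a GRM as TSV
#'
#' Writes either the full symmetric matrix with ids, or a GCTA-style
#' lower-triangle text file (`id1 id2 n_snps relationship`).
#'
#' @param grm a `grm` object.
#' @param path output file.
#' @param format `"matrix"` or `"gcta"`.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path, format = c("matrix", "gcta")) {
  format <- match.arg(format)
  if (format == "matrix") {
    df <- as.data.frame(grm$K)
    names(df) <- grm$ids
    readr::write_tsv(dplyr::bind_cols(tibble(id = grm$ids), df), path)
  } else {
    lt <- which(lower.tri(grm$K, diag = TRUE), arr.ind = TRUE)
    readr::write_tsv(
      tibble(
        id1 = grm$ids[lt[, 1]], id2 = grm$ids[lt[, 2]],
        n_snps = grm$n_snps_used, relationship = grm$K[lt]
      ),
      path, col_names = FALSE
    )
  }
  invisible(path)
}
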