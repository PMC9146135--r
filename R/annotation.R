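# Genome annotation container: genes with coordinates and Pfam hits,
# grouped into biosynthetic gene clusters, plus the proteome.

CLUSTER_TYPES <- c("T1PKS", "T3PKS", "NRPS", "hybrid", "terpene", "other")

#' Construct a genome annotation
#'
#' @param genome Genome identifier.
#' @param genes Tibble with columns `gene_id`, `contig`, `start`, `end`
#'   (1-based closed coordinates), `strand` (`+`/`-`), `pfam`
#'   (comma-separated Pfam accessions or `NA`), `domains` (hyphen-delimited
#'   PKS domain architecture or `NA`), `product`, `cluster_id`.
#' @param clusters Tibble with columns `cluster_id`, `type_label` (one of
#'   T1PKS, T3PKS, NRPS, hybrid, terpene, other), `core_gene_ids`
#'   (comma-separated gene ids).
#' @param proteome Named character vector of amino-acid sequences; every
#'   core gene must have one.
#' @return A `genome_annotation` list.
#' @export
genome_annotation <- function(genome, genes, clusters, proteome) {
  stopifnot(is.character(genome), length(genome) == 1)
  needed <- c("gene_id", "contig", "start", "end", "strand", "pfam",
              "domains", "product", "cluster_id")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols) > 0) {
    abort(sprintf("genes table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$gene_id[genes$start > genes$end]
    abort(sprintf("coordinate error (end < start) for gene(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  clusters$type_label <- ifelse(clusters$type_label %in% CLUSTER_TYPES,
                                clusters$type_label, "other")
  cores <- unlist(strsplit(clusters$core_gene_ids, ",", fixed = TRUE))
  missing_genes <- setdiff(cores, genes$gene_id)
  if (length(missing_genes) > 0) {
    abort(sprintf("cluster table names missing gene id(s): %s",
                  paste(missing_genes, collapse = ", ")))
  }
  orphan <- setdiff(stats::na.omit(genes$cluster_id), clusters$cluster_id)
  if (length(orphan) > 0) {
    abort(sprintf("genes reference unknown cluster id(s): %s",
                  paste(orphan, collapse = ", ")))
  }
  missing_prot <- setdiff(cores, names(proteome))
  if (length(missing_prot) > 0) {
    abort(sprintf("core gene(s) without protein sequence: %s",
                  paste(missing_prot, collapse = ", ")))
  }
  genes <- dplyr::arrange(genes, .data$contig, .data$start)
  structure(
    list(genome = genome, genes = as_tibble(genes),
         clusters = as_tibble(clusters), proteome = proteome),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation '%s': %d genes, %d clusters, %d proteins>\n",
              x$genome, nrow(x$genes), nrow(x$clusters), length(x$proteome)))
  invisible(x)
}

#' Extract one biosynthetic gene cluster
#'
#' @param annot A [genome_annotation()].
#' @param cluster_id Cluster identifier.
#' @return A `bgc` list: `id`, `genome`, `type_label`, `genes` (tibble
#'   ordered by start), `core_gene_ids`, `proteins` (named vector of the
#'   member sequences present in the proteome).
#' @export
get_bgc <- function(annot, cluster_id) {
  row <- annot$clusters[annot$clusters$cluster_id == cluster_id, ]
  if (nrow(row) != 1) abort(sprintf("unknown cluster id: %s", cluster_id))
  genes <- annot$genes[!is.na(annot$genes$cluster_id) &
                         annot$genes$cluster_id == cluster_id, ]
  genes <- dplyr::arrange(genes, .data$start)
  ids <- intersect(genes$gene_id, names(annot$proteome))
  structure(
    list(id = cluster_id, genome = annot$genome,
         type_label = row$type_label,
         genes = genes,
         core_gene_ids = strsplit(row$core_gene_ids, ",", fixed = TRUE)[[1]],
         proteins = annot$proteome[ids]),
    class = "bgc"
  )
}

#' Architectures of the T1PKS core genes of an annotation
#'
#' Convenience extractor feeding [classify_architectures()]: one row per
#' T1PKS cluster core gene that carries a domain architecture.
#'
#' @param annot A [genome_annotation()].
#' @return Tibble with columns `gene_id`, `architecture`, `cluster_id`.
#' @export
core_architectures <- function(annot) {
  t1 <- annot$clusters[annot$clusters$type_label == "T1PKS", ]
  purrr::map_dfr(t1$cluster_id, function(cid) {
    cores <- strsplit(t1$core_gene_ids[t1$cluster_id == cid], ",",
                      fixed = TRUE)[[1]]
    g <- annot$genes[annot$genes$gene_id %in% cores, ]
    tibble(gene_id = g$gene_id, architecture = g$domains, cluster_id = cid)
  })
}
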