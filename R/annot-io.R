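# Readers and writers for the per-genome annotation bundle:
# proteins.faa (FASTA), genes.gff3 (GFF3 with Pfam/cluster_id/domains
# attributes), clusters.tsv, plus the census table. antiSMASH-style region
# records are supported through conversion to the clusters.tsv dialect;
# the readers reject malformed records instead of repairing them, and all
# writer/reader pairs round-trip to equality.

format_gff_attr <- function(id, cluster_id, pfam, domains, product) {
  parts <- c(sprintf("ID=%s", id))
  if (!is.na(cluster_id)) parts <- c(parts, sprintf("cluster_id=%s", cluster_id))
  if (!is.na(pfam)) parts <- c(parts, sprintf("Pfam=%s", pfam))
  if (!is.na(domains)) parts <- c(parts, sprintf("domains=%s", domains))
  if (!is.na(product)) parts <- c(parts, sprintf("product=%s", product))
  paste(parts, collapse = ";")
}

parse_gff_attr <- function(text, field) {
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  out <- vals[match(field, keys)]
  unname(out)
}

#' Write a genome annotation bundle
#'
#' Writes `proteins.faa`, `genes.gff3` and `clusters.tsv` into `dir`.
#' Output is deterministic: identical annotations produce byte-identical
#' files.
#'
#' @param annot A [genome_annotation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotation <- function(annot, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(annot$proteome),
    file.path(dir, "proteins.faa")
  )
  g <- annot$genes
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tlichenpks\tgene\t%d\t%d\t.\t%s\t.\t%s",
            g$contig, g$start, g$end, g$strand,
            mapply(format_gff_attr, g$gene_id, g$cluster_id, g$pfam,
                   g$domains, g$product))
  )
  writeLines(lines, file.path(dir, "genes.gff3"))
  cl <- tibble(
    cluster_id = annot$clusters$cluster_id,
    genome = annot$genome,
    type_label = annot$clusters$type_label,
    core_gene_ids = annot$clusters$core_gene_ids
  )
  readr::write_tsv(cl, file.path(dir, "clusters.tsv"))
  invisible(dir)
}

#' Read a genome annotation bundle
#'
#' Reads the `proteins.faa` + `genes.gff3` + `clusters.tsv` bundle written
#' by [write_annotation()] (or converted from other annotation pipelines).
#' Genes are joined to clusters by the `cluster_id` GFF3 attribute; cluster
#' types outside the recognised vocabulary map to `"other"`. Malformed
#' GFF3 records raise an error naming the offending line; core genes
#' without a protein sequence raise an error listing the ids.
#'
#' @param dir Directory containing the three files, or `NULL` when the
#'   three paths are given explicitly.
#' @param proteins,gff3,clusters Explicit file paths (default the standard
#'   names inside `dir`).
#' @param genome Genome id; defaults to the (unique) genome column of
#'   `clusters.tsv`, falling back to the directory name.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(dir = NULL,
                            proteins = file.path(dir, "proteins.faa"),
                            gff3 = file.path(dir, "genes.gff3"),
                            clusters = file.path(dir, "clusters.tsv"),
                            genome = NULL) {
  for (p in c(proteins, gff3, clusters)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  seqs <- Biostrings::readAAStringSet(proteins)
  proteome <- setNames(as.character(seqs), sub(" .*", "", names(seqs)))

  lines <- readLines(gff3)
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  rows <- purrr::map_dfr(data_idx, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9) {
      abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                    i, length(fields)))
    }
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("malformed GFF3 line %d: non-numeric coordinates", i))
    }
    if (end < start) {
      abort(sprintf("coordinate error at GFF3 line %d: end (%d) < start (%d)",
                    i, end, start))
    }
    if (!fields[7] %in% c("+", "-")) {
      abort(sprintf("malformed GFF3 line %d: strand must be + or -", i))
    }
    id <- parse_gff_attr(fields[9], "ID")
    if (is.na(id)) abort(sprintf("malformed GFF3 line %d: missing ID attribute", i))
    tibble(
      gene_id = id, contig = fields[1], start = start, end = end,
      strand = fields[7],
      pfam = parse_gff_attr(fields[9], "Pfam"),
      domains = parse_gff_attr(fields[9], "domains"),
      product = parse_gff_attr(fields[9], "product"),
      cluster_id = parse_gff_attr(fields[9], "cluster_id")
    )
  })

  cl <- readr::read_tsv(clusters, col_types = "cccc")
  needed <- c("cluster_id", "genome", "type_label", "core_gene_ids")
  if (!all(needed %in% names(cl))) {
    abort(sprintf("clusters table needs columns: %s",
                  paste(needed, collapse = ", ")))
  }
  gid <- genome %||% (if (length(unique(cl$genome)) == 1) cl$genome[1]
                      else basename(dirname(clusters)))
  genome_annotation(
    genome = gid,
    genes = rows,
    clusters = cl[, c("cluster_id", "type_label", "core_gene_ids")],
    proteome = proteome
  )
}

#' Write / read a census table
#'
#' Stable column order: genome, clusters, t1_total, nr, r, pr, hybrid,
#' nrps. An empty table writes a header-only file; write-then-read
#' round-trips to the same table.
#'
#' @param table Census tibble (rows as from [census_genome()] or
#'   [census_fixture()]).
#' @param path Output path.
#' @return For the writer, `path` invisibly; for the reader, the tibble.
#' @export
write_census <- function(table, path) {
  cols <- c("genome", "clusters", "t1_total", "nr", "r", "pr", "hybrid", "nrps")
  out <- as_tibble(table)[, cols]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_census
#' @export
read_census <- function(path) {
  out <- readr::read_tsv(path, col_types = "ciiiiiii")
  class(out) <- c("census_table", class(out))
  out
}
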