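# Per-genome biosynthetic gene cluster censuses and their aggregates.

#' Census one genome's biosynthetic gene clusters
#'
#' Counts clusters by type label; `t1_total` counts T1PKS clusters, and the
#' `nr`/`r`/`pr` columns count the reducing classes of their core genes'
#' classifications. Every T1PKS core must have a classification row.
#'
#' @param annot A [genome_annotation()].
#' @param classifications Tibble from [classify_architectures()] (keyed by
#'   `gene_id`, column `reduction`); defaults to classifying the
#'   annotation's own core architectures.
#' @return One-row census tibble: `genome`, `clusters`, `t1_total`, `nr`,
#'   `r`, `pr`, `hybrid`, `nrps`.
#' @export
census_genome <- function(annot,
                          classifications =
                            classify_architectures(core_architectures(annot))) {
  cl <- annot$clusters
  t1 <- cl[cl$type_label == "T1PKS", ]
  cores <- unlist(strsplit(t1$core_gene_ids, ",", fixed = TRUE))
  missing <- setdiff(cores, classifications$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("T1PKS core(s) without classification: %s",
                  paste(missing, collapse = ", ")))
  }
  red <- classifications$reduction[match(cores, classifications$gene_id)]
  out <- tibble(
    genome = annot$genome,
    clusters = nrow(cl),
    t1_total = nrow(t1),
    nr = sum(red == "NR"),
    r = sum(red == "R"),
    pr = sum(red == "PR"),
    hybrid = sum(cl$type_label == "hybrid"),
    nrps = sum(cl$type_label == "NRPS")
  )
  class(out) <- c("census_table", class(out))
  out
}

#' Aggregate a census table
#'
#' Sums Type I PKS counts, expresses the reducing-class breakdown as
#' percentages of the TI-PKS total (half-up rounding to 2 decimals), and
#' reports the mean cluster count per genome (rounded to the nearest
#' integer) together with the extreme genomes. Ties on the extremes go to
#' the lexicographically first genome and are flagged.
#'
#' @param rows Census tibble with >= 1 row (e.g. [census_fixture()] or
#'   stacked [census_genome()] results).
#' @return One-row tibble: `n_genomes`, `total_t1`, `pct_nr`, `pct_r`,
#'   `pct_pr` (NA when `total_t1` is 0), `mean_clusters`, `min_clusters`,
#'   `min_clusters_genome`, `max_clusters`, `max_clusters_genome`,
#'   `max_t1`, `max_t1_genome`, `ties` (logical).
#' @examples
#' aggregate_census(census_fixture())
#' @export
aggregate_census <- function(rows) {
  if (nrow(rows) < 1) abort("need at least one census row")
  total_t1 <- sum(rows$t1_total)
  pct <- function(x) {
    if (total_t1 == 0) return(NA_real_)
    round_half_up(100 * sum(x) / total_t1, 2)
  }
  argmin <- rows$genome[order(rows$clusters, rows$genome)][1]
  argmax <- rows$genome[order(-rows$clusters, rows$genome)][1]
  argmax_t1 <- rows$genome[order(-rows$t1_total, rows$genome)][1]
  ties <- sum(rows$clusters == min(rows$clusters)) > 1 ||
    sum(rows$clusters == max(rows$clusters)) > 1 ||
    sum(rows$t1_total == max(rows$t1_total)) > 1
  tibble(
    n_genomes = nrow(rows),
    total_t1 = total_t1,
    pct_nr = pct(rows$nr),
    pct_r = pct(rows$r),
    pct_pr = pct(rows$pr),
    mean_clusters = as.integer(round_half_up(mean(rows$clusters))),
    min_clusters = min(rows$clusters),
    min_clusters_genome = argmin,
    max_clusters = max(rows$clusters),
    max_clusters_genome = argmax,
    max_t1 = max(rows$t1_total),
    max_t1_genome = argmax_t1,
    ties = ties
  )
}

#' @method glance census_table
#' @export
glance.census_table <- function(x, ...) {
  aggregate_census(x)
}

#' Stacked per-class census bar chart
#'
#' @param census Census tibble with `genome`, `nr`, `r`, `pr` columns.
#' @return A ggplot object.
#' @export
plot_census <- function(census) {
  long <- tidyr::pivot_longer(
    as_tibble(census)[, c("genome", "nr", "r", "pr")],
    -"genome", names_to = "class", values_to = "count"
  )
  long$class <- factor(toupper(long$class), levels = c("NR", "R", "PR"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genome, y = .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "TI-PKS genes", fill = "class") +
    ggplot2::theme_minimal()
}
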