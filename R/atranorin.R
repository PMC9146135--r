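# The atranorin-cluster screen and pairwise cluster comparison.
#
# An atranorin-like cluster couples a PKS23-like core with a cytochrome
# P450 (PF00067), an O-methyltransferase (PF08241) and a transporter gene.
# The transporter's Pfam evidence is configurable: published descriptions
# of the cluster disagree on whether the transporter is the MFS family
# (PF07690) or the WD-40 accession (PF00400), so the screen supports
# either, both by default, and records which policy was used.

#' Transporter Pfam policy for the atranorin screen
#'
#' @param policy `"either"` (accept PF07690 or PF00400, default),
#'   `"PF07690"` (MFS only) or `"PF00400"` (WD-40 only).
#' @return Character vector of acceptable transporter accessions.
#' @export
transporter_pfams <- function(policy = c("either", "PF07690", "PF00400")) {
  policy <- match.arg(policy)
  switch(policy,
         either = c(PFAM_MFS, PFAM_WD40),
         PF07690 = PFAM_MFS,
         PF00400 = PFAM_WD40)
}

has_pfam <- function(pfam_column, accessions) {
  hits <- strsplit(ifelse(is.na(pfam_column), "", pfam_column), ",",
                   fixed = TRUE)
  any(vapply(hits, function(h) any(h %in% accessions), TRUE))
}

#' Screen a cluster for an atranorin-like composition
#'
#' The cluster's core protein is aligned locally against a PKS23 reference
#' and must pass the ortholog screen thresholds; the cluster must
#' additionally contain, among its non-core genes, a cytochrome P450
#' (PF00067), an O-methyltransferase (PF08241) and a transporter gene
#' (accessions per `pfam_policy`). The verdict is the conjunction of all
#' four conditions, so removing any required gene can only flip a positive
#' verdict to negative, never the reverse.
#'
#' @param bgc A `bgc` (see [get_bgc()]) of type T1PKS.
#' @param reference Named character vector with the PKS23 reference
#'   protein (default the packaged synthetic stand-in).
#' @param params A [screen_params()] applied to the core hit.
#' @param pfam_policy Transporter evidence policy (see
#'   [transporter_pfams()]).
#' @param scheme A [scoring_scheme()].
#' @return One-row tibble: `cluster_id`, `genome`, `core_gene`,
#'   `core_identity`, `core_coverage`, `core_score`, `has_p450`,
#'   `has_omt`, `has_transporter`, `verdict`, `pfam_policy`.
#' @export
screen_atranorin <- function(bgc, reference = pks23_reference(),
                             params = screen_params(),
                             pfam_policy = "either",
                             scheme = scoring_scheme()) {
  if (bgc$type_label != "T1PKS") abort("atranorin screen expects a T1PKS cluster")
  core_id <- bgc$core_gene_ids[1]
  if (!core_id %in% names(bgc$proteins)) {
    abort(sprintf("missing core protein: %s", core_id))
  }
  hit <- align_pair(setNames(bgc$proteins[core_id], core_id), reference,
                    scheme)
  core_pass <- !hit$no_hit &&
    hit$identity >= params$min_identity &&
    hit$coverage >= params$min_coverage
  accessory <- bgc$genes[!(bgc$genes$gene_id %in% bgc$core_gene_ids), ]
  acc <- transporter_pfams(pfam_policy)
  has_p450 <- has_pfam(accessory$pfam, PFAM_P450)
  has_omt <- has_pfam(accessory$pfam, PFAM_OMT)
  has_transporter <- has_pfam(accessory$pfam, acc)
  tibble(
    cluster_id = bgc$id,
    genome = bgc$genome,
    core_gene = core_id,
    core_identity = hit$identity,
    core_coverage = hit$coverage,
    core_score = hit$score,
    has_p450 = has_p450,
    has_omt = has_omt,
    has_transporter = has_transporter,
    verdict = core_pass && has_p450 && has_omt && has_transporter,
    pfam_policy = pfam_policy
  )
}

#' Screen every T1PKS cluster of a genome (or bundle)
#'
#' @param annot A [genome_annotation()].
#' @inheritParams screen_atranorin
#' @return Tibble with one row per T1PKS cluster.
#' @export
screen_atranorin_genome <- function(annot, reference = pks23_reference(),
                                    params = screen_params(),
                                    pfam_policy = "either",
                                    scheme = scoring_scheme()) {
  t1 <- annot$clusters$cluster_id[annot$clusters$type_label == "T1PKS"]
  purrr::map_dfr(t1, function(cid) {
    screen_atranorin(get_bgc(annot, cid), reference, params, pfam_policy,
                     scheme)
  })
}

#' Compare two gene clusters by reciprocal best hits
#'
#' Genes of the two clusters are matched by reciprocal best local
#' alignment score (score ties broken by the smallest positional offset,
#' so arrow plots are deterministic); the output lists matched pairs with
#' their identities and the unmatched genes of either cluster, in gene
#' order, ready for gene-arrow plotting. Swapping the two clusters
#' transposes the match set.
#'
#' @param a,b `bgc` objects (see [get_bgc()]).
#' @param scheme A [scoring_scheme()].
#' @return Tibble: `gene_a`, `gene_b` (NA when unmatched), `identity`,
#'   `score`, `strand_a`, `strand_b`, `position_a`, `position_b`.
#' @export
compare_clusters <- function(a, b, scheme = scoring_scheme()) {
  ga <- a$genes[a$genes$gene_id %in% names(a$proteins), ]
  gb <- b$genes[b$genes$gene_id %in% names(b$proteins), ]
  if (nrow(ga) == 0 || nrow(gb) == 0) {
    abort("both clusters need protein sequences for their genes")
  }
  score_mat <- matrix(0, nrow(ga), nrow(gb),
                      dimnames = list(ga$gene_id, gb$gene_id))
  ident_mat <- score_mat
  for (i in seq_len(nrow(ga))) {
    hits <- align_query(a$proteins[[ga$gene_id[i]]],
                        setNames(b$proteins[gb$gene_id], gb$gene_id), scheme)
    score_mat[i, ] <- hits$score
    ident_mat[i, ] <- ifelse(hits$no_hit, 0, hits$identity)
  }
  pos_a <- seq_len(nrow(ga))
  pos_b <- seq_len(nrow(gb))
  offset <- abs(outer(pos_a, pos_b, "-"))
  best_b_for_a <- vapply(seq_len(nrow(ga)), function(i) {
    s <- score_mat[i, ]
    cand <- which(s == max(s) & s > 0)
    if (length(cand) == 0) return(NA_integer_)
    cand[order(offset[i, cand], cand)][1]
  }, integer(1))
  best_a_for_b <- vapply(seq_len(nrow(gb)), function(j) {
    s <- score_mat[, j]
    cand <- which(s == max(s) & s > 0)
    if (length(cand) == 0) return(NA_integer_)
    cand[order(offset[cand, j], cand)][1]
  }, integer(1))
  matched_b <- integer(nrow(ga))
  for (i in seq_len(nrow(ga))) {
    j <- best_b_for_a[i]
    matched_b[i] <- if (!is.na(j) && !is.na(best_a_for_b[j]) &&
                        best_a_for_b[j] == i) j else NA_integer_
  }
  rows_a <- tibble(
    gene_a = ga$gene_id,
    gene_b = ifelse(is.na(matched_b), NA_character_, gb$gene_id[matched_b]),
    identity = ifelse(is.na(matched_b), NA_real_,
                      ident_mat[cbind(seq_len(nrow(ga)), matched_b)]),
    score = ifelse(is.na(matched_b), NA_real_,
                   score_mat[cbind(seq_len(nrow(ga)), matched_b)]),
    strand_a = ga$strand,
    strand_b = ifelse(is.na(matched_b), NA_character_,
                      gb$strand[matched_b]),
    position_a = pos_a,
    position_b = ifelse(is.na(matched_b), NA_integer_, matched_b)
  )
  unmatched_b <- setdiff(pos_b, stats::na.omit(matched_b))
  rows_b <- tibble(
    gene_a = NA_character_,
    gene_b = gb$gene_id[unmatched_b],
    identity = NA_real_, score = NA_real_,
    strand_a = NA_character_, strand_b = gb$strand[unmatched_b],
    position_a = NA_integer_, position_b = unmatched_b
  )
  out <- dplyr::bind_rows(rows_a, rows_b)
  attr(out, "cluster_a") <- a$id
  attr(out, "cluster_b") <- b$id
  class(out) <- c("cluster_comparison", class(out))
  out
}

#' Gene-arrow plot of a cluster comparison
#'
#' Draws the two clusters as rows of strand-oriented arrows with
#' connecting ribbons between matched genes, shaded by percent identity.
#'
#' @param comparison Output of [compare_clusters()].
#' @return A ggplot object.
#' @export
plot_gene_arrows <- function(comparison) {
  x <- as_tibble(comparison)
  arrows <- dplyr::bind_rows(
    tibble(cluster = attr(comparison, "cluster_a") %||% "A",
           gene = x$gene_a, pos = x$position_a, strand = x$strand_a,
           y = 1),
    tibble(cluster = attr(comparison, "cluster_b") %||% "B",
           gene = x$gene_b, pos = x$position_b, strand = x$strand_b,
           y = 0)
  ) |> dplyr::filter(!is.na(.data$gene))
  links <- dplyr::filter(x, !is.na(.data$gene_a) & !is.na(.data$gene_b))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = links,
      ggplot2::aes(x = .data$position_a, xend = .data$position_b,
                   y = 0.92, yend = 0.08, alpha = .data$identity),
      linewidth = 2, colour = "grey40"
    ) +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = .data$pos - 0.35, xend = .data$pos + 0.35,
                   y = .data$y, yend = .data$y, colour = .data$strand),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "inches")),
      linewidth = 3
    ) +
    ggplot2::geom_text(
      data = arrows,
      ggplot2::aes(x = .data$pos, y = .data$y + 0.12, label = .data$gene),
      size = 2.6
    ) +
    ggplot2::scale_y_continuous(
      breaks = c(0, 1),
      labels = c(attr(comparison, "cluster_b") %||% "B",
                 attr(comparison, "cluster_a") %||% "A"),
      limits = c(-0.2, 1.25)) +
    ggplot2::labs(x = "gene order", y = NULL, alpha = "% identity",
                  colour = "strand") +
    ggplot2::theme_minimal()
}
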