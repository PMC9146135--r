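# Pairwise protein homology and orthogroup inference.
#
# The ortholog screen mirrors a BLASTP-style workflow: optimal local
# alignment with an affine gap penalty, hits filtered by percent identity
# over the alignment length and by query coverage, survivors ranked by raw
# alignment score. E-values are deliberately not computed: Karlin-Altschul
# calibration adds a dependence on database size without changing any
# decision here, because the screen thresholds are identity and coverage.
# Orthogroups are then read off a similarity graph with a Markov Cluster
# (MCL) implementation.

#' Scoring scheme for local protein alignment
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`), or a symmetric 20x20 numeric matrix.
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`. Defaults mirror common BLASTP
#'   settings (11/1 with BLOSUM62).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (is.character(matrix)) {
    mat <- get(data(list = matrix, package = "Biostrings",
                    envir = environment()))
  } else {
    mat <- matrix
  }
  aas <- aa_alphabet()
  mat <- mat[aas, aas]
  if (!isSymmetric(unname(mat))) abort("substitution matrix must be symmetric")
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be positive")
  structure(list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

# One query against a set of subjects in a single vectorised call.
# Returns a tibble of hits in subject order.
align_query <- function(query, subjects, scheme) {
  check_aa(query, "query")
  check_aa(subjects, "subject")
  qlen <- nchar(query)
  als <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(subjects),
    subject = Biostrings::AAString(query),
    type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend
  )
  score <- Biostrings::score(als)
  len <- Biostrings::nchar(als)
  nmat <- Biostrings::nmatch(als)
  # "subject" of the call is the query protein: its aligned span gives
  # query coverage
  qspan <- BiocGenerics::width(Biostrings::subject(als))
  no_hit <- score <= 0 | len == 0
  tibble(
    query = rep(NA_character_, length(subjects)),
    subject = names(subjects) %||% as.character(seq_along(subjects)),
    align_length = ifelse(no_hit, 0L, len),
    identity = ifelse(no_hit, NA_real_, 100 * nmat / len),
    coverage = ifelse(no_hit, NA_real_, 100 * qspan / qlen),
    score = pmax(score, 0),
    no_hit = no_hit
  )
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman local alignment with affine gaps under the supplied
#' scoring scheme. Identity is matches over alignment columns (gaps
#' included in the denominator); coverage is aligned query residues over
#' query length. When no positively scoring local alignment exists the hit
#' is flagged `no_hit` with score 0.
#'
#' @param a,b Amino-acid sequences (query and subject). Named values
#'   propagate into the `query`/`subject` columns.
#' @param scheme A [scoring_scheme()].
#' @return One-row tibble: `query`, `subject`, `align_length`, `identity`,
#'   `coverage`, `score`, `no_hit`.
#' @examples
#' align_pair(c(p1 = "MKVLAW"), c(p2 = "MKVLAW"))
#' @export
align_pair <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(length(a) == 1, length(b) == 1, nzchar(a), nzchar(b))
  hit <- align_query(a, setNames(as.character(b), names(b) %||% "subject"),
                     scheme)
  hit$query <- names(a) %||% "query"
  hit
}

#' Screen a protein database for orthologs of a query
#'
#' Hits failing the identity or coverage thresholds are removed; survivors
#' are ranked by raw alignment score (descending), ties broken by identity
#' then subject id.
#'
#' @param query Single named amino-acid sequence.
#' @param database Named character vector of subject proteins.
#' @param params A [screen_params()].
#' @param scheme A [scoring_scheme()].
#' @return Tibble of passing hits, best first.
#' @export
screen_orthologs <- function(query, database, params = screen_params(),
                             scheme = scoring_scheme()) {
  if (length(database) == 0) {
    return(align_query("A", c(x = "A"), scheme)[0, ])
  }
  hits <- align_query(query, database, scheme)
  hits$query <- names(query) %||% "query"
  hits <- dplyr::filter(
    hits, !.data$no_hit,
    .data$identity >= params$min_identity,
    .data$coverage >= params$min_coverage
  )
  dplyr::arrange(hits, dplyr::desc(.data$score), dplyr::desc(.data$identity),
                 .data$subject)
}

#' Ortholog screen thresholds
#'
#' @param min_identity Minimum percent identity over the alignment length
#'   (default 30).
#' @param min_coverage Minimum percent query coverage (default 50).
#' @return A `screen_params` list.
#' @export
screen_params <- function(min_identity = 30, min_coverage = 50) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100)
  structure(list(min_identity = min_identity, min_coverage = min_coverage),
            class = "screen_params")
}

#' All-vs-all ortholog hits for a protein set
#'
#' Runs the ortholog screen of every protein against every other (self
#' pairs excluded) and returns the directed hit table used to build the
#' similarity graph.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @inheritParams screen_orthologs
#' @return Tibble of directed hits passing the screen.
#' @export
all_vs_all_hits <- function(proteins, params = screen_params(),
                            scheme = scoring_scheme()) {
  stopifnot(!is.null(names(proteins)), !anyDuplicated(names(proteins)))
  purrr::map_dfr(names(proteins), function(q) {
    db <- proteins[setdiff(names(proteins), q)]
    if (length(db) == 0) return(NULL)
    screen_orthologs(setNames(proteins[[q]], q), db, params, scheme)
  })
}

#' Build a protein similarity graph from directed hits
#'
#' Nodes are all supplied proteins, including those with no passing hit.
#' Each unordered pair's edge weight is the mean of its two directed scores
#' (a missing direction counts as 0), normalised to `[0, 1]` by the maximum
#' observed score.
#'
#' @param hits Directed hit tibble from [all_vs_all_hits()].
#' @param proteins Character vector of all protein ids (or a named sequence
#'   vector, whose names are used).
#' @return An undirected weighted [igraph::graph] object.
#' @export
build_graph <- function(hits, proteins) {
  ids <- if (!is.null(names(proteins))) names(proteins) else as.character(proteins)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(hits) == 0) return(g)
  sym <- hits |>
    dplyr::mutate(
      a = pmin(.data$query, .data$subject),
      b = pmax(.data$query, .data$subject)
    ) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(weight = sum(.data$score) / 2, .groups = "drop")
  sym$weight <- sym$weight / max(sym$weight)
  igraph::add_edges(g, rbind(sym$a, sym$b), weight = sym$weight)
}

#' Markov clustering of a similarity graph
#'
#' A from-scratch Markov Cluster (MCL) implementation. Self-loops are added
#' with weight equal to each node's maximum incident edge weight (1 for
#' isolated nodes), the adjacency matrix is column-normalised, and
#' expansion (matrix power) alternates with inflation (entrywise power
#' followed by column renormalisation) until the matrix changes by less
#' than `tol` or `max_iter` is reached (non-convergence yields a warning
#' and clusters are read from the final matrix). Clusters are the connected
#' components of the converged flow matrix, which for a converged MCL run
#' coincide with its attractor systems; the result is a partition of the
#' nodes.
#'
#' @param graph Undirected weighted [igraph::graph] (from [build_graph()]).
#' @param inflation Inflation exponent, must exceed 1 (default 1.5).
#' @param expansion Expansion power (default 2).
#' @param max_iter,tol Iteration controls.
#' @return Tibble with columns `orthogroup`, `member`; orthogroups are
#'   numbered in order of their first member.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, expansion = 2,
                        max_iter = 200, tol = 1e-6) {
  if (inflation <= 1) abort("inflation must exceed 1")
  n <- igraph::vcount(graph)
  ids <- igraph::vertex_attr(graph, "name") %||% as.character(seq_len(n))
  A <- igraph::as_adjacency_matrix(graph, attr = if (igraph::ecount(graph) > 0)
    "weight" else NULL, sparse = FALSE)
  A <- (A + t(A)) / 2
  loop <- apply(A, 1, max)
  diag(A) <- ifelse(loop > 0, loop, 1)
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (k in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf <- sweep(Minf, 2, colSums(Minf), "/")
    Minf[Minf < 1e-12] <- 0
    Minf <- sweep(Minf, 2, colSums(Minf), "/")
    if (max(abs(Minf - M)) < tol) {
      M <- Minf
      converged <- TRUE
      break
    }
    M <- Minf
  }
  if (!converged) warn("MCL did not converge; clustering the final matrix")
  support <- (M > 1e-8) | t(M > 1e-8)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  )$membership
  # renumber clusters by first appearance for determinism
  relabel <- match(comp, unique(comp))
  tibble(orthogroup = sprintf("OG%04d", relabel), member = ids) |>
    dplyr::arrange(.data$orthogroup, .data$member)
}

#' Infer orthogroups for a protein set
#'
#' Convenience pipeline: all-vs-all ortholog screen, similarity graph,
#' Markov clustering.
#'
#' @inheritParams all_vs_all_hits
#' @param inflation MCL inflation parameter (default 1.5).
#' @return Tibble with columns `orthogroup`, `member`.
#' @export
infer_orthogroups <- function(proteins, params = screen_params(),
                              scheme = scoring_scheme(), inflation = 1.5) {
  hits <- all_vs_all_hits(proteins, params, scheme)
  mcl_cluster(build_graph(hits, proteins), inflation = inflation)
}
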