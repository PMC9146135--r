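# Domain-architecture grammars for iterative Type I PKS classification.
#
# A TI-PKS protein is modelled as an ordered sequence of domain tokens
# (KS, AT, ACP, ...). Named PKS groups are described by linear grammars in
# which each element is either mandatory or optional and may offer
# alternative tokens ("[TE|ADH|NAD]"). An architecture belongs to a group
# when it is an exact expansion of the group's grammar: every optional
# element taken 0 or 1 times, order preserved, no extra tokens.

#' Closed alphabet of PKS domain tokens
#'
#' The recognised domains: SAT (starter unit-ACP transacylase), KS (ketoacyl
#' synthase), AT (acyltransferase), DH (dehydratase), ER (enoyl reductase),
#' KR (ketoreductase), ACP (acyl carrier protein), CMeT (methyltransferase),
#' TE (thioesterase), HTH (helix-turn-helix), ADH (adhydrolase), NAD
#' (NAD-binding), PeptidaseS9 (peptidase S9), and Carn (choline/carnitine
#' O-acyltransferase).
#'
#' @return Character vector of legal tokens.
#' @export
domain_tokens <- function() {
  c("SAT", "KS", "AT", "DH", "ER", "KR", "ACP", "CMeT", "TE",
    "HTH", "ADH", "NAD", "PeptidaseS9", "Carn")
}

#' Parse a hyphen-delimited domain architecture
#'
#' Concrete architectures list the domains actually present in a protein,
#' e.g. `"KS-AT-DH-CMeT-ER-KR-ACP-Carn"`. Bracketed (optional) elements are
#' only legal in grammar *patterns*, not in concrete architectures.
#'
#' @param text Non-empty architecture string, tokens separated by `-`.
#' @param permissive If `TRUE`, unknown tokens are kept as opaque tokens that
#'   will fail every grammar instead of raising an error. Real annotations
#'   often carry extra domains; permissive mode lets them through the parser
#'   while keeping classification strict.
#' @return Character vector of tokens (class `domain_architecture`).
#' @examples
#' parse_architecture("KS-AT-KR-ACP")
#' @export
parse_architecture <- function(text, permissive = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) abort("empty architecture string")
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (any(grepl("[][]", tokens))) {
    abort("bracketed tokens are only legal in grammar patterns, not in concrete architectures")
  }
  unknown <- setdiff(tokens, domain_tokens())
  if (length(unknown) > 0 && !permissive) {
    abort(sprintf("unknown domain token(s): %s", paste(unknown, collapse = ", ")))
  }
  structure(tokens, class = "domain_architecture")
}

#' Parse a grammar pattern string
#'
#' Patterns use `[X]` for an optional element and `X|Y` for alternatives,
#' e.g. `"SAT-KS-AT-DH-ACP-[ACP]-HTH-CMeT-[TE|ADH|NAD]-[PeptidaseS9]"`.
#'
#' @param text Pattern string.
#' @return A `grammar_pattern`: list of elements, each with `tokens`
#'   (character vector of alternatives) and `optional` (logical).
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  # tokens contain no hyphens, so a plain split is safe
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  elements <- lapply(parts, function(p) {
    optional <- grepl("^\\[.*\\]$", p)
    body <- sub("^\\[(.*)\\]$", "\\1", p)
    toks <- strsplit(body, "|", fixed = TRUE)[[1]]
    unknown <- setdiff(toks, domain_tokens())
    if (length(unknown) > 0) {
      abort(sprintf("unknown token(s) in pattern: %s", paste(unknown, collapse = ", ")))
    }
    list(tokens = toks, optional = optional)
  })
  if (!any(!vapply(elements, `[[`, TRUE, "optional"))) {
    abort("a grammar pattern needs at least one mandatory element")
  }
  structure(elements, class = "grammar_pattern", pattern = text)
}

#' Match an architecture against a grammar pattern
#'
#' `TRUE` iff the architecture is an exact expansion of the pattern: each
#' element contributes one of its alternative tokens, optional elements may
#' be skipped, order is preserved and no extra tokens are allowed.
#'
#' @param arch A `domain_architecture` (or character vector of tokens).
#' @param pattern A `grammar_pattern` or pattern string.
#' @return Logical scalar.
#' @examples
#' match_pattern(parse_architecture("KS-AT-KR"), "KS-AT-[DH]-[ER]-KR-[ACP]")
#' @export
match_pattern <- function(arch, pattern) {
  if (is.character(pattern) && !inherits(pattern, "grammar_pattern")) {
    pattern <- parse_pattern(pattern)
  }
  tokens <- unclass(arch)
  n <- length(tokens)
  # reachable token-prefix lengths after consuming each pattern element
  reach <- 0L
  for (el in pattern) {
    nxt <- integer(0)
    for (j in reach) {
      if (j < n && tokens[j + 1L] %in% el$tokens) nxt <- c(nxt, j + 1L)
    }
    if (el$optional) nxt <- union(nxt, reach)
    reach <- unique(nxt)
    if (length(reach) == 0) return(FALSE)
  }
  n %in% reach
}

#' Enumerate all expansions of a grammar pattern
#'
#' The expansion set is finite (at most the product of alternative counts
#' over elements, times two per optional element). Used by the grammar
#' round-trip checks: `match_pattern` must accept exactly this set.
#'
#' @param pattern A `grammar_pattern` or pattern string.
#' @return List of character vectors, one per distinct expansion.
#' @export
expand_pattern <- function(pattern) {
  if (is.character(pattern) && !inherits(pattern, "grammar_pattern")) {
    pattern <- parse_pattern(pattern)
  }
  out <- list(character(0))
  for (el in pattern) {
    grown <- list()
    for (prefix in out) {
      for (tok in el$tokens) grown[[length(grown) + 1L]] <- c(prefix, tok)
      if (el$optional) grown[[length(grown) + 1L]] <- prefix
    }
    out <- grown
  }
  unique(out)
}

#' Reducing-class of a PKS domain architecture
#'
#' Non-reducing (NR) PKSs lack reductive domains, partially reducing (PR)
#' PKSs carry a ketoreductase (KR) but no enoyl reductase (ER), and reducing
#' (R) PKSs carry the full reductive set. The discriminators here are KR and
#' ER only: NR architectures may legally contain a DH-position domain (in
#' NR-PKS this region is a product-template-like domain, not a functional
#' dehydratase), so DH is deliberately not used to call the class.
#' Architectures missing KS or AT are not Type I PKS.
#'
#' @param arch A `domain_architecture` (or character vector of tokens).
#' @return One of `"NR"`, `"PR"`, `"R"`, `"not_T1PKS"`.
#' @examples
#' classify_reduction(parse_architecture("KS-AT-DH-KR-ACP"))   # "PR"
#' @export
classify_reduction <- function(arch) {
  tokens <- unclass(arch)
  if (!("KS" %in% tokens) || !("AT" %in% tokens)) return("not_T1PKS")
  if ("ER" %in% tokens) return("R")
  if ("KR" %in% tokens) return("PR")
  "NR"
}

#' Packaged PKS group registry
#'
#' The named PKS groups with their reducing class and domain grammar,
#' shipped as a plain-text table so that group definitions remain revisable
#' data, not code. `NR-SI` and `NR-SII` are subclade-level generalisations
#' of the non-reducing groups (NR-I to NR-V plus NR-VIII, and NR-VI/NR-VII,
#' respectively); NR-IX is the atranorin-associated specialisation that
#' always carries an ADH and never a NAD domain after CMeT. `R` is the
#' generic reducing grammar; R-V, R-IX (facultative carnitine
#' O-acyltransferase tail) and R-X (facultative DH/ER) are the named
#' reducing groups with distinctive grammars.
#'
#' @return Tibble with columns `name`, `class`, `pattern`.
#' @export
pks_group_registry <- function() {
  path <- system.file("extdata", "pks_groups.tsv", package = "lichenpks",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccc")
}

#' Classify an architecture into candidate PKS groups
#'
#' Candidate groups are all registry grammars that accept the architecture.
#' Grammar overlap is preserved, never silently resolved: e.g. `KS-AT-KR`
#' is an expansion of both the PR grammar and the reduced R-X grammar, and
#' both candidates are reported with the ambiguity flagged (R-X membership
#' is ultimately a clade property, so grammar alone cannot decide it). When
#' an orthogroup label is supplied and maps to a group name, that group is
#' promoted to the front and the evidence is recorded as `"both"`.
#'
#' @param arch A `domain_architecture`, or an architecture string.
#' @param orthogroup_label Optional group name supported by orthogroup
#'   evidence (see [orthogroup_group_map()]).
#' @param registry Group registry tibble; defaults to the packaged one.
#' @param gene_id Optional gene identifier carried into the result.
#' @return One-row tibble: `gene_id`, `reduction`, `candidates` (list column
#'   of group names, ordered), `top_group`, `evidence` (`"grammar"`,
#'   `"orthogroup"` or `"both"`), `ambiguous`.
#' @export
assign_group <- function(arch, orthogroup_label = NULL,
                         registry = pks_group_registry(),
                         gene_id = NA_character_) {
  if (is.character(arch) && !inherits(arch, "domain_architecture")) {
    arch <- parse_architecture(arch, permissive = TRUE)
  }
  reduction <- classify_reduction(arch)
  hits <- vapply(registry$pattern, function(p) match_pattern(arch, p), TRUE)
  cand <- registry$name[hits]
  classes <- registry$class[hits]
  # groups whose class agrees with the domain-based call come first
  ord <- order(classes != reduction, cand)
  cand <- cand[ord]
  evidence <- "grammar"
  if (!is.null(orthogroup_label) && !is.na(orthogroup_label) &&
      orthogroup_label %in% registry$name) {
    evidence <- if (orthogroup_label %in% cand) "both" else "orthogroup"
    cand <- c(orthogroup_label, setdiff(cand, orthogroup_label))
  }
  cand_classes <- registry$class[match(cand, registry$name)]
  ambiguous <- length(cand) > 1 || any(cand_classes != reduction)
  tibble(
    gene_id = gene_id,
    reduction = reduction,
    candidates = list(cand),
    top_group = if (length(cand) > 0) cand[[1]] else NA_character_,
    evidence = evidence,
    ambiguous = ambiguous
  )
}

#' Classify a table of architectures
#'
#' Vectorised driver over a tibble with columns `gene_id` and
#' `architecture` (hyphen-delimited strings), optionally `orthogroup_label`.
#'
#' @param architectures Tibble of gene ids and architecture strings.
#' @param registry Group registry tibble.
#' @return Tibble with one classification row per gene (see [assign_group()]).
#' @export
classify_architectures <- function(architectures,
                                   registry = pks_group_registry()) {
  stopifnot(all(c("gene_id", "architecture") %in% names(architectures)))
  labels <- if ("orthogroup_label" %in% names(architectures)) {
    architectures$orthogroup_label
  } else {
    rep(NA_character_, nrow(architectures))
  }
  purrr::pmap_dfr(
    list(architectures$architecture, labels, architectures$gene_id),
    function(a, l, g) assign_group(a, orthogroup_label = l, registry = registry,
                                   gene_id = g)
  )
}

#' Map orthogroups to PKS group names by majority grammar label
#'
#' An orthogroup inherits the group name carried by the majority of its
#' members' grammar classifications; ties leave the orthogroup unlabelled.
#'
#' @param orthogroups Tibble with columns `orthogroup`, `member`.
#' @param classifications Tibble from [classify_architectures()] keyed by
#'   `gene_id`.
#' @return Tibble with columns `orthogroup`, `group` (`NA` when tied or no
#'   member has a grammar label).
#' @export
orthogroup_group_map <- function(orthogroups, classifications) {
  joined <- dplyr::left_join(
    orthogroups,
    dplyr::select(classifications, gene_id, top_group),
    by = c(member = "gene_id")
  )
  joined |>
    dplyr::filter(!is.na(.data$top_group)) |>
    dplyr::count(.data$orthogroup, .data$top_group) |>
    dplyr::group_by(.data$orthogroup) |>
    dplyr::summarise(group = {
      best <- .data$top_group[.data$n == max(.data$n)]
      if (length(best) == 1) best else NA_character_
    }, .groups = "drop")
}
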