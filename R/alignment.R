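# Alignment container and I/O, trimming, and per-site category statistics.

#' Construct an amino-acid alignment
#'
#' @param x Either a character matrix (one residue per cell, rows = taxa,
#'   rownames = taxon ids) or a named character vector of equal-length
#'   sequence strings. The gap symbol is `-`.
#' @return An `aa_alignment`: a character matrix with unique rownames.
#' @export
aa_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) abort("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1) abort("sequences must have equal length")
    x <- do.call(rbind, strsplit(x, ""))
  }
  stopifnot(is.matrix(x), is.character(x))
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    abort("alignment rows must carry unique taxon ids")
  }
  structure(x, class = c("aa_alignment", "matrix"))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment: %d taxa x %d sites>\n", nrow(x), ncol(x)))
  invisible(x)
}

# Alignment as named sequence strings.
alignment_strings <- function(aln) {
  setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
}

#' Read a protein alignment
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"` (relaxed interleaved/sequential
#'   PHYLIP, read via phangorn).
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    strings <- setNames(as.character(seqs), sub(" .*", "", names(seqs)))
  } else {
    pd <- phangorn::read.phyDat(path, format = "phylip", type = "AA")
    m <- toupper(as.character(pd))
    return(aa_alignment(m))
  }
  aa_alignment(toupper(strings))
}

#' Write a protein alignment
#'
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"` (sequential, relaxed names).
#' @return The path, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  strings <- alignment_strings(aln)
  if (format == "fasta") {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(strings), path)
  } else {
    lines <- c(sprintf("%d %d", nrow(aln), ncol(aln)),
               sprintf("%s  %s", names(strings), strings))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Alignment trimming parameters
#'
#' @param gap_threshold Minimum fraction of non-gap residues a column must
#'   retain to be kept (default 0.70).
#' @param res_overlap Minimum fraction of *other* sequences that must have
#'   a residue in a column for a residue there to count as "good"
#'   (default 0.70).
#' @param seq_overlap Minimum percentage of good residues (over the full
#'   alignment length) a sequence needs to be kept (default 60).
#' @return A `trim_params` list.
#' @export
trim_params <- function(gap_threshold = 0.70, res_overlap = 0.70,
                        seq_overlap = 60) {
  stopifnot(gap_threshold >= 0, gap_threshold <= 1,
            res_overlap >= 0, res_overlap <= 1,
            seq_overlap >= 0, seq_overlap <= 100)
  structure(list(gap_threshold = gap_threshold, res_overlap = res_overlap,
                 seq_overlap = seq_overlap), class = "trim_params")
}

#' Trim an alignment by sequence and column occupancy
#'
#' Two fixed stages. Stage 1 drops sequences: a residue (non-gap cell) is
#' "good" when the fraction of the other sequences with a residue in its
#' column is at least `res_overlap`; a sequence is kept when its percentage
#' of good residues over the alignment length is at least `seq_overlap`
#' (gap cells are never good, so gap-rich sequences fail). Stage 2 then
#' drops columns whose fraction of non-gap residues among the kept
#' sequences falls below `gap_threshold`. These operational definitions
#' approximate the overlap trimming of common alignment-trimming tools;
#' the output is always a sub-matrix of the input, never an altered one.
#'
#' @param aln An `aa_alignment` (gap symbol `-`).
#' @param params A [trim_params()].
#' @return Trimmed `aa_alignment` with attributes `dropped_sequences` and
#'   `dropped_columns`.
#' @export
trim_alignment <- function(aln, params = trim_params()) {
  gap <- matrix(aln %in% GAP_CHARS, nrow = nrow(aln))
  n <- nrow(aln)
  colres <- colSums(!gap)
  # fraction of OTHER sequences with a residue in each column, per sequence
  good <- matrix(FALSE, n, ncol(aln))
  for (i in seq_len(n)) {
    others <- (colres - !gap[i, ]) / (n - 1)
    good[i, ] <- !gap[i, ] & others >= params$res_overlap
  }
  keep_seq <- 100 * rowSums(good) / ncol(aln) >= params$seq_overlap
  if (!any(keep_seq)) abort("trimming dropped all sequences")
  sub <- aln[keep_seq, , drop = FALSE]
  occupancy <- colSums(!(sub == "-" | sub %in% GAP_CHARS)) / nrow(sub)
  keep_col <- occupancy >= params$gap_threshold
  out <- aa_alignment(sub[, keep_col, drop = FALSE])
  attr(out, "dropped_sequences") <- rownames(aln)[!keep_seq]
  attr(out, "dropped_columns") <- which(!keep_col)
  out
}

#' Site category statistics of an alignment
#'
#' Per column, over non-gap residues: 0 or 1 distinct state makes the site
#' constant; at least two states each present in at least two sequences
#' makes it parsimony-informative; anything else is a singleton site. The
#' three categories always sum to the number of sites. Distinct patterns
#' count unique whole columns, with the gap treated as a state.
#'
#' @param aln An `aa_alignment`.
#' @return One-row tibble: `n_sites`, `n_constant`, `n_singleton`,
#'   `n_parsimony_informative`, `n_distinct_patterns`.
#' @export
site_stats <- function(aln) {
  classify_col <- function(col) {
    res <- col[!(col %in% GAP_CHARS)]
    tab <- table(res)
    if (length(tab) <= 1) return("constant")
    if (sum(tab >= 2) >= 2) return("parsimony_informative")
    "singleton"
  }
  cats <- apply(aln, 2, classify_col)
  keys <- apply(aln, 2, paste, collapse = "")
  tibble(
    n_sites = ncol(aln),
    n_constant = sum(cats == "constant"),
    n_singleton = sum(cats == "singleton"),
    n_parsimony_informative = sum(cats == "parsimony_informative"),
    n_distinct_patterns = length(unique(keys))
  )
}
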