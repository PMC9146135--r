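# Shared internal helpers.

#' The 20-letter amino-acid alphabet
#'
#' Single-letter codes in the conventional order used throughout the package
#' (alphabetical by letter).
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")
}

# Half-up decimal rounding. base::round() rounds half to even, which does not
# reproduce percentages printed from integer counts.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Derive a labelled sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own reproducible stream
#' from one master seed, so stages can be re-run independently. The derived
#' seed is a deterministic hash of the master seed and a stage label, kept
#' within the 32-bit integer range.
#'
#' @param seed Master seed (single integer).
#' @param label Character label naming the stage (e.g. `"genomes"`).
#' @return A single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) + h * 7919) %% 2147483647L)
}

# Validate that a character vector contains only legal amino-acid residues.
check_aa <- function(x, what = "sequence") {
  bad <- setdiff(unique(unlist(strsplit(x, ""))), aa_alphabet())
  if (length(bad) > 0) {
    abort(sprintf("illegal residue(s) in %s: %s", what,
                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}

# Random amino-acid sequence of length n under uniform frequencies.
random_protein <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

# Mutate a protein: each site substituted with probability q to a uniformly
# chosen different residue.
mutate_protein <- function(seq, q) {
  res <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(res)) < q)
  for (i in hit) {
    res[i] <- sample(setdiff(aa_alphabet(), res[i]), 1)
  }
  paste(res, collapse = "")
}

# Expected pairwise identity between two sequences independently derived from
# a common ancestor with per-site substitution probability q.
expected_pair_identity <- function(q) {
  (1 - q)^2 + q^2 / 19
}

# Per-site substitution probability whose expected pairwise identity equals
# `target` (a fraction in (0, 1]). Solved by bisection.
identity_to_subst_rate <- function(target) {
  stopifnot(target > 0, target <= 1)
  if (target >= 1) return(0)
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (expected_pair_identity(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
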