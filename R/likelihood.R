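# Fixed-topology likelihood computation by Felsenstein's pruning algorithm.
#
# Alignments are collapsed to distinct site patterns before pruning, and
# partial likelihoods are rescaled per pattern to keep long alignments and
# deep trees away from underflow. Gaps (and ambiguous residues) are treated
# as missing data: their tip partials are 1 for every state.

GAP_CHARS <- c("-", "X", "?", ".")

# Collapse an alignment into distinct patterns of model-state indices.
# Returns tip state matrix (ntaxa x npatterns, NA = missing), pattern
# weights, and the site -> pattern map.
collapse_patterns <- function(aln, model) {
  states <- matrix(match(aln, model$states), nrow = nrow(aln),
                   dimnames = dimnames(aln))
  is_gap <- matrix(aln %in% GAP_CHARS, nrow = nrow(aln))
  bad <- !is_gap & is.na(states)
  if (any(bad)) {
    abort(sprintf("unrecognised residue(s): %s",
                  paste(unique(aln[bad]), collapse = ", ")))
  }
  key <- apply(states, 2, paste, collapse = ",")
  pat <- match(key, unique(key))
  keep <- !duplicated(key)
  list(
    tip_states = states[, keep, drop = FALSE],
    weights = as.integer(table(factor(pat, levels = seq_len(sum(keep))))),
    site_pattern = pat,
    taxa = rownames(aln)
  )
}

rowmax20 <- function(m) {
  mx <- m[, 1]
  for (j in 2:ncol(m)) mx <- pmax(mx, m[, j])
  mx
}

# Pruning pass for one rate category. Returns per-pattern log-likelihood.
prune_category <- function(prep, tree, model, rate) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- ncol(prep$tip_states)
  tree <- ape::reorder.phylo(tree, "postorder")
  tipidx <- match(tree$tip.label, prep$taxa)
  partial <- vector("list", nnode)
  logscale <- numeric(npat)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    P <- transition_prob(model, tree$edge.length[e], rate)
    if (child <= ntip) {
      s <- prep$tip_states[tipidx[child], ]
      contrib <- matrix(1, npat, 20)
      obs <- !is.na(s)
      contrib[obs, ] <- t(P)[s[obs], , drop = FALSE]
    } else {
      contrib <- partial[[child]] %*% t(P)
    }
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
      mx <- rowmax20(partial[[parent]])
      mx[mx == 0] <- 1
      partial[[parent]] <- partial[[parent]] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- tree$edge[nrow(tree$edge), 1]
  lik <- as.vector(partial[[root]] %*% model$freqs)
  log(lik) + logscale
}

# Per-pattern log-likelihood averaged over gamma categories.
prune_patterns <- function(prep, tree, model) {
  k <- length(model$rates)
  percat <- vapply(model$rates,
                   function(r) prune_category(prep, tree, model, r),
                   numeric(ncol(prep$tip_states)))
  percat <- matrix(percat, ncol = k)
  if (k == 1) return(as.vector(percat))
  mx <- apply(percat, 1, max)
  mx + log(rowMeans(exp(percat - mx)))
}

check_taxa <- function(aln, tree) {
  extra_aln <- setdiff(rownames(aln), tree$tip.label)
  extra_tree <- setdiff(tree$tip.label, rownames(aln))
  if (length(extra_aln) > 0 || length(extra_tree) > 0) {
    abort(sprintf(
      "alignment/tree taxa mismatch; only in alignment: %s; only in tree: %s",
      paste(extra_aln, collapse = ",") %||% "",
      paste(extra_tree, collapse = ",") %||% ""
    ))
  }
}

#' Per-site log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein pruning under an amino-acid substitution model with optional
#' discrete-gamma rate heterogeneity (equal-probability categories averaged
#' per site). Gaps are treated as missing data.
#'
#' @param aln An `aa_alignment` (character matrix, rows = taxa).
#' @param tree An [ape::phylo] tree with branch lengths; its tip set must
#'   equal the alignment's taxa.
#' @param model A [subst_model()].
#' @return Numeric vector of natural-log site likelihoods, one per column.
#' @export
site_loglik <- function(aln, tree, model) {
  check_taxa(aln, tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch length")
  prep <- collapse_patterns(aln, model)
  lnl <- prune_patterns(prep, tree, model)
  lnl[prep$site_pattern]
}

#' Total log-likelihood of an alignment on a fixed tree
#'
#' @inheritParams site_loglik
#' @return Single numeric value.
#' @export
total_loglik <- function(aln, tree, model) {
  check_taxa(aln, tree)
  prep <- collapse_patterns(aln, model)
  sum(prune_patterns(prep, tree, model) * prep$weights)
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise univariate maximisation of the total log-likelihood:
#' each branch is optimised in turn by golden-section search (all others
#' held fixed), sweeping over branches until a full sweep improves the
#' total by less than `tol`. A proposed length is only accepted if it does
#' not decrease the likelihood, so the total is monotone non-decreasing
#' across sweeps.
#'
#' @param aln An `aa_alignment`.
#' @param topology An [ape::phylo] topology; existing branch lengths are
#'   used as the starting point (missing ones start at 0.1).
#' @param model A [subst_model()].
#' @param tol Convergence tolerance on the total log-likelihood.
#' @param max_sweeps Maximum number of sweeps over all branches.
#' @param max_length Upper bound of the search interval per branch.
#' @return The tree with optimised `edge.length` and attribute `loglik`.
#' @export
optimize_branch_lengths <- function(aln, topology, model, tol = 1e-6,
                                    max_sweeps = 50, max_length = 20) {
  check_taxa(aln, topology)
  tree <- topology
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  prep <- collapse_patterns(aln, model)
  obj <- function(tr) sum(prune_patterns(prep, tr, model) * prep$weights)
  cur <- obj(tree)
  for (sweep in seq_len(max_sweeps)) {
    start <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        tr <- tree
        tr$edge.length[e] <- t
        obj(tr)
      }
      opt <- optimize(f, interval = c(1e-8, max_length), maximum = TRUE,
                      tol = 1e-6)
      if (opt$objective >= cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - start < tol) break
  }
  attr(tree, "loglik") <- cur
  tree
}
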