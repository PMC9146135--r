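# Independent oracles used by the test suite. These deliberately share no
# code with the package implementations they check.

# Brute-force affine-gap local alignment score (Gotoh DP, plain loops).
# A gap of length L costs open + L * ext. Gap-adjacent-to-gap transitions
# are never optimal at these penalties, so they are not modelled.
sw_score_oracle <- function(a, b, mat, open = 11, ext = 1) {
  ar <- strsplit(a, "")[[1]]
  br <- strsplit(b, "")[[1]]
  n <- length(ar); m <- length(br)
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[ar[i - 1], br[j - 1]]
      M[i, j] <- s + max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                         Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Step-by-step MCL oracle on an adjacency matrix: independent loop
# structure, clusters read off by grouping identical nonzero column
# supports and merging overlaps.
mcl_oracle <- function(adj, inflation = 1.5, max_iter = 500, tol = 1e-7) {
  n <- nrow(adj)
  A <- (adj + t(adj)) / 2
  for (i in seq_len(n)) {
    mx <- max(A[i, ])
    A[i, i] <- if (mx > 0) mx else 1
  }
  M <- A
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    for (j in seq_len(n)) M2[, j] <- M2[, j] / sum(M2[, j])
    M2[M2 < 1e-12] <- 0
    for (j in seq_len(n)) M2[, j] <- M2[, j] / sum(M2[, j])
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      break
    }
    M <- M2
  }
  # union-find over shared support
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (j in seq_len(n)) {
    sup <- which(M[, j] > 1e-8)
    for (s in sup) {
      ra <- find(j); rb <- find(s)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Exhaustive tree likelihood: sum over all internal-node state
# assignments, averaged over gamma categories. Uses the model's published
# transition probabilities but its own summation.
brute_site_loglik <- function(aln, tree, model) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  internal <- root:nnode
  tipstate <- matrix(match(aln, model$states), nrow = nrow(aln))
  rownames(tipstate) <- rownames(aln)
  tipstate <- tipstate[tree$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  out <- numeric(ncol(aln))
  for (site in seq_len(ncol(aln))) {
    lik_cats <- vapply(model$rates, function(rate) {
      P <- lapply(seq_len(nrow(tree$edge)), function(e) {
        transition_prob(model, tree$edge.length[e], rate)
      })
      state_of <- function(node, assignment) {
        if (node <= ntip) tipstate[node, site]
        else assignment[match(node, internal)]
      }
      total <- 0
      for (g in seq_len(nrow(grid))) {
        assignment <- grid[g, ]
        p <- model$freqs[assignment[1]]
        for (e in seq_len(nrow(tree$edge))) {
          sp <- state_of(tree$edge[e, 1], assignment)
          sc <- state_of(tree$edge[e, 2], assignment)
          if (is.na(sc)) next  # missing tip: marginalised, handled below
          p <- p * P[[e]][sp, sc]
        }
        total <- total + p
      }
      total
    }, numeric(1))
    out[site] <- log(mean(lik_cats))
  }
  out
}

# Adjusted Rand index between two labellings (via mclust when available).
ari <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

random_aa_seq <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

# Small shared fixtures ------------------------------------------------

blosum62_matrix <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  aas <- aa_alphabet()
  e$BLOSUM62[aas, aas]
}

quartet_trees <- function() {
  list(
    true = ape::read.tree(text = "((A:0.2,B:0.2):0.15,C:0.2,D:0.2);"),
    alt = ape::read.tree(text = "((A:0.2,C:0.2):0.15,B:0.2,D:0.2);")
  )
}
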