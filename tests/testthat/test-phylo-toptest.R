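# Trimming, site statistics, likelihoods and topology tests.

test_that("gap-free alignments pass trimming unchanged", {
  aln <- aa_alignment(c(a = "MKVLAW", b = "MKVLAW", c = "MKVLCW",
                        d = "MKVLAW"))
  out <- trim_alignment(aln)
  expect_identical(as.vector(out), as.vector(aln))
  expect_identical(dim(out), dim(aln))
  expect_length(attr(out, "dropped_sequences"), 0)
  expect_length(attr(out, "dropped_columns"), 0)
})

test_that("gappy columns and gappy sequences are dropped", {
  # one column with 3/4 gaps: occupancy 0.25 < 0.70
  aln <- aa_alignment(c(a = "MKVLA", b = "MK-LA", c = "MK-LA", d = "MK-LA"))
  out <- trim_alignment(aln)
  expect_equal(ncol(out), 4)
  expect_equal(attr(out, "dropped_columns"), 3)

  # a 90%-gap sequence against gap-free partners is dropped at
  # seq_overlap 60 (its good-residue share is 10%)
  aln2 <- aa_alignment(c(
    full1 = "MKVLAWCDEF", full2 = "MKVLAWCDEF", full3 = "MKVLAWCDEF",
    full4 = "MKVLAWCDEF", full5 = "MKVLAWCDEF",
    gappy = "M---------"
  ))
  out2 <- trim_alignment(aln2)
  expect_equal(attr(out2, "dropped_sequences"), "gappy")
  expect_equal(nrow(out2), 5)

  expect_error(
    trim_alignment(aa_alignment(c(a = "M---", b = "-K--")),
                   trim_params(seq_overlap = 90)),
    "all sequences")
})

test_that("trimming never alters retained residues", {
  withr::with_seed(141, {
    m <- matrix(sample(c(aa_alphabet(), "-"), 8 * 40, replace = TRUE,
                       prob = c(rep(1, 20), 6)), nrow = 8)
    rownames(m) <- paste0("t", 1:8)
  })
  aln <- aa_alignment(m)
  out <- tryCatch(trim_alignment(aln), error = function(e) NULL)
  if (!is.null(out) && nrow(out) > 0 && ncol(out) > 0) {
    kept_rows <- match(rownames(out), rownames(aln))
    kept_cols <- setdiff(seq_len(ncol(aln)), attr(out, "dropped_columns"))
    got <- unclass(out)
    attr(got, "dropped_sequences") <- NULL
    attr(got, "dropped_columns") <- NULL
    expect_identical(got, unclass(aln)[kept_rows, kept_cols, drop = FALSE])
  }
})

test_that("site categories partition the sites", {
  uniform <- aa_alignment(c(a = "MMMMMMMMMM", b = "MMMMMMMMMM",
                            c = "MMMMMMMMMM"))
  s <- site_stats(uniform)
  expect_equal(unlist(s), c(n_sites = 10, n_constant = 10, n_singleton = 0,
                            n_parsimony_informative = 0,
                            n_distinct_patterns = 1))
  # identical rows over varied residues: all constant, one pattern per
  # distinct column
  ident <- aa_alignment(c(a = "MKVLAWCDEF", b = "MKVLAWCDEF",
                          c = "MKVLAWCDEF"))
  s1 <- site_stats(ident)
  expect_equal(s1$n_constant, 10)
  expect_equal(s1$n_distinct_patterns, 10)
  # hand-enumerated toy: columns AAAA, ACAA, AACC
  toy <- aa_alignment(rbind(t1 = c("A", "A", "A"), t2 = c("A", "C", "A"),
                            t3 = c("A", "A", "C"), t4 = c("A", "A", "C")))
  s2 <- site_stats(toy)
  expect_equal(s2$n_constant, 1)
  expect_equal(s2$n_singleton, 1)
  expect_equal(s2$n_parsimony_informative, 1)
  expect_equal(s2$n_distinct_patterns, 3)
  # category sum identity on random gapped alignments
  withr::with_seed(149, {
    for (i in 1:5) {
      m <- matrix(sample(c("A", "C", "D", "-"), 6 * 30, replace = TRUE),
                  nrow = 6, dimnames = list(paste0("t", 1:6), NULL))
      st <- site_stats(aa_alignment(m))
      expect_equal(st$n_constant + st$n_singleton +
                     st$n_parsimony_informative, st$n_sites)
      expect_lte(st$n_distinct_patterns, st$n_sites)
    }
  })
})

test_that("pruning matches closed forms on two taxa", {
  mod <- subst_model("Poisson")
  # zero branch, identical sequences: per-site lnL = ln(1/20)
  tree0 <- ape::read.tree(text = "(A:0,B:0);")
  aln0 <- aa_alignment(c(A = "MKVL", B = "MKVL"))
  expect_equal(site_loglik(aln0, tree0, mod), rep(log(1 / 20), 4))
  # general two-taxon case: lnL = ln(pi * P(t1+t2))
  tree <- ape::read.tree(text = "(A:0.07,B:0.22);")
  withr::with_seed(151, {
    aln <- gen_alignment(tree, mod, 200, seed = 151)
  })
  P <- transition_prob(mod, 0.29)
  idx <- matrix(match(aln, mod$states), nrow = 2)
  closed <- log(mod$freqs[idx[1, ]] * P[cbind(idx[1, ], idx[2, ])])
  expect_equal(site_loglik(aln, tree, mod), unname(closed), tolerance = 1e-12)
})

test_that("pruning equals exhaustive state summation on small trees", {
  trees <- list(
    ape::read.tree(text = "((A:0.15,B:0.3):0.1,(C:0.2,D:0.05):0.4);"),
    ape::read.tree(text = "(((A:0.1,B:0.2):0.1,C:0.3):0.2,(D:0.15,E:0.25):0.1);")
  )
  models <- list(subst_model("Poisson"),
                 subst_model("LG", gamma_categories = 4, alpha = 0.8))
  for (tree in trees) {
    for (mod in models) {
      aln <- gen_alignment(tree, mod, 4, seed = 157)
      expect_equal(site_loglik(aln, tree, mod),
                   brute_site_loglik(aln, tree, mod),
                   tolerance = 1e-10)
    }
  }
})

test_that("gaps are treated as missing data", {
  mod <- subst_model("Poisson")
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,C:0.1,D:0.1);")
  aln <- aa_alignment(rbind(A = c("M", "-"), B = c("M", "K"),
                            C = c("M", "K"), D = c("M", "-")))
  lnl <- site_loglik(aln, tree, mod)
  expect_true(all(is.finite(lnl)))
  expect_equal(lnl, brute_site_loglik(aln, tree, mod), tolerance = 1e-10)
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  tree <- ape::read.tree(text = "((A:0.15,B:0.3):0.1,(C:0.2,D:0.05):0.4);")
  mod <- subst_model("LG")
  aln <- gen_alignment(tree, mod, 300, seed = 163)
  pd <- phangorn::phyDat(unclass(aln), type = "AA")
  fit <- phangorn::pml(tree, pd, model = "LG")
  expect_equal(total_loglik(aln, tree, mod), as.numeric(fit$logLik),
               tolerance = 1e-6)
})

test_that("taxon mismatches raise a symmetric-difference error", {
  tree <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- aa_alignment(c(A = "MK", C = "MK"))
  expect_error(site_loglik(aln, tree, subst_model("Poisson")),
               "only in alignment: C.*only in tree: B")
})

test_that("branch-length optimisation is monotone and recovers truth", {
  mod <- subst_model("Poisson")
  tree <- ape::read.tree(text = "((A:0.15,B:0.25):0.1,C:0.2,D:0.3);")
  aln <- gen_alignment(tree, mod, 20000, seed = 167)
  start <- tree
  start$edge.length <- rep(0.3, nrow(tree$edge))
  lnl0 <- total_loglik(aln, start, mod)
  fit <- optimize_branch_lengths(aln, start, mod)
  expect_gte(attr(fit, "loglik"), lnl0)
  expect_equal(fit$edge.length, tree$edge.length, tolerance = 0.1)
  # zero-length truth: identical sequences across a branch push its
  # estimate to the boundary
  tree0 <- ape::read.tree(text = "(A:0.5,B:0.5);")
  aln0 <- aa_alignment(rbind(A = sample(aa_alphabet(), 500, TRUE)))
  aln0 <- aa_alignment(rbind(A = aln0[1, ], B = aln0[1, ]))
  fit0 <- optimize_branch_lengths(aln0, tree0, mod)
  expect_true(all(fit0$edge.length <= 1e-4))
})

test_that("RELL replicates are seeded and have the right expectation", {
  withr::with_seed(179, {
    m <- site_lnl_matrix(matrix(stats::rnorm(3 * 40, mean = -4), 3, 40))
  })
  r1 <- rell_resample(m, B = 5, seed = 9)
  r2 <- rell_resample(m, B = 5, seed = 9)
  expect_identical(r1, r2)
  expect_equal(dim(r1), c(3L, 5L))
  # all-equal per-site values: every replicate equals n * value
  flat <- site_lnl_matrix(matrix(-2, 2, 30))
  expect_true(all(rell_resample(flat, B = 20, seed = 1) == -60))
  half <- rell_resample(flat, B = 3, seed = 1, scale = 0.5)
  expect_true(all(half == -2 * 15))
  # replicate means approximate scale * total within Monte-Carlo error
  big <- rell_resample(m, B = 4000, seed = 5)
  expect_equal(rowMeans(big), rowSums(m), tolerance = 0.02)
})

test_that("degenerate inputs give p = 1 across all tests", {
  flat <- site_lnl_matrix(rbind(t1 = rep(-3, 25), t2 = rep(-3, 25)))
  expect_equal(kh_test(flat, B = 200, seed = 1), 1)
  expect_equal(unname(sh_test(flat, B = 200, seed = 1)), c(1, 1))
  expect_equal(unname(elw(flat, B = 200, seed = 1)), c(0.5, 0.5))
  au <- au_test(flat, B = 500, seed = 1)
  expect_true(all(au$p_au >= 0 & au$p_au <= 1))
})

test_that("test outputs respect their invariants on random matrices", {
  withr::with_seed(181, {
    for (i in 1:5) {
      ntree <- sample(2:4, 1)
      m <- site_lnl_matrix(matrix(stats::rnorm(ntree * 60, -3, 0.5),
                                  ntree, 60))
      res <- toptest_report(m, B = 400, seed = i)
      expect_true(all(res$p_kh >= 0 & res$p_kh <= 1))
      expect_true(all(res$p_sh >= 0 & res$p_sh <= 1))
      expect_true(all(res$p_au >= 0 & res$p_au <= 1))
      expect_equal(sum(res$c_elw), 1, tolerance = 1e-9)
      expect_true(all(res$deltal >= 0))
      expect_equal(res$deltal[which.max(res$logl)], 0)
      # SH is conservative relative to KH
      expect_true(all(res$p_sh >= res$p_kh - 0.1))
    }
  })
})

test_that("a dominant tree takes all the likelihood weight", {
  m <- site_lnl_matrix(rbind(strong = rep(-1, 100), weak = rep(-1.4, 100)))
  w <- elw(m, B = 2000, seed = 3)
  expect_gt(w[["strong"]], 0.99)
  expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("report reproduces the published deltaL from printed totals", {
  m <- site_lnl_matrix(rbind(
    "Bacidia+Cladoniaceae" = -28054.52811,
    "Cladoniaceae+Parmeliaceae" = -28108.54142
  ))
  res <- toptest_report(m, B = 100, seed = 1)
  expect_equal(round(res$deltal[2], 3), 54.013)
  expect_equal(res$deltal[1], 0)
  expect_equal(res$tree[which.max(res$logl)], "Bacidia+Cladoniaceae")
})

test_that("report marks p-values below alpha with a minus sign", {
  m <- site_lnl_matrix(rbind(good = rep(-2, 60),
                             bad = rep(-2, 60) - c(2, rep(0.15, 59))))
  res <- toptest_report(m, B = 500, seed = 11)
  printed <- capture.output(print(res))
  expect_true(any(grepl("-", printed[grepl("bad", printed)])))
  td <- tidy(res)
  expect_true(td$rejected_kh[td$tree == "bad"])
  expect_false(td$rejected_kh[td$tree == "good"])
  gl <- glance(res)
  expect_equal(gl$best_tree, "good")
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("model construction satisfies its invariants", {
  for (mod in list(subst_model("Poisson"),
                   subst_model("LG"),
                   subst_model("LG", gamma_categories = 8, alpha = 0.5))) {
    expect_equal(rowSums(mod$Q), rep(0, 20), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(mod$freqs), 1, tolerance = 1e-12)
    expect_equal(-sum(mod$freqs * diag(mod$Q)), 1, tolerance = 1e-12)
    expect_equal(mean(mod$rates), 1, tolerance = 1e-12)
    P <- transition_prob(mod, 0.37)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(P >= 0))
    # detailed balance (reversibility): diag(pi) P is symmetric
    expect_true(isSymmetric(unname(mod$freqs * P), tol = 1e-10))
  }
  expect_error(subst_model("LG", gamma_categories = 4), "alpha")
  expect_error(transition_prob(subst_model("Poisson"), -1), "negative")
})

test_that("discrete gamma matches an independent discretisation", {
  skip_if_not_installed("phangorn")
  for (alpha in c(0.3, 1, 2.5)) {
    expect_equal(discrete_gamma_rates(alpha, 4),
                 as.vector(phangorn::discrete.gamma(alpha, 4)),
                 tolerance = 1e-8)
  }
})
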