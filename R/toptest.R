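# Tree topology tests over per-site log-likelihoods.
#
# All tests share one resampling primitive: RELL (resampling estimated
# log-likelihoods), which bootstraps site indices and re-sums the stored
# per-site values instead of re-optimising anything. On top of it sit the
# one-sided Kishino-Hasegawa test, the Shimodaira-Hasegawa test, expected
# likelihood weights, and the approximately unbiased test via multiscale
# bootstrap.

#' Per-site log-likelihood matrix
#'
#' @param x Numeric matrix, rows = trees, columns = sites; rownames are the
#'   tree ids (generated when absent). Entries must be finite.
#' @return A `site_lnl_matrix`.
#' @export
site_lnl_matrix <- function(x) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x))
  if (any(!is.finite(x))) abort("per-site log-likelihoods must be finite")
  if (is.null(rownames(x))) {
    rownames(x) <- sprintf("tree%d", seq_len(nrow(x)))
  }
  if (anyDuplicated(rownames(x))) abort("tree ids must be unique")
  structure(x, class = c("site_lnl_matrix", "matrix"))
}

#' Read / write a per-site log-likelihood table
#'
#' Long TSV with columns `tree`, `site`, `lnl`.
#'
#' @param path File path.
#' @return For the reader, a [site_lnl_matrix()].
#' @export
read_site_lnl <- function(path) {
  long <- readr::read_tsv(path, col_types = "cid")
  wide <- tidyr::pivot_wider(long, names_from = "site", values_from = "lnl")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$tree
  site_lnl_matrix(m)
}

#' @rdname read_site_lnl
#' @param m A [site_lnl_matrix()].
#' @export
write_site_lnl <- function(m, path) {
  long <- tibble(
    tree = rep(rownames(m), each = ncol(m)),
    site = rep(seq_len(ncol(m)), times = nrow(m)),
    lnl = as.vector(t(m))
  )
  readr::write_tsv(long, path)
  invisible(path)
}

#' RELL bootstrap of total log-likelihoods
#'
#' Each replicate draws `round(scale * n_sites)` site indices with
#' replacement -- the same indices for every tree -- and sums the stored
#' per-site log-likelihoods.
#'
#' @param m A [site_lnl_matrix()].
#' @param B Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param scale Resampling scale r > 0 (r != 1 only used by the multiscale
#'   AU test).
#' @return Numeric matrix of replicate totals, trees x B.
#' @export
rell_resample <- function(m, B = 10000, seed = 1, scale = 1) {
  stopifnot(B >= 1, scale > 0)
  n <- ncol(m)
  draw <- max(1L, round(scale * n))
  withr::with_seed(seed, {
    counts <- vapply(seq_len(B),
                     function(b) tabulate(sample.int(n, draw, replace = TRUE), n),
                     integer(n))
  })
  out <- unclass(m) %*% counts
  rownames(out) <- rownames(m)
  out
}

#' One-sided Kishino-Hasegawa test (RELL)
#'
#' For exactly two trees: the observed statistic is the total
#' log-likelihood difference between the better and the worse tree; the
#' null distribution is the centred RELL-resampled difference, and the
#' one-sided p-value for the worse tree is the fraction of null replicates
#' at least as large as the observed difference. Two identical per-site
#' vectors give p = 1 by convention.
#'
#' @param m A [site_lnl_matrix()] with exactly 2 rows.
#' @param B,seed Resampling controls.
#' @return Single p-value (for the worse of the two trees).
#' @export
kh_test <- function(m, B = 10000, seed = 1) {
  if (nrow(m) != 2) abort("kh_test needs exactly 2 trees")
  totals <- rowSums(m)
  best <- which.max(totals)
  worse <- 3L - best
  delta <- totals[best] - totals[worse]
  reps <- rell_resample(m, B = B, seed = seed)
  d <- reps[best, ] - reps[worse, ]
  d <- d - mean(d)
  mean(d >= delta)
}

#' Shimodaira-Hasegawa test (RELL)
#'
#' Each tree's replicate totals are centred at their own mean; per
#' replicate the maximum over trees of the centred values is taken, and a
#' tree's p-value is the fraction of replicates in which
#' `max - centred value` is at least its observed log-likelihood deficit.
#'
#' @param m A [site_lnl_matrix()] (>= 2 trees).
#' @param B,seed Resampling controls.
#' @return Named numeric vector of p-values, one per tree.
#' @export
sh_test <- function(m, B = 10000, seed = 1) {
  if (nrow(m) < 2) abort("sh_test needs at least 2 trees")
  totals <- rowSums(m)
  delta <- max(totals) - totals
  reps <- rell_resample(m, B = B, seed = seed)
  centred <- reps - rowMeans(reps)
  mx <- apply(centred, 2, max)
  p <- vapply(seq_len(nrow(m)),
              function(t) mean(mx - centred[t, ] >= delta[t]), numeric(1))
  setNames(p, rownames(m))
}

#' Expected likelihood weights (RELL)
#'
#' Per replicate, each tree receives the softmax weight of its resampled
#' total; the expected weight is the mean over replicates. Weights sum
#' to 1.
#'
#' @inheritParams sh_test
#' @return Named numeric vector of weights summing to 1.
#' @export
elw <- function(m, B = 10000, seed = 1) {
  if (nrow(m) < 2) abort("elw needs at least 2 trees")
  reps <- rell_resample(m, B = B, seed = seed)
  w <- apply(reps, 2, function(l) {
    e <- exp(l - max(l))
    e / sum(e)
  })
  setNames(rowMeans(matrix(w, nrow = nrow(m))), rownames(m))
}

#' Approximately unbiased test (multiscale RELL bootstrap)
#'
#' For each scale r, the bootstrap proportion BP(r) of each tree is the
#' fraction of replicates (of `round(r * n)` resampled sites) in which the
#' tree attains the maximum total. `qnorm(1 - BP)` is then regressed on
#' `d * sqrt(r) + c / sqrt(r)` by weighted least squares over the scales
#' with 0 < BP < 1, and the AU p-value is `1 - pnorm(d - c)`. Trees whose
#' BP is degenerate (0 or 1) at all but one scale get a flagged degenerate
#' p of 0 or 1.
#'
#' @param m A [site_lnl_matrix()] (>= 2 trees).
#' @param B Total replicate budget; each scale uses `round(B / 10)`
#'   replicates so total work stays near `B`.
#' @param seed Integer seed.
#' @param scales Resampling scales (>= 3 values).
#' @return Tibble: `tree`, `p_au`, `degenerate`.
#' @export
au_test <- function(m, B = 10000, seed = 1, scales = seq(0.5, 1.4, by = 0.1)) {
  if (nrow(m) < 2) abort("au_test needs at least 2 trees")
  if (length(scales) < 3) abort("au_test needs at least 3 scales")
  Bper <- max(10L, round(B / 10))
  bp <- matrix(NA_real_, nrow(m), length(scales),
               dimnames = list(rownames(m), NULL))
  for (s in seq_along(scales)) {
    reps <- rell_resample(m, B = Bper, seed = derive_seed(seed, paste0("au", s)),
                          scale = scales[s])
    win <- apply(reps, 2, which.max)
    bp[, s] <- tabulate(win, nbins = nrow(m)) / Bper
  }
  out <- purrr::map_dfr(seq_len(nrow(m)), function(t) {
    b <- bp[t, ]
    usable <- b > 0 & b < 1
    if (sum(usable) < 2) {
      return(tibble(tree = rownames(m)[t],
                    p_au = if (mean(b) > 0.5) 1 else 0,
                    degenerate = TRUE))
    }
    r <- scales[usable]
    z <- qnorm(1 - b[usable])
    w <- Bper * dnorm(z)^2 / (b[usable] * (1 - b[usable]))
    X <- cbind(sqrt_r = sqrt(r), inv_sqrt_r = 1 / sqrt(r))
    fit <- stats::lm.wfit(X, z, w)
    dcoef <- fit$coefficients[["sqrt_r"]]
    ccoef <- fit$coefficients[["inv_sqrt_r"]]
    tibble(tree = rownames(m)[t],
           p_au = min(1, max(0, 1 - pnorm(dcoef - ccoef))),
           degenerate = FALSE)
  })
  out
}

#' Topology test report
#'
#' Runs the full battery over a per-site log-likelihood matrix: total
#' log-likelihood, deficit from the best tree (`deltal`, a raw
#' difference), one-sided KH p-value of each tree against the best tree,
#' SH p-value, expected likelihood weight, and AU p-value. A topology is
#' marked rejected (`"-"`) when a test's p-value falls below `alpha`.
#'
#' @param m A [site_lnl_matrix()], or a plain trees-by-sites numeric
#'   matrix.
#' @param alpha Rejection level for the marks (default 0.05).
#' @param B,seed Resampling controls.
#' @return A `toptest_result` tibble: `tree`, `logl`, `deltal`, `p_kh`,
#'   `p_sh`, `c_elw`, `p_au`, `au_degenerate`, plus `alpha`, `B`,
#'   `n_sites` attributes.
#' @examples
#' m <- site_lnl_matrix(rbind(a = c(-2, -3), b = c(-2.5, -3.5)))
#' toptest_report(m, B = 100)
#' @export
toptest_report <- function(m, alpha = 0.05, B = 10000, seed = 1) {
  m <- site_lnl_matrix(m)
  totals <- rowSums(m)
  best <- which.max(totals)
  deltal <- totals[best] - totals
  p_kh <- vapply(seq_len(nrow(m)), function(t) {
    if (t == best) {
      # degenerate self-comparison is skipped; test best against runner-up
      others <- setdiff(seq_len(nrow(m)), best)
      rival <- others[which.max(totals[others])]
    } else {
      rival <- best
    }
    pair <- site_lnl_matrix(unclass(m)[c(best, t_or(t, best, rival)), ,
                                       drop = FALSE])
    kh_pair(pair, target = rownames(m)[t], B = B,
            seed = derive_seed(seed, paste0("kh", t)))
  }, numeric(1))
  p_sh <- sh_test(m, B = B, seed = derive_seed(seed, "sh"))
  c_elw <- elw(m, B = B, seed = derive_seed(seed, "elw"))
  au <- au_test(m, B = B, seed = derive_seed(seed, "au"))
  out <- tibble(
    tree = rownames(m),
    logl = as.numeric(totals),
    deltal = as.numeric(deltal),
    p_kh = p_kh,
    p_sh = as.numeric(p_sh),
    c_elw = as.numeric(c_elw),
    p_au = au$p_au,
    au_degenerate = au$degenerate
  )
  class(out) <- c("toptest_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "B") <- B
  attr(out, "n_sites") <- ncol(m)
  out
}

t_or <- function(t, best, rival) if (t == best) rival else t

# KH p-value for a named target tree within a 2-row matrix whose first row
# is the best tree.
kh_pair <- function(pair, target, B, seed) {
  totals <- rowSums(pair)
  if (identical(pair[1, ], pair[2, ])) return(1)
  delta <- max(totals) - totals[target]
  reps <- rell_resample(pair, B = B, seed = seed)
  d <- (reps[setdiff(rownames(pair), target), ] - reps[target, ])
  d <- d - mean(d)
  mean(d >= delta)
}

mark <- function(p, alpha) ifelse(p < alpha, "-", "+")

#' @export
print.toptest_result <- function(x, ...) {
  alpha <- attr(x, "alpha")
  shown <- dplyr::mutate(
    as_tibble(x),
    p_kh = sprintf("%.4g%s", .data$p_kh, mark(.data$p_kh, alpha)),
    p_sh = sprintf("%.4g%s", .data$p_sh, mark(.data$p_sh, alpha)),
    c_elw = sprintf("%.4g%s", .data$c_elw, mark(.data$c_elw, alpha)),
    p_au = sprintf("%.4g%s", .data$p_au, mark(.data$p_au, alpha))
  )
  cat(sprintf("Topology tests over %d sites (alpha = %g, B = %d)\n",
              attr(x, "n_sites"), alpha, attr(x, "B")))
  print(shown[, c("tree", "logl", "deltal", "p_kh", "p_sh", "c_elw", "p_au")])
  invisible(x)
}

#' @method tidy toptest_result
#' @export
tidy.toptest_result <- function(x, ...) {
  alpha <- attr(x, "alpha")
  as_tibble(x) |>
    dplyr::mutate(
      rejected_kh = .data$p_kh < alpha,
      rejected_sh = .data$p_sh < alpha,
      rejected_au = .data$p_au < alpha
    )
}

#' @method glance toptest_result
#' @export
glance.toptest_result <- function(x, ...) {
  tibble(
    n_trees = nrow(x),
    n_sites = attr(x, "n_sites"),
    B = attr(x, "B"),
    alpha = attr(x, "alpha"),
    best_tree = x$tree[which.max(x$logl)],
    max_deltal = max(x$deltal)
  )
}

#' @method autoplot toptest_result
#' @export
autoplot.toptest_result <- function(object, ...) {
  alpha <- attr(object, "alpha")
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("tree", "p_kh", "p_sh", "p_au")],
    -"tree", names_to = "test", values_to = "p"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tree, y = .data$p,
                                     colour = .data$test)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "p-value", x = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
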