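# Amino-acid substitution models: Poisson (equal rates and frequencies,
# useful for closed-form checks) and LG (Le & Gascuel 2008 general matrix).
# Rate heterogeneity across sites uses the discrete-gamma approximation
# with k equal-probability categories, each category at the mean rate of
# its gamma quantile band; category rates always average to 1.

# Canonical amino-acid state order for general matrices
# (A R N D C Q E G H I L K M F P S T W Y V).
MODEL_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Published LG exchangeabilities (pairwise, combn order over MODEL_STATES)
# and stationary frequencies (Le & Gascuel 2008).
LG_RATES <- c(
    0.425093, 0.276818, 0.395144, 2.489084, 0.969894, 1.038545,
    2.066040, 0.358858, 0.149830, 0.395337, 0.536518, 1.124035,
    0.253701, 1.177651, 4.727182, 2.139501, 0.180717, 0.218959,
    2.547870, 0.751878, 0.123954, 0.534551, 2.807908, 0.363970,
    0.390192, 2.426601, 0.126991, 0.301848, 6.326067, 0.484133,
    0.052722, 0.332533, 0.858151, 0.578987, 0.593607, 0.314440,
    0.170887, 5.076149, 0.528768, 1.695752, 0.541712, 1.437645,
    4.509238, 0.191503, 0.068427, 2.145078, 0.371004, 0.089525,
    0.161787, 4.008358, 2.000679, 0.045376, 0.612025, 0.083688,
    0.062556, 0.523386, 5.243870, 0.844926, 0.927114, 0.010690,
    0.015076, 0.282959, 0.025548, 0.017416, 0.394456, 1.240275,
    0.425860, 0.029890, 0.135107, 0.037967, 0.084808, 0.003499,
    0.569265, 0.640543, 0.320627, 0.594007, 0.013266, 0.893680,
    1.105251, 0.075382, 2.784478, 1.143480, 0.670128, 1.165532,
    1.959291, 4.128591, 0.267959, 4.813505, 0.072854, 0.582457,
    3.234294, 1.672569, 0.035855, 0.624294, 1.223828, 1.080136,
    0.236199, 0.257336, 0.210332, 0.348847, 0.423881, 0.044265,
    0.069673, 1.807177, 0.173735, 0.018811, 0.419409, 0.611973,
    0.604545, 0.077852, 0.120037, 0.245034, 0.311484, 0.008705,
    0.044261, 0.296636, 0.139538, 0.089586, 0.196961, 1.739990,
    0.129836, 0.268491, 0.054679, 0.076701, 0.108882, 0.366317,
    0.697264, 0.442472, 0.682139, 0.508851, 0.990012, 0.584262,
    0.597054, 5.306834, 0.119013, 4.145067, 0.159069, 4.273607,
    1.112727, 0.078281, 0.064105, 1.033739, 0.111660, 0.232523,
    10.649107, 0.137500, 6.312358, 2.592692, 0.249060, 0.182287,
    0.302936, 0.619632, 0.299648, 1.702745, 0.656604, 0.023918,
    0.390322, 0.748683, 1.136863, 0.049906, 0.131932, 0.185202,
    1.798853, 0.099849, 0.346960, 2.020366, 0.696175, 0.481306,
    1.898718, 0.094464, 0.361819, 0.165001, 2.457121, 7.803902,
    0.654683, 1.338132, 0.571468, 0.095131, 0.089613, 0.296501,
    6.472279, 0.248862, 0.400547, 0.098369, 0.140825, 0.245841,
    2.188158, 3.151815, 0.189510, 0.249313)

LG_FREQS <- c(
    0.07906592, 0.05594094, 0.04197696, 0.05305195, 0.01293699, 0.04076696,
    0.07158593, 0.05733694, 0.02235498, 0.06215694, 0.09908090, 0.06459994,
    0.02295098, 0.04230196, 0.04403996, 0.06119694, 0.05328695, 0.01206599,
    0.03415497, 0.06914693)

# 20x20 symmetric exchangeability matrix from a pairwise rate vector in
# combn order: (1,2), (1,3), ..., (1,20), (2,3), ...
lower_to_sym <- function(rates) {
  m <- matrix(0, 20, 20, dimnames = list(MODEL_STATES, MODEL_STATES))
  k <- 1
  for (i in 1:19) {
    for (j in (i + 1):20) {
      m[i, j] <- m[j, i] <- rates[k]
      k <- k + 1
    }
  }
  m
}

#' Discrete-gamma category rates
#'
#' Rates of `k` equal-probability categories of a Gamma(shape, rate = shape)
#' distribution, each category at its conditional mean; the category rates
#' average exactly to 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of categories.
#' @return Numeric vector of length `k`.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(1)
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  k * diff(pgamma(b, shape = alpha + 1, rate = alpha))
}

#' Amino-acid substitution model
#'
#' Builds a reversible rate matrix Q from packaged exchangeabilities and
#' stationary frequencies, scaled to an expected rate of one substitution
#' per site per unit branch length, with optional discrete-gamma rate
#' heterogeneity. The Poisson model (all exchangeabilities and frequencies
#' equal) admits closed-form two-sequence checks; LG is the standard
#' general amino-acid matrix.
#'
#' @param name `"Poisson"` or `"LG"`.
#' @param frequencies `"model"` for the matrix's own frequencies, or a
#'   named numeric vector of 20 frequencies (empirical `+F` style); it is
#'   renormalised to sum to 1.
#' @param gamma_categories Number of discrete-gamma rate categories
#'   (1 disables rate heterogeneity).
#' @param alpha Gamma shape; required when `gamma_categories > 1`.
#' @return A `subst_model` with elements `name`, `states`, `freqs`, `Q`,
#'   eigendecomposition terms, `rates` (category rates) and `alpha`.
#' @export
subst_model <- function(name = c("Poisson", "LG"), frequencies = "model",
                        gamma_categories = 1, alpha = NULL) {
  name <- match.arg(name)
  if (name == "Poisson") {
    S <- matrix(1, 20, 20, dimnames = list(MODEL_STATES, MODEL_STATES))
    diag(S) <- 0
    freqs <- setNames(rep(1 / 20, 20), MODEL_STATES)
  } else {
    S <- lower_to_sym(LG_RATES)
    freqs <- setNames(LG_FREQS, MODEL_STATES)
  }
  if (!identical(frequencies, "model")) {
    stopifnot(is.numeric(frequencies), length(frequencies) == 20)
    if (!is.null(names(frequencies))) frequencies <- frequencies[MODEL_STATES]
    freqs <- setNames(as.numeric(frequencies), MODEL_STATES)
  }
  freqs <- freqs / sum(freqs)
  Q <- S * rep(freqs, each = 20)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  # symmetrised eigendecomposition for P(t) = U1 exp(L t) U2
  d <- sqrt(freqs)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U1 <- eig$vectors / d
  U2 <- t(eig$vectors) * rep(d, each = 20)
  if (gamma_categories > 1 && is.null(alpha)) {
    abort("alpha is required when gamma_categories > 1")
  }
  rates <- if (gamma_categories > 1) {
    discrete_gamma_rates(alpha, gamma_categories)
  } else 1
  structure(
    list(name = name, states = MODEL_STATES, freqs = freqs, Q = Q,
         eigenvalues = eig$values, U1 = U1, U2 = U2,
         rates = rates, alpha = alpha),
    class = "subst_model"
  )
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t r)` for branch length `t` and relative rate `r`,
#' computed from the model's eigendecomposition. Tiny negative entries from
#' round-off are clamped to zero and rows renormalised.
#'
#' @param model A [subst_model()].
#' @param t Branch length (expected substitutions per site), `>= 0`.
#' @param rate Relative rate multiplier (default 1).
#' @return 20x20 row-stochastic matrix in model state order.
#' @export
transition_prob <- function(model, t, rate = 1) {
  if (t < 0) abort("negative branch length")
  P <- model$U1 %*% (exp(model$eigenvalues * t * rate) * model$U2)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Empirical amino-acid frequencies of an alignment
#'
#' @param aln An `aa_alignment` (character matrix, rows = taxa).
#' @return Named frequency vector over the 20 amino acids (gaps ignored).
#' @export
aa_frequencies <- function(aln) {
  res <- table(factor(aln[aln %in% MODEL_STATES], levels = MODEL_STATES))
  freqs <- as.numeric(res) / sum(res)
  setNames(freqs, MODEL_STATES)
}
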