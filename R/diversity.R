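#' Brillouin-type enzyme-diversity index
#'
#' \deqn{D = \frac{1}{N}\left(\log_2 N! - \sum_i \log_2 n_i!\right)}
#' where the `n_i` are the (possibly non-integer average) gene counts of
#' the `s` families and `N` is their sum. Non-integer counts are handled
#' through the log-gamma extension of the factorial,
#' \eqn{\log x! = \log\Gamma(x+1)}. Units: bits per gene.
#'
#' @param n Non-negative numeric vector of per-family (average) gene
#'   counts.
#' @return The diversity D (>= 0; 0 iff a single family carries all genes).
#' @examples
#' diversity_index(c(2, 2))  # (log2(24) - 2) / 4
#' @export
diversity_index <- function(n) {
  stopifnot(all(n >= 0))
  N <- sum(n)
  if (N <= 0) stop("total gene number must be positive")
  (lgamma(N + 1) - sum(lgamma(n + 1))) / (N * log(2))
}

#' One-tailed exact binomial test
#'
#' Exact tail sum of the binomial pmf, as used for copy-number
#' comparisons between biological groups. How a comparison maps onto
#' trials/successes is left to the caller; this is the bare primitive.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability (0 < p0 < 1).
#' @param alternative `"greater"` or `"less"`.
#' @return The exact one-tailed p-value.
#' @export
exact_binomial_test <- function(x, n, p0 = 0.5,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(x >= 0, x <= n, p0 > 0, p0 < 1)
  binom.test(x, n, p = p0, alternative = alternative)$p.value
}

#' One-tailed Fisher's exact test on a 2x2 table
#'
#' Hypergeometric tail on the fixed-margins distribution, as used for
#' enrichment tests between biological groups.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"` or `"less"` (one-tailed).
#' @return The exact one-tailed p-value.
#' @export
fisher_exact <- function(table, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (sum(table) == 0) stop("empty table")
  fisher.test(table, alternative = alternative)$p.value
}

#' Bonferroni adjustment
#'
#' @param p Vector of p-values.
#' @return `min(1, m * p)` with `m = length(p)`.
#' @export
bonferroni_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "bonferroni")
}

# Classical one-way ANOVA F statistics, vectorised over the columns of a
# trait matrix.
.anova_F <- function(X, groups) {
  X <- as.matrix(X)
  g <- as.factor(groups)
  n <- nrow(X)
  a <- nlevels(g)
  gm <- colMeans(X)
  means <- rowsum(X, g) / as.vector(table(g))
  ssb <- colSums(as.vector(table(g)) * sweep(means, 2, gm)^2)
  sst <- colSums(sweep(X, 2, gm)^2)
  ssw <- sst - ssb
  Fv <- (ssb / (a - 1)) / (ssw / (n - a))
  Fv[ssw == 0 & ssb == 0] <- 0
  Fv
}

# ML (GLS) Brownian-motion rate and phylogenetic mean of a trait.
.bm_ml <- function(C, x) {
  Ci <- solve(C)
  one <- rep(1, length(x))
  mu <- as.numeric((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
  r <- x - mu
  sig2 <- as.numeric(t(r) %*% Ci %*% r) / length(x)
  list(mu = mu, sig2 = sig2)
}

#' Phylogenetic ANOVA
#'
#' Classical one-way F statistic for a continuous trait across groups,
#' with the null distribution obtained by simulating the trait under
#' Brownian motion on the tree (rate and mean from their ML/GLS
#' estimates). p = (1 + #\{F_sim >= F_obs\}) / (n_sim + 1).
#'
#' @param tree Time tree (`phylo`).
#' @param trait Named numeric vector over the tips.
#' @param groups Named group labels over the tips (e.g. lifestyles).
#' @param n_sim Number of Brownian-motion null simulations.
#' @param seed RNG seed.
#' @return List with `F`, `p`, `sig2` (the ML Brownian rate) and `mu`.
#' @export
phyl_anova <- function(tree, trait, groups, n_sim = 1000, seed = NULL) {
  trait <- trait[tree$tip.label]
  groups <- as.factor(groups[tree$tip.label])
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  C <- bm_covariance(tree)
  Fobs <- .anova_F(matrix(trait, ncol = 1), groups)
  if (sd(trait) == 0) return(list(F = 0, p = 1, sig2 = 0,
                                  mu = mean(trait)))
  est <- .bm_ml(C, trait)
  with_seed(seed, {
    L <- t(chol(C))
    Z <- matrix(stats::rnorm(length(trait) * n_sim), ncol = n_sim)
    sims <- est$mu + sqrt(est$sig2) * (L %*% Z)
    Fsim <- .anova_F(sims, groups)
    p <- (1 + sum(Fsim >= Fobs)) / (n_sim + 1)
    list(F = as.numeric(Fobs), p = p, sig2 = est$sig2, mu = est$mu)
  })
}
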