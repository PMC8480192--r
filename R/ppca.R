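#' Brownian-motion covariance of a rooted tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances. Symmetric positive semi-definite.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @return Species x species covariance matrix (same unit as the branch
#'   lengths).
#' @export
bm_covariance <- function(tree) {
  # a phylo read by this package always carries a root node; basal
  # polytomies (star trees) are legitimate and give a diagonal block
  ape::vcv.phylo(tree)
}

#' Phylogenetic principal-component analysis
#'
#' PCA computed in the Brownian-motion metric of the tree: with
#' \eqn{C} the species covariance, the phylogenetic (GLS) mean is
#' \eqn{a = (1' C^{-1} 1)^{-1} 1' C^{-1} X}, the evolutionary covariance
#' \eqn{R = (X - 1a)' C^{-1} (X - 1a) / (n - 1)} is eigendecomposed, and
#' species scores are \eqn{S = (X - 1a) V}. Covariance mode by default;
#' correlation mode standardises by the square roots of `diag(R)`.
#'
#' @param tree Time tree.
#' @param X Species x feature numeric matrix (e.g. gene-family counts);
#'   rows matched to tips by name.
#' @param mode `"cov"` (default) or `"corr"`.
#' @param ridge Diagonal ridge added to `C` if it is numerically singular.
#' @return List of class `ppca` with `mean` (a), `R`, `eigenvalues`,
#'   `loadings`, `scores`, and `percent_var`.
#' @export
ppca <- function(tree, X, mode = c("cov", "corr"), ridge = 1e-8) {
  mode <- match.arg(mode)
  X <- as.matrix(X)[tree$tip.label, , drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop("need >= 3 species")
  C <- bm_covariance(tree)
  Ci <- tryCatch(solve(C), error = function(e) {
    warning("singular phylogenetic covariance; adding ridge ", ridge)
    solve(C + diag(ridge, n))
  })
  one <- rep(1, n)
  a <- as.numeric(t(one) %*% Ci %*% X) / as.numeric(t(one) %*% Ci %*% one)
  Xc <- sweep(X, 2, a)
  R <- t(Xc) %*% Ci %*% Xc / (n - 1)
  R <- (R + t(R)) / 2
  if (max(abs(R)) == 0) stop("constant feature matrix (rank 0)")
  if (mode == "corr") {
    sdv <- sqrt(diag(R))
    sdv[sdv == 0] <- 1
    Xc <- sweep(Xc, 2, sdv, "/")
    R <- t(Xc) %*% Ci %*% Xc / (n - 1)
    R <- (R + t(R)) / 2
  }
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  V <- eig$vectors
  # deterministic sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  S <- Xc %*% V
  colnames(S) <- colnames(V) <- paste0("PC", seq_len(ncol(V)))
  rownames(V) <- colnames(X)
  structure(list(mean = a, R = R, eigenvalues = ev, loadings = V,
                 scores = S, percent_var = 100 * ev / sum(ev),
                 mode = mode),
            class = "ppca")
}

#' Project ancestral nodes into the morphospace
#'
#' Maximum-likelihood Brownian-motion ancestral estimates of each score
#' column (the phylomorphospace construction): the root estimate is the
#' GLS phylogenetic mean of the column.
#'
#' @param tree Time tree.
#' @param scores Tip score matrix (tips x components), e.g. from [ppca()].
#' @return Matrix internal nodes x components of ancestral score
#'   estimates, rownames = internal node labels.
#' @details The ML estimate at a node equals the GLS phylogenetic mean
#'   of the tips after re-rooting the tree at that node; computing it
#'   that way handles polytomies (star trees included) exactly.
#' @export
ancestral_scores <- function(tree, scores) {
  scores <- as.matrix(scores)[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  anc <- matrix(NA_real_, tree$Nnode, ncol(scores),
                dimnames = list(tree$node.label, colnames(scores)))
  one <- rep(1, n_tip)
  for (v in seq_len(tree$Nnode)) {
    node <- n_tip + v
    tv <- if (node == root) tree else ape::root(tree, node = node)
    Ci <- solve(ape::vcv.phylo(tv)[tree$tip.label, tree$tip.label])
    w <- as.numeric(t(one) %*% Ci) / as.numeric(t(one) %*% Ci %*% one)
    anc[v, ] <- as.numeric(w %*% scores)
  }
  anc
}

# Squared Euclidean distance matrix.
.sqdist <- function(X) as.matrix(dist(X))^2

# PERMANOVA sums of squares from a squared-distance matrix.
.permanova_F <- function(D2, groups) {
  n <- nrow(D2)
  g <- as.factor(groups)
  a <- nlevels(g)
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ssb <- sst - ssw
  list(F = (ssb / (a - 1)) / (ssw / (n - a)), sst = sst, ssw = ssw)
}

#' PERMANOVA on ordination scores (or a distance matrix)
#'
#' Pseudo-F from the partitioned sums of squared distances (Euclidean on
#' the supplied scores by default), with a complete-label permutation
#' null: p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1).
#'
#' @param x Score matrix (rows = samples), or a `dist` object.
#' @param groups Group labels (named or in row order).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List with `F`, `p`, `df`, and `degenerate` (TRUE when all
#'   pairwise distances vanish, in which case F is `NA`).
#' @export
permanova <- function(x, groups, n_perm = 999, seed = NULL) {
  if (inherits(x, "dist")) {
    D2 <- as.matrix(x)^2
  } else {
    x <- as.matrix(x)
    if (!is.null(rownames(x)) && !is.null(names(groups)))
      groups <- groups[rownames(x)]
    D2 <- .sqdist(x)
  }
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) == 0)) stop("empty group")
  if (all(D2 < .Machine$double.eps * 100)) {
    return(list(F = NA_real_, p = NA_real_,
                df = c(nlevels(g) - 1, nrow(D2) - nlevels(g)),
                degenerate = TRUE))
  }
  obs <- .permanova_F(D2, g)
  with_seed(seed, {
    n <- nrow(D2)
    Fperm <- vapply(seq_len(n_perm), function(i)
      .permanova_F(D2, g[sample.int(n)])$F, numeric(1))
    p <- (1 + sum(Fperm >= obs$F)) / (n_perm + 1)
    list(F = obs$F, p = p,
         df = c(nlevels(g) - 1, n - nlevels(g)), degenerate = FALSE)
  })
}

#' Pairwise PERMANOVA with FDR correction
#'
#' Runs [permanova()] on every pair of groups and applies the
#' Benjamini-Hochberg adjustment over all pairs. Pairs are ordered
#' deterministically (sorted group names).
#'
#' @inheritParams permanova
#' @return Data frame with `group1`, `group2`, `F`, `p_raw`, `p_adj`.
#' @export
pairwise_permanova_fdr <- function(x, groups, n_perm = 999, seed = NULL) {
  x <- as.matrix(x)
  if (!is.null(rownames(x)) && !is.null(names(groups)))
    groups <- groups[rownames(x)]
  g <- droplevels(as.factor(groups))
  levs <- sort(levels(g))
  pairs <- combn(levs, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    keep <- g %in% pairs[, i]
    pr <- permanova(x[keep, , drop = FALSE], droplevels(g[keep]),
                    n_perm = n_perm,
                    seed = if (is.null(seed)) NULL else seed + i)
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               F = pr$F, p_raw = pr$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out
}
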