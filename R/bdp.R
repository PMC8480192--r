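#' Birth-death model for gene-family copy numbers
#'
#' A single global rate `lambda` (events per gene per My, birth = death)
#' governs copy-number evolution along the time tree. The state space is
#' truncated at `n_max`; the root prior conditions on family presence at
#' the root (uniform over 1..n_max by default).
#'
#' @param lambda Gain/loss rate per gene per My (>= 0).
#' @param n_max Count-state cap (integer >= 1).
#' @param root_prior Probability vector over states 0..n_max, or the string
#'   `"uniform_present"` (uniform over 1..n_max, zero mass on 0).
#' @return An object of class `bdp_model`.
#' @export
bdp_model <- function(lambda, n_max, root_prior = "uniform_present") {
  stopifnot(lambda >= 0, n_max >= 1, n_max == round(n_max))
  if (identical(root_prior, "uniform_present")) {
    root_prior <- c(0, rep(1 / n_max, n_max))
  }
  stopifnot(length(root_prior) == n_max + 1, all(root_prior >= 0))
  root_prior <- root_prior / sum(root_prior)
  structure(list(lambda = lambda, n_max = as.integer(n_max),
                 root_prior = root_prior),
            class = "bdp_model")
}

#' Transition probability of the linear birth-death count process
#'
#' Probability that a family with `s` gene copies at the start of a branch
#' has `c` copies after time `t`, under equal per-gene birth and death rate
#' `lambda`. With \eqn{\alpha = \lambda t / (1 + \lambda t)}:
#' \deqn{P(c \mid s, t) = \sum_{j=0}^{\min(s,c)} \binom{s}{j}
#'   \binom{s+c-j-1}{s-1} \alpha^{s+c-2j} (1-2\alpha)^j}
#' for s >= 1, with an absorbing zero state: P(0|0,t) = 1.
#'
#' @param s Parent count (>= 0).
#' @param c Child count (>= 0).
#' @param t Elapsed time (My, >= 0).
#' @param lambda Birth = death rate per gene per My.
#' @return A probability in \[0, 1\]. Vectorised over `c`.
#' @export
transition_prob <- function(s, c, t, lambda) {
  stopifnot(s >= 0, all(c >= 0), t >= 0, lambda >= 0)
  if (length(s) != 1 || length(t) != 1) stop("s and t must be scalars")
  alpha <- lambda * t / (1 + lambda * t)
  vapply(c, function(ci) .trans_prob1(s, ci, alpha), numeric(1))
}

.trans_prob1 <- function(s, c, alpha) {
  if (alpha == 0) return(as.numeric(c == s))
  if (s == 0) return(as.numeric(c == 0))
  j <- 0:min(s, c)
  base <- 1 - 2 * alpha
  # signed log-space sum: (1-2*alpha) may be <= 0 when lambda*t > 1
  logmag <- lchoose(s, j) + lchoose(s + c - j - 1, s - 1) +
    (s + c - 2 * j) * log(alpha) +
    ifelse(j == 0, 0, j * log(abs(base)))
  sign <- ifelse(j %% 2 == 1 & base < 0, -1, 1)
  keep <- is.finite(logmag) & !(base == 0 & j > 0)
  if (base == 0) keep <- keep & j == 0
  p <- sum(sign[keep] * exp(logmag[keep]))
  min(max(p, 0), 1)
}

# Single-gene descendant-count distribution over 0..n_max:
# P(1 -> 0) = alpha, P(1 -> c) = (1-alpha)^2 alpha^(c-1) for c >= 1.
.bdp_p1 <- function(alpha, n_max) {
  if (alpha == 0) return(c(0, 1, rep(0, n_max - 1)))
  c(alpha, (1 - alpha)^2 * alpha^(0:(n_max - 1)))
}

# Transition matrix over states 0..n_max for one branch. Row s is the
# s-fold convolution of the single-gene kernel (truncated at n_max), which
# equals the closed-form sum in transition_prob().
transition_matrix <- function(t, lambda, n_max) {
  alpha <- lambda * t / (1 + lambda * t)
  n1 <- n_max + 1L
  P <- matrix(0, n1, n1)
  P[1, 1] <- 1
  if (n_max >= 1) {
    p1 <- .bdp_p1(alpha, n_max)
    row <- p1
    P[2, ] <- row
    s <- 1L
    while (s < n_max) {
      new <- numeric(n1)
      for (i in 0:n_max) {
        if (row[i + 1] == 0) next
        idx <- i:n_max
        new[idx + 1] <- new[idx + 1] + row[i + 1] * p1[idx - i + 1]
      }
      row <- new
      s <- s + 1L
      P[s + 1, ] <- row
    }
  }
  P
}

# Per-edge transition matrices, cached by branch length.
.edge_matrices <- function(tree, lambda, n_max, log = FALSE) {
  lens <- tree$edge.length
  uniq <- unique(lens)
  mats <- lapply(uniq, transition_matrix, lambda = lambda, n_max = n_max)
  if (log) mats <- lapply(mats, function(m) log(m))
  mats[match(lens, uniq)]
}

# Tip partial-likelihood matrix (states x families) builder.
.tip_indicator <- function(counts, n_max) {
  L <- matrix(0, n_max + 1L, length(counts))
  L[cbind(counts + 1L, seq_along(counts))] <- 1
  L
}

#' Log-likelihood of tip counts under the birth-death model
#'
#' Felsenstein pruning (sum-product) over the truncated count states, with
#' the root partial likelihood summed against the model's root prior.
#'
#' @param tree Time tree (`phylo`, branch lengths in My).
#' @param tip_counts Named integer vector of copy numbers, one per tip.
#' @param model A [bdp_model()].
#' @return The log-likelihood (scalar).
#' @export
family_loglik <- function(tree, tip_counts, model) {
  counts <- .match_tip_counts(tree, tip_counts)
  if (any(counts > model$n_max)) stop("tip count exceeds n_max")
  ll <- .bdp_loglik_block(tree, matrix(counts, ncol = 1), model)
  as.numeric(ll)
}

.match_tip_counts <- function(tree, tip_counts) {
  if (is.null(names(tip_counts))) {
    if (length(tip_counts) != length(tree$tip.label))
      stop("unnamed tip_counts must match the number of tips")
    return(as.integer(tip_counts))
  }
  miss <- setdiff(tree$tip.label, names(tip_counts))
  if (length(miss)) stop("tips without counts: ", paste(miss, collapse = ", "))
  as.integer(tip_counts[tree$tip.label])
}

# Vectorised pruning for many families sharing one model.
# counts_mat: tips x families (rows in tree$tip.label order).
.bdp_loglik_block <- function(tree, counts_mat, model, edge_mats = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_fam <- ncol(counts_mat)
  if (is.null(edge_mats))
    edge_mats <- .edge_matrices(tree, model$lambda, model$n_max)
  partial <- vector("list", n_node)
  logscale <- numeric(n_fam)
  for (v in seq_len(n_tip))
    partial[[v]] <- .tip_indicator(counts_mat[v, ], model$n_max)
  # message passing: edges child-before-parent, rescaling each message
  # per family to avoid underflow on large trees
  for (e in postorder_edges(tree)) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    msg <- edge_mats[[e]] %*% partial[[chi]]
    cmax <- apply(msg, 2, max)
    cmax[cmax == 0] <- 1
    msg <- sweep(msg, 2, cmax, "/")
    logscale <- logscale + log(cmax)
    if (is.null(partial[[par]])) partial[[par]] <- msg
    else partial[[par]] <- partial[[par]] * msg
  }
  root <- n_tip + 1L
  lik <- colSums(model$root_prior * partial[[root]])
  log(lik) + logscale
}

#' Maximum-likelihood estimate of the global birth-death rate
#'
#' Maximises the summed family log-likelihoods over `lambda` by bounded
#' one-dimensional search. Each family gets its own state cap
#' (`2 * max(count)`, floor 10) unless `n_max` is supplied.
#'
#' @param tree Time tree.
#' @param counts Species x family count matrix.
#' @param families Optional character vector restricting the fit to a
#'   subset of families.
#' @param n_max Optional shared state cap.
#' @param interval Search interval for lambda (per gene per My).
#' @param tol Absolute tolerance of the optimiser.
#' @return List with `lambda` (the MLE), `loglik` at the optimum, and
#'   `n_max` (named per-family caps used).
#' @export
estimate_lambda <- function(tree, counts, families = colnames(counts),
                            n_max = NULL, interval = c(1e-6, 10),
                            tol = 1e-7) {
  counts <- counts[tree$tip.label, families, drop = FALSE]
  if (all(counts == 0)) stop("all-zero count matrix")
  caps <- if (is.null(n_max)) pmax(2L * apply(counts, 2, max), 10L)
          else setNames(rep(as.integer(n_max), ncol(counts)), colnames(counts))
  names(caps) <- colnames(counts)
  groups <- split(seq_along(caps), caps)
  negll <- function(lambda) {
    tot <- 0
    for (g in groups) {
      nm <- caps[g[1]]
      model <- bdp_model(lambda, nm)
      tot <- tot + sum(.bdp_loglik_block(tree, counts[, g, drop = FALSE], model))
    }
    -tot
  }
  opt <- optimize(negll, interval = interval, tol = tol)
  list(lambda = opt$minimum, loglik = -opt$objective, n_max = caps)
}

#' Joint most-probable ancestral copy numbers (Viterbi)
#'
#' Max-product dynamic program over count states with backtracking; ties
#' are broken toward the smaller count so results are deterministic.
#'
#' @inheritParams family_loglik
#' @return Named integer vector over all nodes (tips carry their observed
#'   counts), with attribute `log_prob`, the joint log-probability of the
#'   assignment (including the root prior).
#' @export
ancestral_counts <- function(tree, tip_counts, model) {
  counts <- .match_tip_counts(tree, tip_counts)
  if (any(counts > model$n_max)) stop("tip count exceeds n_max")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n1 <- model$n_max + 1L
  logP <- .edge_matrices(tree, model$lambda, model$n_max, log = TRUE)
  delta <- matrix(0, n1, n_node)        # best log-prob of subtree given state
  for (v in seq_len(n_tip)) {
    delta[, v] <- -Inf
    delta[counts[v] + 1L, v] <- 0
  }
  ord <- postorder_edges(tree)
  back <- vector("list", length(ord))   # per edge: argmax child state per parent state
  for (ei in seq_along(ord)) {
    e <- ord[ei]
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    m <- logP[[e]] + matrix(delta[, chi], n1, n1, byrow = TRUE)
    best_child <- apply(m, 1, which.max)   # which.max returns first (= smaller count) on ties
    back[[ei]] <- best_child
    contrib <- m[cbind(seq_len(n1), best_child)]
    delta[, par] <- delta[, par] + contrib
  }
  root <- n_tip + 1L
  root_score <- log(model$root_prior) + delta[, root]
  states <- integer(n_node)
  states[root] <- which.max(root_score) - 1L
  # forward pass in parent-before-child edge order
  for (ei in rev(seq_along(ord))) {
    e <- ord[ei]
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    states[chi] <- back[[ei]][states[par] + 1L] - 1L
  }
  out <- setNames(states, node_ids(tree))
  attr(out, "log_prob") <- max(root_score)
  out
}

#' Forward-simulate one family's counts on the tree
#'
#' Draws the root state from the model's root prior and each child state
#' from the analytic transition kernel of its branch, so the simulation is
#' an exact draw from the model used for likelihoods.
#'
#' @inheritParams family_loglik
#' @param n_fam Number of independent families to simulate.
#' @param seed Optional RNG seed.
#' @return Integer matrix nodes x families of counts (all nodes).
#' @export
simulate_bdp_family <- function(tree, model, n_fam = 1, seed = NULL) {
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    P <- .edge_matrices(tree, model$lambda, model$n_max)
    states <- matrix(0L, n_node, n_fam)
    root <- n_tip + 1L
    states[root, ] <- sample.int(model$n_max + 1L, n_fam, replace = TRUE,
                                 prob = model$root_prior) - 1L
    ord <- rev(postorder_edges(tree))   # parent before child
    for (e in ord) {
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      pm <- P[[e]]
      by_state <- split(seq_len(n_fam), states[par, ])
      for (s in names(by_state)) {
        idx <- by_state[[s]]
        pr <- pm[as.integer(s) + 1L, ]
        states[chi, idx] <- sample.int(model$n_max + 1L, length(idx),
                                       replace = TRUE, prob = pr) - 1L
      }
    }
    rownames(states) <- node_ids(tree)
    states
  })
}

#' Family-wide Monte-Carlo p-value for rate heterogeneity
#'
#' Simulates `n_sim` null families under the fitted global rate and
#' compares their log-likelihoods with the observed family's:
#' p = (1 + #\{loglik_sim <= loglik_obs\}) / (n_sim + 1). Small p flags a
#' family whose configuration is unlikely under the global rate, i.e. a
#' fast-evolving family.
#'
#' @inheritParams family_loglik
#' @param n_sim Number of null simulations (>= 1).
#' @param seed RNG seed.
#' @param null_logliks Optional pre-computed null log-likelihoods (shared
#'   across families fitted under the same model), as returned by
#'   [bdp_null_logliks()].
#' @return The p-value in (0, 1].
#' @export
familywide_pvalue <- function(tree, tip_counts, model, n_sim = 1000,
                              seed = NULL, null_logliks = NULL) {
  if (is.null(null_logliks)) {
    if (n_sim < 1) stop("n_sim must be >= 1")
    null_logliks <- bdp_null_logliks(tree, model, n_sim, seed)
  }
  obs <- family_loglik(tree, tip_counts, model)
  (1 + sum(null_logliks <= obs)) / (length(null_logliks) + 1)
}

#' Null distribution of family log-likelihoods
#'
#' Simulates families from the model and returns their log-likelihoods;
#' the same null set can be reused for every family sharing the model.
#'
#' @inheritParams familywide_pvalue
#' @return Numeric vector of length `n_sim`.
#' @export
bdp_null_logliks <- function(tree, model, n_sim = 1000, seed = NULL) {
  sims <- simulate_bdp_family(tree, model, n_fam = n_sim, seed = seed)
  tips <- sims[seq_along(tree$tip.label), , drop = FALSE]
  .bdp_loglik_block(tree, tips, model)
}

#' Per-branch Viterbi p-values
#'
#' For each branch with Viterbi states (s*, c*), the p-value is the total
#' probability of child counts whose transition probability from s* is as
#' small or smaller than that of c*, over the truncated state space:
#' an exact "as-or-less-likely" tail. Small p flags branches with
#' significant expansions or contractions.
#'
#' @inheritParams family_loglik
#' @param anc Optional precomputed [ancestral_counts()] vector.
#' @return Data frame with one row per branch: `parent`, `child`,
#'   `parent_count`, `child_count`, `direction` (expansion / contraction /
#'   none) and `viterbi_p`.
#' @export
viterbi_branch_pvalues <- function(tree, tip_counts, model, anc = NULL) {
  if (is.null(anc)) anc <- ancestral_counts(tree, tip_counts, model)
  P <- .edge_matrices(tree, model$lambda, model$n_max)
  ids <- node_ids(tree)
  out <- data.frame(
    parent = ids[tree$edge[, 1]],
    child = ids[tree$edge[, 2]],
    parent_count = anc[tree$edge[, 1]],
    child_count = anc[tree$edge[, 2]]
  )
  out$direction <- ifelse(out$child_count > out$parent_count, "expansion",
                          ifelse(out$child_count < out$parent_count,
                                 "contraction", "none"))
  out$viterbi_p <- vapply(seq_len(nrow(out)), function(i) {
    row <- P[[i]][out$parent_count[i] + 1L, ]
    pstar <- row[out$child_count[i] + 1L]
    sum(row[row <= pstar + 1e-12])
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Select fast-evolving families
#'
#' @param pvalues Named vector of family-wide p-values.
#' @param alpha Significance cutoff (default 0.01).
#' @return Character vector of family ids with p < alpha, in the input
#'   order (deterministic).
#' @export
classify_fast_families <- function(pvalues, alpha = 0.01) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  names(pvalues)[pvalues < alpha]
}

#' Fit the birth-death model to a whole count matrix
#'
#' Convenience wrapper running the full gene-family evolution stage:
#' global-lambda estimation, per-family ancestral counts, family-wide
#' p-values (with a shared null per state cap) and per-branch Viterbi
#' p-values for the fast families.
#'
#' @inheritParams estimate_lambda
#' @param n_sim Null simulations per family-wide test.
#' @param seed RNG seed for the Monte-Carlo null.
#' @param alpha Family-wide significance cutoff.
#' @return List with elements `lambda`, `loglik`, `family_table`
#'   (loglik + p per family), `ancestral` (nodes x families matrix),
#'   `fast_families`, and `branch_tables` (per fast family).
#' @export
bdp_fit <- function(tree, counts, families = colnames(counts),
                    n_max = NULL, n_sim = 1000, seed = 1, alpha = 0.01) {
  counts <- counts[tree$tip.label, families, drop = FALSE]
  fit <- estimate_lambda(tree, counts, n_max = n_max)
  caps <- fit$n_max
  anc <- matrix(0L, length(node_ids(tree)), ncol(counts),
                dimnames = list(node_ids(tree), colnames(counts)))
  ll <- numeric(ncol(counts))
  p <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    model <- bdp_model(fit$lambda, caps[j])
    ll[j] <- family_loglik(tree, counts[, j], model)
    anc[, j] <- ancestral_counts(tree, counts[, j], model)
  }
  # family-wide test conditions the null on the inferred root count
  # (point root prior), with a shared state cap so log-likelihoods are
  # comparable across families
  cap <- max(caps)
  roots <- anc[length(tree$tip.label) + 1L, ]
  nulls <- list()
  for (j in seq_len(ncol(counts))) {
    r <- roots[j]
    key <- as.character(r)
    rp <- rep(0, cap + 1); rp[r + 1] <- 1
    model_r <- bdp_model(fit$lambda, cap, rp)
    if (is.null(nulls[[key]]))
      nulls[[key]] <- bdp_null_logliks(tree, model_r, n_sim,
                                       seed = seed + r)
    obs <- family_loglik(tree, counts[, j], model_r)
    p[j] <- (1 + sum(nulls[[key]] <= obs)) / (n_sim + 1)
  }
  fam_tab <- data.frame(family = colnames(counts), loglik = ll,
                        family_wide_p = p)
  fast <- classify_fast_families(setNames(p, colnames(counts)), alpha)
  branch <- lapply(setNames(fast, fast), function(f) {
    model <- bdp_model(fit$lambda, caps[f])
    viterbi_branch_pvalues(tree, counts[, f], model, anc = anc[, f])
  })
  list(lambda = fit$lambda, loglik = fit$loglik, n_max = caps,
       family_table = fam_tab, ancestral = anc,
       fast_families = fast, branch_tables = branch)
}
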