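# Shared fixtures and independent oracles used across the test files.

# Small hand-built trees
tree_cherry <- function() read_timetree("(A:1,B:1);")
tree_3tip <- function() read_timetree("((A:1,B:1):1,C:2);")
tree_4tip <- function() read_timetree("((A:1,B:1):1,(C:1,D:1):1);")
tree_5tip <- function() read_timetree("(((A:1,B:1):1,C:2):1,(D:2,E:2):1);")
tree_star <- function(n = 6) {
  read_timetree(paste0("(", paste0("t", seq_len(n), ":1", collapse = ","), ");"))
}

# Independent event-level simulator of the linear birth-death process
# (written here so it does not share code with the package generator).
oracle_gillespie <- function(n0, lambda, t) {
  n <- n0
  clock <- 0
  repeat {
    if (n == 0) return(0L)
    clock <- clock + rexp(1, n * 2 * lambda)
    if (clock > t) return(n)
    n <- n + sample(c(1L, -1L), 1)
  }
}

# Exhaustive-enumeration likelihood oracle: sums the joint probability of
# tip counts over every assignment of internal-node states, using
# transition_prob() only as the per-branch kernel.
oracle_enum_loglik <- function(tree, tip_counts, model) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  states <- 0:model$n_max
  grid <- as.matrix(expand.grid(rep(list(states), n_int)))
  counts <- as.integer(tip_counts[tree$tip.label])
  total <- 0
  for (r in seq_len(nrow(grid))) {
    assign_all <- c(counts, grid[r, ])
    p <- model$root_prior[grid[r, 1] + 1]   # root = first internal node
    for (e in seq_len(nrow(tree$edge))) {
      s <- assign_all[tree$edge[e, 1]]
      cc <- assign_all[tree$edge[e, 2]]
      p <- p * transition_prob(s, cc, tree$edge.length[e], model$lambda)
      if (p == 0) break
    }
    total <- total + as.numeric(p)
  }
  log(total)
}

# Best joint assignment by enumeration (probability of the max-product
# path, including the root prior).
oracle_enum_viterbi <- function(tree, tip_counts, model) {
  n_int <- tree$Nnode
  states <- 0:model$n_max
  grid <- as.matrix(expand.grid(rep(list(states), n_int)))
  counts <- as.integer(tip_counts[tree$tip.label])
  best <- -Inf
  best_assign <- NULL
  for (r in seq_len(nrow(grid))) {
    assign_all <- c(counts, grid[r, ])
    p <- log(model$root_prior[grid[r, 1] + 1])
    for (e in seq_len(nrow(tree$edge))) {
      s <- assign_all[tree$edge[e, 1]]
      cc <- assign_all[tree$edge[e, 2]]
      p <- p + log(transition_prob(s, cc, tree$edge.length[e], model$lambda))
      if (!is.finite(p)) break
    }
    p <- as.numeric(p)
    if (p > best) { best <- p; best_assign <- grid[r, ] }
  }
  list(log_prob = best, internal = best_assign)
}

# Brute-force weighted-kNN oracle with the kernel formulas written out
# longhand.
oracle_wknn <- function(train_X, train_y, query, k, kernel, d) {
  dd <- apply(train_X, 1, function(r) sum(abs(r - query)^d)^(1 / d))
  o <- order(dd)
  dk1 <- dd[o[k + 1]]
  nb <- o[seq_len(k)]
  if (dd[o[k]] >= dk1 - 1e-12) nb <- union(nb, which(abs(dd - dk1) <= 1e-12))
  u <- if (dk1 == 0) rep(0, length(nb)) else pmin(dd[nb] / dk1, 1)
  rk <- rank(dd[nb], ties.method = "first")
  p <- ncol(train_X)
  w <- switch(kernel,
    rectangular = ifelse(u <= 1, 0.5, 0),
    triangular = ifelse(u <= 1, 1 - u, 0),
    epanechnikov = ifelse(u <= 1, 0.75 * (1 - u^2), 0),
    gaussian = exp(-u^2 / 2),
    rank = k + 1 - rk,
    optimal = pmax((1 / k) * (1 + p / 2 - p / (2 * k^(2 / p)) *
                                (rk^(1 + 2 / p) - (rk - 1)^(1 + 2 / p))), 0))
  classes <- sort(unique(train_y))
  tot <- vapply(classes, function(cl) sum(w[train_y[nb] == cl]), numeric(1))
  if (all(tot == 0)) return(train_y[o[1]])
  classes[which.max(tot)]
}

# Marginal root/internal posteriors by exhaustive enumeration on a small
# alphabet, from first principles (matrix exponentials via repeated
# squaring-free eigen calls are avoided: uses the model's P(t) only
# through direct exponential of the generator with Higham-free series).
oracle_asr_posterior <- function(tree, tip_states, alphabet, Q, freqs) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  ns <- length(alphabet)
  Pm <- lapply(tree$edge.length, function(t) {
    # truncated series for expm(Q t); branch lengths are small in tests
    A <- diag(ns); term <- diag(ns)
    for (i in 1:60) { term <- term %*% (Q * t) / i; A <- A + term }
    A
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), n_int)))
  tipidx <- match(tip_states[tree$tip.label], alphabet)
  joint <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    assign_all <- c(tipidx, grid[r, ])
    p <- freqs[grid[r, 1]]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Pm[[e]][assign_all[tree$edge[e, 1]], assign_all[tree$edge[e, 2]]]
    joint[r] <- p
  }
  # marginal posterior per internal node
  post <- matrix(0, n_int, ns)
  for (j in seq_len(n_int))
    for (a in seq_len(ns))
      post[j, a] <- sum(joint[grid[, j] == a])
  sweep(post, 1, rowSums(post), "/")
}

# A well-separated 6-class dataset for classifier checks.
make_clusters <- function(n_per = 10, n_class = 2, gap = 8, p = 2, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(n_class), function(i)
    matrix(rnorm(n_per * p, mean = gap * i), n_per, p)))
  list(X = X, y = rep(LETTERS[seq_len(n_class)], each = n_per))
}
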