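test_that("transition kernel matches its closed forms", {
  expect_equal(transition_prob(3, 3, 0, 0.5), 1)
  expect_equal(transition_prob(3, 2, 0, 0.5), 0)
  # alpha = 1/3 at lambda = 0.5, t = 1
  expect_equal(transition_prob(1, 1, 1, 0.5), 4 / 9, tolerance = 1e-12)
  expect_equal(transition_prob(1, 0, 1, 0.5), 1 / 3, tolerance = 1e-12)
  expect_equal(transition_prob(0, 0, 5, 0.5), 1)
  expect_equal(transition_prob(0, 3, 5, 0.5), 0)
  expect_error(transition_prob(-1, 0, 1, 0.5))
})

test_that("transition matrix rows are near-stochastic and match the sum formula", {
  # truncation loss vanishes when the cap is generous relative to s and
  # lambda*t (the operating regime: lambda*t <= ~0.4 on a dated tree)
  P <- lignodecay:::transition_matrix(0.25, 1, 40)
  for (s in 0:20) {
    expect_gte(sum(P[s + 1, ]), 1 - 1e-6)
    expect_lte(sum(P[s + 1, ]), 1 + 1e-12)
  }
  # rows equal the closed-form sum everywhere, including lambda*t = 1
  for (lt in c(0.1, 0.5, 1)) {
    P2 <- lignodecay:::transition_matrix(lt, 1, 20)
    for (s in c(0, 1, 3, 7, 10))
      expect_equal(P2[s + 1, ], transition_prob(s, 0:20, lt, 1),
                   tolerance = 1e-12)
  }
  # loss shrinks monotonically with the cap
  losses <- vapply(c(20, 30, 40), function(nm)
    1 - sum(lignodecay:::transition_matrix(0.5, 1, nm)[11, ]), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("pruning equals exhaustive enumeration on small trees", {
  model <- bdp_model(0.3, 5)
  trees <- list(tree_3tip(), tree_4tip(), tree_5tip())
  counts <- list(c(A = 2, B = 3, C = 1),
                 c(A = 2, B = 2, C = 4, D = 0),
                 c(A = 1, B = 2, C = 3, D = 5, E = 0))
  for (i in seq_along(trees)) {
    ll <- family_loglik(trees[[i]], counts[[i]], model)
    expect_equal(ll, oracle_enum_loglik(trees[[i]], counts[[i]], model),
                 tolerance = 1e-10)
  }
})

test_that("viterbi reconstruction attains the enumeration optimum", {
  model <- bdp_model(0.3, 5)
  tr <- tree_4tip()
  tc <- c(A = 2, B = 2, C = 4, D = 0)
  anc <- ancestral_counts(tr, tc, model)
  oracle <- oracle_enum_viterbi(tr, tc, model)
  expect_equal(attr(anc, "log_prob"), oracle$log_prob, tolerance = 1e-10)
})

test_that("frozen process (lambda = 0) pins every node to the root state", {
  tr <- tree_4tip()
  rp <- c(0, 0, 0, 1, 0, 0)   # point mass at 3
  model <- bdp_model(0, 5, rp)
  expect_equal(family_loglik(tr, c(A = 3, B = 3, C = 3, D = 3), model), 0)
  expect_equal(family_loglik(tr, c(A = 3, B = 3, C = 2, D = 3), model), -Inf)
  anc <- ancestral_counts(tr, c(A = 3, B = 3, C = 3, D = 3), model)
  expect_true(all(anc == 3))
})

test_that("consensus tips give consensus ancestors at small rates", {
  tr <- tree_4tip()
  model <- bdp_model(0.01, 10)
  anc <- ancestral_counts(tr, c(A = 4, B = 4, C = 4, D = 4), model)
  expect_true(all(anc == 4))
})

test_that("lambda estimation hits the lower bound on constant families", {
  tr <- tree_4tip()
  counts <- matrix(3L, 4, 5, dimnames = list(c("A", "B", "C", "D"),
                                             paste0("f", 1:5)))
  fit <- estimate_lambda(tr, counts)
  expect_lte(fit$lambda, 1e-5)
})

test_that("likelihood at the fitted rate beats nearby rates", {
  tr <- simulate_tree(20, 100, seed = 2)
  model <- bdp_model(0.004, 12)
  tips <- simulate_bdp_family(tr, model, n_fam = 60, seed = 3)[1:20, ]
  colnames(tips) <- paste0("f", 1:60)
  fit <- estimate_lambda(tr, tips, n_max = 12)
  for (lam in fit$lambda * c(0.9, 1.1)) {
    ll <- sum(lignodecay:::.bdp_loglik_block(tr, tips, bdp_model(lam, 12)))
    expect_gte(fit$loglik, ll - 1e-6)
  }
})

test_that("viterbi branch p-values follow the as-or-less-likely tail", {
  tr <- tree_cherry()
  # modal transition at tiny rate: p = 1
  model <- bdp_model(1e-6, 10)
  out <- viterbi_branch_pvalues(tr, c(A = 4, B = 4), model)
  expect_true(all(abs(out$viterbi_p - 1) < 1e-3))
  expect_true(all(out$direction == "none"))

  # hand enumeration: s* = 1, c* = 0, alpha = 1/3
  model2 <- bdp_model(0.5, 15)
  tr2 <- read_timetree("(A:1,B:1);")
  anc <- setNames(c(0L, 0L, 1L), c("A", "B", "N1"))
  out2 <- viterbi_branch_pvalues(tr2, c(A = 0, B = 0), model2, anc = anc)
  probs <- transition_prob(1, 0:15, 1, 0.5)
  expected <- sum(probs[probs <= probs[1] + 1e-12])
  expect_equal(out2$viterbi_p[1], expected, tolerance = 1e-12)
  expect_true(all(out2$viterbi_p > 0 & out2$viterbi_p <= 1))
  expect_equal(out2$direction[1], "contraction")
})

test_that("family-wide p-values are valid and flag planted expansions", {
  tr <- simulate_tree(12, 50, seed = 7)
  model <- bdp_model(0.002, 40)
  # quiet family: all tips near the root state
  quiet <- setNames(rep(3L, 12), tr$tip.label)
  p_quiet <- familywide_pvalue(tr, quiet, model, n_sim = 200, seed = 1)
  expect_gt(p_quiet, 0.05)
  # family with an extreme expansion on one terminal branch
  burst <- quiet
  burst[1] <- 30L
  p_burst <- familywide_pvalue(tr, burst, model, n_sim = 1000, seed = 2)
  expect_lt(p_burst, 0.01)
  expect_gt(p_burst, 0)
})

test_that("fast-family selection applies the alpha cutoff deterministically", {
  expect_identical(classify_fast_families(c(a = 0.5, b = 0.5)), character(0))
  expect_identical(classify_fast_families(c(a = 0.005, b = 0.02)), "a")
  expect_error(classify_fast_families(c(a = 1.5)))
})

test_that("simulation from the kernel is reproducible and respects the root prior", {
  tr <- tree_4tip()
  model <- bdp_model(0.1, 8)
  s1 <- simulate_bdp_family(tr, model, n_fam = 5, seed = 9)
  s2 <- simulate_bdp_family(tr, model, n_fam = 5, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1["N1", ] >= 1))   # uniform-present prior excludes 0
})
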