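test_that("prediction reproduces the worked neighbour example", {
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  m <- wknn_model(X, c("A", "A", "B", "B"), k = 3, kernel = "rectangular",
                  d = 1, scale = FALSE)
  out <- wknn_predict(m, 1.5)
  expect_equal(out$label, "A")
  # neighbours {1, 2, 0} with equal rectangular weight 1/2
  expect_equal(out$A, 1)
  expect_equal(out$B, 0.5)
})

test_that("predictions equal the brute-force kernel oracle on 12-point data", {
  set.seed(20)
  for (rep in 1:3) {
    X <- matrix(rnorm(24), 12, 2)
    y <- sample(c("A", "B", "C"), 12, replace = TRUE)
    queries <- matrix(rnorm(10), 5, 2)
    for (kernel in wknn_kernels()) {
      for (d in c(1, 2)) {
        m <- wknn_model(X, y, k = 4, kernel = kernel, d = d, scale = FALSE)
        got <- wknn_predict(m, queries)$label
        want <- apply(queries, 1, function(q)
          oracle_wknn(X, y, q, k = 4, kernel = kernel, d = d))
        expect_equal(got, unname(want),
                     info = paste(kernel, "d =", d, "rep", rep))
      }
    }
  }
})

test_that("k = 1 is plain nearest neighbour for every kernel", {
  set.seed(21)
  X <- matrix(rnorm(16), 8, 2)
  y <- rep(c("A", "B"), 4)
  q <- matrix(rnorm(6), 3, 2)
  nn <- apply(q, 1, function(z)
    y[which.min(colSums((t(X) - z)^2))])
  for (kernel in wknn_kernels()) {
    m <- wknn_model(X, y, k = 1, kernel = kernel, d = 2, scale = FALSE)
    expect_equal(wknn_predict(m, q)$label, unname(nn), info = kernel)
  }
  # query on a training point
  m1 <- wknn_model(X, y, k = 1, kernel = "triangular", d = 2, scale = FALSE)
  expect_equal(wknn_predict(m1, X[3, , drop = FALSE])$label, y[3])
})

test_that("rectangular kernel reproduces unweighted majority vote", {
  set.seed(22)
  X <- matrix(rnorm(30), 15, 2)
  y <- sample(c("A", "B"), 15, replace = TRUE)
  m <- wknn_model(X, y, k = 5, kernel = "rectangular", d = 2, scale = FALSE)
  q <- matrix(rnorm(8), 4, 2)
  got <- wknn_predict(m, q)$label
  want <- apply(q, 1, function(z) {
    nb <- order(colSums((t(X) - z)^2))[1:5]
    tab <- table(y[nb])
    names(tab)[which.max(tab)]   # ties broken alphabetically, as in the model
  })
  expect_equal(got, unname(want))
})

test_that("loocv is perfect on separable clusters and chance on shuffled labels", {
  cl <- make_clusters(n_per = 10, n_class = 2, gap = 8, seed = 30)
  expect_equal(loocv_accuracy(cl$X, cl$y, k = 3), 1.0)

  set.seed(31)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- sample(rep(letters[1:6], 10))
  acc <- loocv_accuracy(X, y, k = 5)
  # ~ 1/6 within generous binomial error (3.5 sd)
  expect_lt(abs(acc - 1 / 6), 3.5 * sqrt((1 / 6) * (5 / 6) / 60))
})

test_that("loocv equals a fold-by-fold brute-force oracle", {
  set.seed(32)
  X <- matrix(rnorm(24), 12, 2)
  y <- sample(c("A", "B"), 12, replace = TRUE)
  for (kernel in c("rectangular", "gaussian", "rank")) {
    acc <- loocv_accuracy(X, y, k = 3, kernel = kernel, d = 1, scale = FALSE)
    oracle <- mean(vapply(1:12, function(i)
      oracle_wknn(X[-i, ], y[-i], X[i, ], k = 3, kernel = kernel,
                  d = 1) == y[i], logical(1)))
    expect_equal(acc, oracle, info = kernel)
  }
})

test_that("the default tuning grid holds 300 models and selects the best", {
  cl <- make_clusters(n_per = 14, n_class = 2, gap = 6, seed = 33)
  tn <- wknn_tune(cl$X, cl$y)
  expect_equal(nrow(tn$grid), 300)
  expect_equal(max(tn$grid$accuracy), tn$best$accuracy)
  # restricted grid selects the only model
  tn1 <- wknn_tune(cl$X, cl$y, k_grid = 7, kernel_grid = "gaussian",
                   d_grid = 2)
  expect_equal(tn1$best$k, 7)
  expect_equal(tn1$best$kernel, "gaussian")
  expect_equal(tn1$best$d, 2)
})

test_that("tuning ties break toward small k, kernel order, then small d", {
  # constant labels: every model has accuracy 1, so the first grid point
  # in tie-break order must win
  X <- matrix(seq_len(20), ncol = 2)
  y <- rep("A", 10)
  tn <- wknn_tune(X, y, k_grid = c(3, 1), kernel_grid = c("gaussian",
                                                          "rectangular"))
  expect_equal(tn$best$k, 1)
  expect_equal(tn$best$kernel, "rectangular")
  expect_equal(tn$best$d, 1)
})

test_that("prediction is invariant to feature order and affine rescaling", {
  set.seed(34)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("A", "B"), 10)
  q <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("f1", "f2")))
  m <- wknn_model(X, y, k = 5, kernel = "triangular", d = 2)
  base <- wknn_predict(m, q)$label
  # feature order flipped
  m2 <- wknn_model(X[, 2:1], y, k = 5, kernel = "triangular", d = 2)
  expect_equal(wknn_predict(m2, q[, 2:1])$label, base)
  # affine rescale of one feature is absorbed by standardisation
  X3 <- X; X3[, 1] <- 100 * X3[, 1] + 7
  q3 <- q; q3[, 1] <- 100 * q3[, 1] + 7
  m3 <- wknn_model(X3, y, k = 5, kernel = "triangular", d = 2)
  expect_equal(wknn_predict(m3, q3)$label, base)
})

test_that("label noise degrades separable-data accuracy monotonically", {
  cl <- make_clusters(n_per = 15, n_class = 2, gap = 8, seed = 35)
  accs <- vapply(c(0, 6, 12), function(nflip) {
    y <- cl$y
    if (nflip > 0) {
      set.seed(36)
      flip <- sample(length(y), nflip)
      y[flip] <- ifelse(y[flip] == "A", "B", "A")
    }
    loocv_accuracy(cl$X, y, k = 3)
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
})

test_that("ancestral prediction is consistent with direct prediction", {
  cl <- make_clusters(n_per = 8, n_class = 2, gap = 6, seed = 37)
  colnames(cl$X) <- c("f1", "f2")
  m <- wknn_model(cl$X, cl$y, k = 3)
  anc <- cl$X[c(1, 12), , drop = FALSE]
  rownames(anc) <- c("N1", "N2")
  pred <- predict_ancestral_lifestyles(m, anc)
  expect_equal(pred$label, wknn_predict(m, anc)$label)
  # identical ancestral vectors get identical labels
  same <- matrix(rep(cl$X[1, ], 3), 3, byrow = TRUE,
                 dimnames = list(paste0("N", 1:3), c("f1", "f2")))
  expect_equal(length(unique(predict_ancestral_lifestyles(m, same)$label)), 1)
  expect_error(predict_ancestral_lifestyles(m, anc[, 1, drop = FALSE]),
               "feature")
})
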