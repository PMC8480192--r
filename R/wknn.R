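#' Kernel functions for weighted k-nearest-neighbour voting
#'
#' Translates normalised neighbour distances u (distance divided by the
#' (k+1)-th neighbour distance) into voting weights. Available kernels:
#' rectangular 1/2 on \[0,1\]; triangular (1-u); epanechnikov 3/4(1-u^2);
#' gaussian exp(-u^2/2); rank (k+1-rank of the neighbour); optimal
#' (Samworth's asymptotically optimal rank weights, which depend on the
#' feature dimension).
#'
#' @return Character vector of the supported kernel names, in their
#'   canonical (tie-break) order.
#' @export
wknn_kernels <- function() {
  c("rectangular", "triangular", "epanechnikov", "gaussian",
    "rank", "optimal")
}

# weights for one neighbourhood: u = normalised distances (sorted order
# not required), rk = distance ranks (1 = nearest), p = feature dimension
.kernel_weights <- function(kernel, u, rk, k, p) {
  switch(kernel,
    rectangular = 0.5 * (u <= 1),
    triangular = pmax(1 - u, 0),
    epanechnikov = 0.75 * pmax(1 - u^2, 0),
    gaussian = exp(-u^2 / 2),
    rank = k + 1 - rk,
    optimal = {
      # Samworth weights on ranks: w_i = (1/k) [1 + p/2 -
      #   p/(2 k^{2/p}) (i^{1+2/p} - (i-1)^{1+2/p})], floored at 0
      i <- rk
      w <- (1 / k) * (1 + p / 2 -
        p / (2 * k^(2 / p)) * (i^(1 + 2 / p) - (i - 1)^(1 + 2 / p)))
      pmax(w, 0)
    },
    stop("unknown kernel: ", kernel))
}

.minkowski <- function(M, x, d) {
  if (d == 1) return(colSums(abs(t(M) - x)))
  if (d == 2) return(sqrt(colSums((t(M) - x)^2)))
  colSums(abs(t(M) - x)^d)^(1 / d)
}

#' Fit a weighted k-nearest-neighbour model
#'
#' Stores the training data together with the model parameters and the
#' per-feature standardisation (z-score, fitted on the training data
#' only).
#'
#' @param X Training feature matrix (samples x features).
#' @param y Training labels.
#' @param k Number of neighbours (1..n-1).
#' @param kernel One of [wknn_kernels()].
#' @param d Minkowski distance exponent (>= 1); `d = 1` is Manhattan.
#' @param scale Standardise features (z-score) before computing
#'   distances.
#' @return Object of class `wknn_model`.
#' @export
wknn_model <- function(X, y, k = 5, kernel = "rectangular", d = 1,
                       scale = TRUE) {
  X <- as.matrix(X)
  stopifnot(k >= 1, d >= 1, kernel %in% wknn_kernels(),
            nrow(X) == length(y))
  if (k + 1 > nrow(X)) stop("need at least k+1 training points")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  if (!scale) { ctr[] <- 0; scl[] <- 1 }
  structure(list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"),
                 y = as.character(y), k = as.integer(k), kernel = kernel,
                 d = d, center = ctr, scale = scl,
                 classes = sort(unique(as.character(y)))),
            class = "wknn_model")
}

#' Predict with a weighted k-nearest-neighbour model
#'
#' Finds the k nearest training points by Minkowski distance on the
#' standardised features, normalises distances by the (k+1)-th neighbour
#' distance, converts them to weights with the model's kernel and returns
#' the class with the largest summed weight. Distance ties at the
#' (k+1)-th neighbour are included with u = 1. If every weight vanishes
#' the nearest neighbour's label is returned.
#'
#' @param model A [wknn_model()].
#' @param newdata Feature matrix (rows = query points) or a single
#'   feature vector.
#' @return Data frame with `label` plus one weight column per class.
#' @export
wknn_predict <- function(model, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  Z <- sweep(sweep(newdata, 2, model$center), 2, model$scale, "/")
  k <- model$k
  p <- ncol(model$X)
  res <- lapply(seq_len(nrow(Z)), function(i) {
    dd <- .minkowski(model$X, Z[i, ], model$d)
    o <- order(dd)   # stable: ties by training-row order
    dk1 <- dd[o[min(k + 1, length(dd))]]
    tol <- 1e-12 * max(dk1, 1)
    nb <- o[seq_len(k)]
    if (dd[o[k]] >= dk1 - tol) {
      # tie at the (k+1)-th neighbour: include every tied point (u = 1)
      nb <- union(nb, which(abs(dd - dk1) <= tol))
    }
    u <- if (dk1 == 0) rep(0, length(nb)) else pmin(dd[nb] / dk1, 1)
    rk <- rank(dd[nb], ties.method = "first")
    w <- .kernel_weights(model$kernel, u, rk, k, p)
    tot <- vapply(model$classes,
                  function(cl) sum(w[model$y[nb] == cl]), numeric(1))
    if (all(tot == 0)) tot[model$y[o[1]] == model$classes] <- 1
    lab <- model$classes[which.max(tot)]
    c(list(label = lab), as.list(tot))
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  rownames(out) <- rownames(newdata)
  out
}

#' Leave-one-out cross-validated accuracy
#'
#' Each point is predicted from a model fitted (standardisation
#' included) on the remaining points.
#'
#' @inheritParams wknn_model
#' @return Accuracy in \[0, 1\].
#' @export
loocv_accuracy <- function(X, y, k = 5, kernel = "rectangular", d = 1,
                           scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k + 2) stop("too few points for leave-one-out with this k")
  hits <- vapply(seq_len(n), function(i) {
    m <- wknn_model(X[-i, , drop = FALSE], y[-i], k = k, kernel = kernel,
                    d = d, scale = scale)
    wknn_predict(m, X[i, , drop = FALSE])$label == y[i]
  }, logical(1))
  mean(hits)
}

#' Tune the weighted kNN classifier by leave-one-out accuracy
#'
#' Evaluates the full model grid (by default k = 1..25, the six kernels,
#' Minkowski d in \{1, 2\}: 300 models) and selects the most accurate
#' one. Ties are broken toward smaller k, then kernel order as listed in
#' [wknn_kernels()], then smaller d.
#'
#' @inheritParams wknn_model
#' @param k_grid,kernel_grid,d_grid Grid components.
#' @return List of class `wknn_tuning` with `grid` (one row per model
#'   with its LOOCV accuracy), `best` (the selected row) and `model`
#'   (the fitted `wknn_model`).
#' @export
wknn_tune <- function(X, y, k_grid = 1:25, kernel_grid = wknn_kernels(),
                      d_grid = c(1, 2), scale = TRUE) {
  grid <- expand.grid(k = k_grid, kernel = kernel_grid, d = d_grid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # k values too large for leave-one-out on this sample are kept in the
  # grid with NA accuracy so the declared model count is preserved
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    if (nrow(X) < grid$k[i] + 2) return(NA_real_)
    loocv_accuracy(X, y, k = grid$k[i], kernel = grid$kernel[i],
                   d = grid$d[i], scale = scale)
  }, numeric(1))
  if (all(is.na(grid$accuracy))) stop("no feasible model in the grid")
  ord <- order(-grid$accuracy, grid$k,
               match(grid$kernel, wknn_kernels()), grid$d, na.last = TRUE)
  best <- grid[ord[1], ]
  model <- wknn_model(X, y, k = best$k, kernel = best$kernel, d = best$d,
                      scale = scale)
  structure(list(grid = grid, best = best, model = model),
            class = "wknn_tuning")
}

#' Predict ancestral lifestyles from reconstructed repertoires
#'
#' Applies a trained classifier to ancestral gene-count vectors (e.g. the
#' birth-death reconstructions of the fast-evolving families) to label
#' each internal node with a lifestyle.
#'
#' @param model A trained [wknn_model()]; its feature set must match the
#'   columns of `ancestral_X`.
#' @param ancestral_X Internal-node x feature matrix of reconstructed
#'   counts.
#' @return Data frame (rownames = node ids) with the predicted `label`
#'   and per-class weights.
#' @export
predict_ancestral_lifestyles <- function(model, ancestral_X) {
  ancestral_X <- as.matrix(ancestral_X)
  if (ncol(ancestral_X) != ncol(model$X) ||
      (!is.null(colnames(ancestral_X)) && !is.null(colnames(model$X)) &&
       !identical(colnames(ancestral_X), colnames(model$X))))
    stop("ancestral features do not match the model's feature list")
  wknn_predict(model, ancestral_X)
}
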