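# Chemometric batch discrimination: autoscaling, hierarchical clustering
# (squared Euclidean distance, between-groups/average linkage), correlation
# PCA with composite scoring, OPLS-DA (Trygg-Wold) with cross-validated Q2,
# permutation testing and VIP, and pooled two-sample t-tests.

#' Autoscale a data matrix
#'
#' Centers every column to mean 0 and scales to unit sample standard
#' deviation (unit-variance / "UV" scaling).
#'
#' @param m Numeric matrix or data.frame (samples x variables), no missing
#'   values, no constant column.
#' @return Matrix of the same shape with attributes `center` and `scale`.
#' @export
autoscale <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing values not allowed")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) stop("constant column(s): cannot autoscale")
  scale(m)
}

#' Hierarchical clustering with squared Euclidean distance
#'
#' Agglomerative clustering using squared Euclidean distances and
#' between-groups (average) linkage, the pairing used by SPSS's default
#' systematic cluster analysis.
#'
#' @param m Numeric matrix or data.frame (>= 2 samples); row names become
#'   sample labels.
#' @return Object of class `cluster_tree` wrapping the `hclust` result:
#'   `merge`, `height`, `labels`, plus `cut(k)` via [cut_tree()].
#' @export
hcluster <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 samples")
  d2 <- stats::dist(m)^2
  hc <- stats::hclust(d2, method = "average")
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 labels = hc$labels), class = "cluster_tree")
}

#' Cut a cluster tree into k groups
#'
#' @param tree A `cluster_tree`.
#' @param k Number of groups, 1 <= k <= n.
#' @return Named integer vector of group labels.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  stats::cutree(tree$hclust, k = k)
}

#' Correlation-matrix PCA with composite scoring support
#'
#' Eigendecomposition of the correlation matrix of `m`. Loadings are
#' eigenvectors scaled by the square root of their eigenvalue; score
#' coefficients are loadings divided by the eigenvalue (so scores are the
#' standardized regression-style factor scores SPSS prints); component
#' signs are fixed so each component's largest-magnitude loading is
#' positive. Components with eigenvalue > `retain_above` are retained.
#'
#' @param m Data matrix (samples x variables). Autoscaled internally.
#' @param retain_above Eigenvalue retention threshold (default 1, the
#'   Kaiser rule).
#' @return `pca_model`: `eigenvalues`, `contribution_pct`,
#'   `cumulative_pct`, `loadings`, `score_coefficients`, `scores`
#'   (retained components), `retained`.
#' @export
pca <- function(m, retain_above = 1) {
  m <- as.matrix(m)
  z <- autoscale(m)
  p <- ncol(z)
  R <- stats::cor(m)
  es <- eigen(R, symmetric = TRUE)
  lambda <- pmax(es$values, 0)
  keep_nonzero <- lambda > 1e-12
  lambda <- lambda[keep_nonzero]
  vecs <- es$vectors[, keep_nonzero, drop = FALSE]
  # sign convention: largest |loading| positive
  for (j in seq_along(lambda)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  loadings <- sweep(vecs, 2, sqrt(lambda), `*`)
  coefs <- sweep(loadings, 2, lambda, `/`)
  rownames(loadings) <- rownames(coefs) <- colnames(m)
  colnames(loadings) <- colnames(coefs) <- paste0("PC", seq_along(lambda))
  retained <- which(lambda > retain_above)
  scores <- z %*% coefs
  contribution <- 100 * lambda / p
  structure(
    list(eigenvalues = lambda,
         contribution_pct = contribution,
         cumulative_pct = cumsum(contribution),
         loadings = loadings,
         score_coefficients = coefs,
         scores = scores,
         retained = retained),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("Correlation PCA:", length(x$eigenvalues), "components;",
      length(x$retained), "retained (eigenvalue > 1)\n")
  print(data.frame(eigenvalue = round(x$eigenvalues, 3),
                   contribution_pct = round(x$contribution_pct, 3),
                   cumulative_pct = round(x$cumulative_pct, 3)))
  invisible(x)
}

#' Composite PCA score and rank
#'
#' Weighted mean of the retained component scores with the variance
#' contributions as weights: `F = sum(w_i t_i) / sum(w_i)`. Ranks are
#' descending (best composite = rank 1) with ties averaged.
#'
#' @param scores Matrix (samples x retained components) or a `pca_model`
#'   (its retained components are used).
#' @param contributions Per-component variance contributions (%), > 0;
#'   taken from the model when `scores` is a `pca_model`.
#' @return data.frame `composite, rank` (rownames = sample ids).
#' @export
composite_score <- function(scores, contributions = NULL) {
  if (inherits(scores, "pca_model")) {
    model <- scores
    contributions <- model$contribution_pct[model$retained]
    scores <- model$scores[, model$retained, drop = FALSE]
  }
  scores <- as.matrix(scores)
  if (length(contributions) != ncol(scores))
    stop("length of contributions must match number of score columns")
  if (any(contributions <= 0)) stop("contributions must be > 0")
  f <- drop(scores %*% contributions) / sum(contributions)
  data.frame(composite = f, rank = rank(-f), row.names = rownames(scores))
}

# -- OPLS-DA ----------------------------------------------------------------

# One NIPALS-style OPLS round on (X, y): predictive weight from X'y, then
# `n_ortho` orthogonal components peeled off before the final predictive
# component is fit on the filtered X.
opls_fit_core <- function(X, y, n_ortho) {
  X0 <- X
  W_o <- P_o <- T_o <- NULL
  for (i in seq_len(n_ortho)) {
    w <- drop(crossprod(X, y))
    w <- w / sqrt(sum(w^2))
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break # no orthogonal variation left
    w_o <- w_o / nrm
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }
  w <- drop(crossprod(X, y))
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  p <- drop(crossprod(X, t)) / sum(t^2)
  c_coef <- sum(y * t) / sum(t^2)
  list(w = w, t = t, p = p, c = c_coef,
       W_o = W_o, P_o = P_o, T_o = T_o, X_filtered = X, X0 = X0)
}

# Predict y for new (autoscaled) rows with a fitted core model.
opls_predict_core <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (!is.null(fit$W_o)) {
    for (i in seq_len(ncol(fit$W_o))) {
      t_o <- drop(Xnew %*% fit$W_o[, i])
      Xnew <- Xnew - tcrossprod(t_o, fit$P_o[, i])
    }
  }
  drop(Xnew %*% fit$w) * fit$c
}

cv_folds <- function(n, k, seed) {
  k <- min(k, n)
  ord <- sample.int(n) # caller controls the RNG state
  split(ord, rep_len(seq_len(k), n))
}

opls_q2 <- function(X, y, n_ortho, folds) {
  press <- 0
  for (idx in folds) {
    fit <- opls_fit_core(X[-idx, , drop = FALSE], y[-idx], n_ortho)
    pred <- opls_predict_core(fit, X[idx, , drop = FALSE])
    press <- press + sum((y[idx] - pred)^2)
  }
  1 - press / sum(y^2)
}

#' Orthogonal PLS discriminant analysis
#'
#' Fits one predictive component plus orthogonal components (Trygg-Wold
#' decomposition) to an autoscaled X against a centered two-class y.
#' Orthogonal components are added while 7-fold cross-validated Q2 improves
#' by more than `q2_tol` (max `max_ortho`). Fold membership is by sample
#' order after a seeded shuffle.
#'
#' @param m Data matrix (samples x variables); autoscaled internally.
#' @param groups Two-level factor/vector of class labels, or a numeric
#'   vector already coded. Coded internally to +/-1 and centered.
#' @param n_folds Cross-validation folds (default 7, capped at n).
#' @param max_ortho Maximum orthogonal components (default 5).
#' @param q2_tol Minimum Q2 improvement to add a component (default 0.01).
#' @param seed Seed for the fold shuffle (default 1).
#' @return `opls_model`: predictive `weights`/`scores`/`loadings`,
#'   orthogonal `ortho_weights`/`ortho_scores`/`ortho_loadings`, `R2X`,
#'   `R2Y`, `Q2`, `n_ortho`, `vip`, plus the scaled data and coded y
#'   needed for permutation testing.
#' @export
oplsda <- function(m, groups, n_folds = 7, max_ortho = 5, q2_tol = 0.01,
                   seed = 1) {
  m <- as.matrix(m)
  X <- autoscale(m)
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("groups must have exactly 2 levels")
  y <- ifelse(g == levels(g)[1], -1, 1)
  y <- y - mean(y)
  n <- nrow(X)
  set.seed(seed)
  folds <- cv_folds(n, n_folds, seed)
  # grow orthogonal components while CV Q2 improves
  q2 <- opls_q2(X, y, 0, folds)
  n_ortho <- 0
  while (n_ortho < max_ortho) {
    q2_next <- opls_q2(X, y, n_ortho + 1, folds)
    if (!is.finite(q2_next) || q2_next - q2 <= q2_tol) break
    q2 <- q2_next
    n_ortho <- n_ortho + 1
  }
  fit <- opls_fit_core(X, y, n_ortho)
  ssx <- sum(X^2)
  explained <- sum(tcrossprod(fit$t, fit$p)^2)
  if (!is.null(fit$T_o))
    for (i in seq_len(ncol(fit$T_o)))
      explained <- explained + sum(tcrossprod(fit$T_o[, i], fit$P_o[, i])^2)
  r2x <- explained / ssx
  yhat <- fit$t * fit$c
  r2y <- 1 - sum((y - yhat)^2) / sum(y^2)
  model <- structure(
    list(weights = fit$w, scores = fit$t, loadings = fit$p, c = fit$c,
         ortho_weights = fit$W_o, ortho_scores = fit$T_o,
         ortho_loadings = fit$P_o,
         R2X = r2x, R2Y = r2y, Q2 = q2, n_ortho = n_ortho,
         X = X, y = y, folds = folds, seed = seed,
         variable_names = colnames(m)),
    class = "opls_model")
  model$vip <- vip(model)
  model
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS-DA: 1 predictive + %d orthogonal component(s)\n", x$n_ortho))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %.3f\n", x$R2X, x$R2Y, x$Q2))
  invisible(x)
}

#' Class prediction from an OPLS-DA model
#'
#' @param object `opls_model`.
#' @param newdata Optional new data on the original scale; training X when
#'   omitted.
#' @param ... Unused.
#' @return Numeric predicted y (sign gives the class).
#' @export
predict.opls_model <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else
    scale(as.matrix(newdata), center = attr(object$X, "scaled:center"),
          scale = attr(object$X, "scaled:scale"))
  fit <- list(w = object$weights, c = object$c,
              W_o = object$ortho_weights, P_o = object$ortho_loadings)
  opls_predict_core(fit, X)
}

#' Variable importance in projection
#'
#' VIP over the predictive component(s):
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)`, so that
#' `sum(VIP^2) = p`. With a single predictive component this reduces to
#' `sqrt(p) * |w_j|`.
#'
#' @param model A fitted `opls_model`.
#' @return Named numeric vector of VIP values.
#' @export
vip <- function(model) {
  if (!inherits(model, "opls_model")) stop("vip() needs a fitted opls_model")
  w <- model$weights
  p <- length(w)
  out <- sqrt(p * w^2 / sum(w^2))
  names(out) <- model$variable_names
  out
}

#' Permutation test of an OPLS-DA model
#'
#' Permutes the class vector `n_perm` times, refits with the same number of
#' orthogonal components and fold structure, and records the correlation of
#' each permuted y with the original together with the refitted R2Y and Q2.
#' Intercepts are the least-squares lines of R2Y and Q2 against
#' |correlation|, evaluated at correlation 0, with the original model
#' included as the correlation-1 point.
#'
#' @param model A fitted `opls_model`.
#' @param n_perm Number of permutations, >= 20 (the reference workflow uses 200).
#' @param seed RNG seed.
#' @return List of class `opls_permutation`: `R2_intercept`,
#'   `Q2_intercept`, `perm` (data.frame `cor, R2Y, Q2`), `original`
#'   (R2Y, Q2), and `valid` (original Q2 above all permuted Q2 and
#'   Q2 intercept < 0).
#' @export
permutation_test <- function(model, n_perm = 200, seed = 1) {
  stopifnot(inherits(model, "opls_model"))
  if (n_perm < 20) stop("n_perm must be >= 20")
  X <- model$X
  y <- model$y
  set.seed(seed)
  perm <- data.frame(cor = numeric(n_perm), R2Y = numeric(n_perm),
                     Q2 = numeric(n_perm))
  for (i in seq_len(n_perm)) {
    yp <- sample(y)
    fit <- opls_fit_core(X, yp, model$n_ortho)
    yhat <- fit$t * fit$c
    perm$R2Y[i] <- 1 - sum((yp - yhat)^2) / sum(yp^2)
    perm$Q2[i] <- opls_q2(X, yp, model$n_ortho, model$folds)
    perm$cor[i] <- abs(stats::cor(yp, y))
  }
  xs <- c(perm$cor, 1)
  r2s <- c(perm$R2Y, model$R2Y)
  q2s <- c(perm$Q2, model$Q2)
  r2_int <- unname(stats::coef(stats::lm(r2s ~ xs))[1])
  q2_int <- unname(stats::coef(stats::lm(q2s ~ xs))[1])
  structure(
    list(R2_intercept = r2_int, Q2_intercept = q2_int, perm = perm,
         original = c(R2Y = model$R2Y, Q2 = model$Q2),
         valid = model$Q2 > max(perm$Q2) && q2_int < 0),
    class = "opls_permutation")
}

#' Pooled two-sample t-test
#'
#' Student's two-sample t-test with pooled variance (not Welch), two-sided.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List `t, df, p`.
#' @export
ttest_pooled <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs n >= 2")
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
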