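#' Fit a PLS1 regression model by NIPALS
#'
#' Partial least squares regression for a single response, fitted with the
#' classical NIPALS algorithm: at each component the weight vector is the
#' (normalized) covariance between the deflated predictors and the deflated
#' response, scores and loadings are extracted, and both blocks are deflated.
#' Predictors and response are mean-centered; columns are not autoscaled,
#' because spectral channels share a common intensity unit (a documented
#' switch, `scale = TRUE`, enables unit-variance scaling).
#'
#' The regression coefficient vector on the original variable scale is
#' assembled as `b = W (P'W)^{-1} q`; coefficients for every intermediate
#' component count 1..A are retained (`coefficients` matrix), which makes
#' cross-validation over component counts cheap.
#'
#' Columns with zero variance after centering carry no covariance and get a
#' zero weight; they are tolerated (flat baseline channels are routine in
#' emission spectra). If *no* column carries variance, or the response does
#' not covary with any column, the fit is impossible and an error names the
#' offending columns.
#'
#' @param X numeric matrix (n x p), no missing values.
#' @param y numeric response vector, length n.
#' @param ncomp number of latent components A, `1 <= A <= min(n - 1, p)`.
#' @param scale logical; autoscale columns to unit variance (default FALSE).
#' @param tol numerical tolerance for rank exhaustion.
#' @return An object of class `pls_model` with elements `ncomp` (components
#'   actually extracted), `x_mean`, `y_mean`, `x_scale`, `weights` (W),
#'   `loadings` (P), `q` (y-loadings), `projection` (R = W (P'W)^{-1}),
#'   `coefficients` (p x A matrix, column A = coefficient vector using A
#'   components), `intercepts` (length A), `coef` (final coefficient vector)
#'   and `intercept`.
#' @seealso [pls_predict()], [rmsecv()]
#' @export
fit_pls <- function(X, y, ncomp, scale = FALSE, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  if (ncomp < 1) stop("ncomp must be >= 1")
  A <- min(ncomp, n - 1L, p)

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- X - rep(x_mean, each = n)
  if (scale) {
    x_scale <- apply(X, 2, sd)
    x_scale[x_scale < tol] <- 1
    Xc <- Xc / rep(x_scale, each = n)
  } else {
    x_scale <- rep(1, p)
  }
  yc <- y - y_mean

  W <- P <- R <- matrix(0, p, A)
  q <- numeric(A)
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < tol) {
      if (a == 1L) {
        bad <- which(apply(X, 2, function(col) diff(range(col)) == 0))
        if (length(bad) == ncol(X)) {
          stop("degenerate X: all columns have zero variance (columns ",
               paste(head(bad, 10), collapse = ", "),
               if (length(bad) > 10) ", ..." else "", ")")
        }
        stop("degenerate fit: no covariance between X and y",
             if (length(bad)) paste0(" (zero-variance columns: ",
                                     paste(head(bad, 10), collapse = ", "),
                                     if (length(bad) > 10) ", ..." else "", ")")
             else "")
      }
      break
    }
    w <- w / nw
    t_a <- Xc %*% w
    tt <- sum(t_a^2)
    if (tt < tol) break
    p_a <- crossprod(Xc, t_a) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - t_a * q_a
    r <- if (a == 1L) w else
      w - R[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(P[, seq_len(a - 1L), drop = FALSE], w)
    W[, a] <- w
    P[, a] <- p_a
    R[, a] <- r
    q[a] <- q_a
    a_done <- a
  }
  A <- a_done
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  R <- R[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]

  # coefficient path: column a = R[, 1:a] %*% q[1:a]; cumulative sums via an
  # upper-triangular ones matrix (avoids an apply() over p rows)
  Rq <- R * rep(q, each = p)
  U <- upper.tri(matrix(0, A, A), diag = TRUE) * 1
  B <- (Rq %*% U) / x_scale
  intercepts <- y_mean - as.numeric(crossprod(x_mean, B))

  structure(list(
    ncomp = A, requested_ncomp = ncomp,
    x_mean = x_mean, y_mean = y_mean, x_scale = x_scale,
    weights = W, loadings = P, q = q, projection = R,
    coefficients = B, intercepts = intercepts,
    coef = B[, A], intercept = intercepts[A]
  ), class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' Predictions use the coefficient route `yhat = X b + b0`, which is
#' algebraically identical to the latent-variable route (scores times
#' y-loadings); see [pls_scores()] for the latter.
#'
#' @param model a [fit_pls()] object.
#' @param X_new numeric matrix with the training column count.
#' @param ncomp component count to use (default: all fitted components).
#' @return numeric vector of predictions.
#' @export
pls_predict <- function(model, X_new, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_mean)) {
    stop("X_new has ", ncol(X_new), " columns; model was trained on ",
         length(model$x_mean))
  }
  if (ncomp < 1 || ncomp > model$ncomp) stop("ncomp out of fitted range")
  as.numeric(X_new %*% model$coefficients[, ncomp] + model$intercepts[ncomp])
}

#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  pls_predict(object, newdata, ncomp = ncomp)
}

#' Latent-variable scores for new data
#'
#' Computes scores by the genuine NIPALS route — projecting with each weight
#' vector and deflating with each loading in turn — rather than through the
#' pre-assembled projection matrix. Used to verify that the coefficient and
#' latent routes agree.
#'
#' @inheritParams pls_predict
#' @return list with `scores` (n x A) and `predictions` via the latent route.
#' @export
pls_scores <- function(model, X_new, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  n <- nrow(X_new)
  Xc <- (X_new - rep(model$x_mean, each = n)) / rep(model$x_scale, each = n)
  A <- ncomp
  Tm <- matrix(0, n, A)
  for (a in seq_len(A)) {
    t_a <- Xc %*% model$weights[, a]
    Xc <- Xc - tcrossprod(t_a, model$loadings[, a])
    Tm[, a] <- t_a
  }
  list(scores = Tm,
       predictions = as.numeric(Tm %*% model$q[seq_len(A)] + model$y_mean))
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS1 (NIPALS) model:", length(x$x_mean), "variables,",
      x$ncomp, "components\n")
  invisible(x)
}

# K-fold RMSECV over component counts 1..ncomp_max for a fixed fold
# assignment. Internal workhorse shared by rmsecv() and the selectors.
# Returns list(rmsecv = vector over A, best = min over A).
kfold_rmsecv <- function(X, y, ncomp_max, fold_id) {
  n <- nrow(X)
  p <- ncol(X)
  folds <- sort(unique(fold_id))
  a_cap <- ncomp_max
  for (k in folds) a_cap <- min(a_cap, sum(fold_id != k) - 1L, p)
  a_cap <- max(1L, a_cap)
  sse <- numeric(a_cap)
  a_eff <- a_cap
  for (k in folds) {
    tr <- fold_id != k
    fit <- fit_pls(X[tr, , drop = FALSE], y[tr], ncomp = a_cap)
    a_eff <- min(a_eff, fit$ncomp)
    pred <- X[!tr, , drop = FALSE] %*% fit$coefficients +
      rep(fit$intercepts, each = sum(!tr))
    res <- (y[!tr] - pred)^2
    used <- seq_len(fit$ncomp)
    sse[used] <- sse[used] + colSums(res[, used, drop = FALSE])
    if (fit$ncomp < a_cap) { # rank exhausted: reuse last feasible component
      extra <- seq(fit$ncomp + 1L, a_cap)
      sse[extra] <- sse[extra] + sum(res[, fit$ncomp])
    }
  }
  rmse <- sqrt(sse / n)
  list(rmsecv = rmse, best = min(rmse), best_ncomp = which.min(rmse),
       ncomp_max = a_cap)
}

#' Cross-validated RMSECV curve for PLS component selection
#'
#' K-fold cross-validation of the NIPALS PLS model over candidate component
#' counts 1..`ncomp_max`. Fold assignment is drawn once (fixed by `seed`) and
#' shared across all component counts; out-of-fold predictions are pooled
#' into a single RMSECV per component count. `folds = n` gives leave-one-out.
#' The best component count is the smallest one attaining the minimum
#' RMSECV (parsimony tie-break).
#'
#' @inheritParams fit_pls
#' @param ncomp_max largest component count to evaluate; silently capped at
#'   the fold-wise feasible maximum (with a warning when capping occurs).
#' @param folds number of folds, between 2 and n.
#' @param seed RNG seed fixing the fold assignment.
#' @return An object of class `pls_cv`: list with `rmsecv` (vector over
#'   component counts), `best_ncomp`, `folds`, `fold_id`.
#' @export
rmsecv <- function(X, y, ncomp_max = 15, folds = 5, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("folds must be between 2 and n")
  if (!is.null(seed)) set.seed(seed)
  fold_id <- if (folds == n) seq_len(n) else sample(rep_len(seq_len(folds), n))
  res <- kfold_rmsecv(X, y, ncomp_max, fold_id)
  if (res$ncomp_max < ncomp_max) {
    warning("ncomp_max capped at ", res$ncomp_max,
            " by fold-wise feasibility")
  }
  structure(list(rmsecv = res$rmsecv,
                 best_ncomp = res$best_ncomp,
                 best_rmsecv = res$best,
                 folds = folds, fold_id = fold_id),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat("PLS cross-validation (", x$folds, "folds ):",
      length(x$rmsecv), "component counts; best A =", x$best_ncomp,
      "with RMSECV =", format(x$best_rmsecv), "\n")
  invisible(x)
}
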