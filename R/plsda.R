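#' One-hot class indicator matrix
#'
#' @param labels vector of class labels, all members of `classes`.
#' @param classes vector giving the class (column) order.
#' @return 0/1 matrix, one row per label, columns named by class; each row
#'   sums to one.
#' @export
one_hot <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx)) {
    stop("label(s) outside the class set: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, as.character(classes)))
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

#' Fit a PLS-DA model by NIPALS
#'
#' Sequential extraction of latent components on column-centred `X` and a
#' column-centred class-indicator response `Y` (PLS2). Each component's
#' X-weight vector is the NIPALS fixed point — the dominant covariance
#' direction — computed exactly through the small `q x q` eigenproblem
#' instead of by power iteration, followed by the usual score/loading
#' computation and rank-one deflation. Columns of `X`
#' are centred but not scaled: spectra entering band selection are already
#' SNV-standardised per row (`scale = TRUE` switches autoscaling on).
#' Extraction stops early, with the realised component count reported, when a
#' degenerate (zero-variance) component is met.
#'
#' @param X numeric predictor matrix (samples x bands).
#' @param Y numeric response matrix, e.g. from [one_hot()].
#' @param n_latent number of latent variables, `>= 1` and at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param scale autoscale X columns (default `FALSE`).
#' @param tol NIPALS convergence tolerance on the score vector.
#' @return Object of class `plsda`: X/Y means, X-weights `W`, X-loadings
#'   `P`, Y-loadings `C`, score norms, per-component explained Y-variance
#'   `ssy`, regression coefficients `B` (bands x classes) and `intercept`.
#' @export
fit_plsda <- function(X, Y, n_latent, scale = FALSE, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y row counts differ")
  if (n_latent < 1 || n_latent > min(n - 1, p)) {
    stop("n_latent must lie in [1, min(rows - 1, cols)]")
  }
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- apply(X, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
  }
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  Yc <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, n_latent); P <- matrix(0, p, n_latent)
  C <- matrix(0, q, n_latent); tt <- numeric(n_latent); ssy <- numeric(n_latent)
  a <- 0L
  for (comp in seq_len(n_latent)) {
    # dominant-covariance X-weight: the NIPALS fixed point, obtained exactly
    # from the small q x q eigenproblem of M'M with M = Xc'Yc
    M <- crossprod(Xc, Yc)
    if (q == 1L) {
      w <- M[, 1]
    } else {
      ev <- eigen(crossprod(M), symmetric = TRUE)
      if (ev$values[1] < tol^2) break
      w <- drop(M %*% ev$vectors[, 1])
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-150) break
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w  # fix the sign convention
    tvec <- Xc %*% w
    tn <- sum(tvec^2)
    if (tn < 1e-12 * n) break
    cvec <- crossprod(Yc, tvec) / tn
    pvec <- crossprod(Xc, tvec) / tn
    a <- comp
    W[, a] <- w; P[, a] <- pvec; C[, a] <- cvec; tt[a] <- tn
    ssy[a] <- tn * sum(cvec^2)  # ||t c'||_F^2: Y-variance carried by component a
    Xc <- Xc - tvec %*% t(pvec)
    Yc <- Yc - tvec %*% t(cvec)
  }
  if (a == 0L) stop("no latent component could be extracted (degenerate data)")
  if (a < n_latent) {
    warning(sprintf("extraction stopped early: %d of %d components", a, n_latent))
    W <- W[, 1:a, drop = FALSE]; P <- P[, 1:a, drop = FALSE]
    C <- C[, 1:a, drop = FALSE]; tt <- tt[1:a]; ssy <- ssy[1:a]
  }
  Wstar <- W %*% solve(crossprod(P, W))
  B <- sweep(Wstar %*% t(C), 1, x_scale, "/")
  intercept <- y_mean - drop(x_mean %*% B)
  structure(list(n_latent = a, x_mean = x_mean, y_mean = y_mean,
                 x_scale = x_scale, W = W, P = P, C = C, Wstar = Wstar,
                 t_norm2 = tt, ssy = ssy, B = B, intercept = intercept,
                 classes = colnames(Y)),
            class = "plsda")
}

#' Predict from a PLS-DA model
#'
#' @param object a fitted [fit_plsda()] model.
#' @param newdata matrix of spectra (samples x bands).
#' @param ncomp number of components used (default all fitted).
#' @param ... unused.
#' @return Matrix of predicted indicator values (samples x classes).
#' @export
predict.plsda <- function(object, newdata, ncomp = object$n_latent, ...) {
  newdata <- as.matrix(newdata)
  if (ncomp < 1 || ncomp > object$n_latent) stop("invalid ncomp")
  Xc <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_scale, "/")
  Tn <- Xc %*% object$Wstar[, 1:ncomp, drop = FALSE]
  Yhat <- Tn %*% t(object$C[, 1:ncomp, drop = FALSE])
  sweep(Yhat, 2, object$y_mean, "+")
}

#' Predicted class labels
#'
#' @inheritParams predict.plsda
#' @return Character vector of class labels (largest indicator score).
#' @export
plsda_classify <- function(object, newdata, ncomp = object$n_latent) {
  Yhat <- predict(object, newdata, ncomp = ncomp)
  object$classes[max.col(Yhat, ties.method = "first")]
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a ssy_a * (w_ja / ||w_a||)^2 / sum_a ssy_a)` with
#' `p` bands, component X-weights `w_a` and per-component explained
#' Y-variance `ssy_a`. The squares of the scores average to one:
#' `sum(VIP^2) = p`.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return Numeric vector of nonnegative per-band VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  if (sum(model$ssy) <= 0) stop("zero total explained Y-variance")
  W <- model$W
  p <- nrow(W)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  drop(sqrt(p * (wn %*% model$ssy) / sum(model$ssy)))
}

#' Choose the number of latent variables by Monte-Carlo cross-validation
#'
#' For every candidate component count `1..max_lv`, the mean held-out RMSE
#' over `runs` random splits at `fraction` training ratio is computed from a
#' single `max_lv`-component fit per split (predictions accumulate
#' component-wise). Returns the argmin; ties break to the smaller count.
#'
#' @param X predictor matrix.
#' @param Y indicator response matrix.
#' @param max_lv largest candidate component count, >= 1.
#' @param runs number of Monte-Carlo splits (default 1000).
#' @param fraction training fraction per split (default 0.8).
#' @param seed optional RNG seed (caller's RNG state is preserved).
#' @return Integer: chosen number of latent variables, with attribute
#'   `rmse` holding the per-candidate mean held-out RMSE.
#' @export
choose_n_latent <- function(X, Y, max_lv, runs = 1000, fraction = 0.8, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  n_train <- floor(fraction * n)
  if (max_lv < 1) stop("max_lv must be >= 1")
  if (n_train < 2 || n_train >= n) stop("too few samples for an MCCV split")
  body <- function() {
    max_lv <- min(max_lv, n_train - 1, ncol(X))
    sse <- numeric(max_lv); m <- 0
    for (r in seq_len(runs)) {
      tr <- sample.int(n, n_train)
      fit <- suppressWarnings(fit_plsda(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], max_lv))
      Xc <- sweep(sweep(X[-tr, , drop = FALSE], 2, fit$x_mean), 2, fit$x_scale, "/")
      Tn <- Xc %*% fit$Wstar
      Yhat <- matrix(rep(fit$y_mean, each = nrow(Xc)), nrow(Xc))
      for (a in seq_len(fit$n_latent)) {
        Yhat <- Yhat + Tn[, a, drop = FALSE] %*% t(fit$C[, a, drop = FALSE])
        sse[a] <- sse[a] + sum((Yhat - Y[-tr, , drop = FALSE])^2)
      }
      if (fit$n_latent < max_lv) {  # degenerate fit: reuse last prediction
        for (a in (fit$n_latent + 1):max_lv) sse[a] <- sse[a] + sum((Yhat - Y[-tr, ])^2)
      }
      m <- m + length(Y[-tr, ])
    }
    rmse <- sqrt(sse / m)
    # smallest count within tolerance of the minimum (ties -> fewer LVs)
    tol <- 1e-10 + 1e-8 * min(rmse)
    best <- min(which(rmse <= min(rmse) + tol))
    structure(as.integer(best), rmse = rmse)
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}
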