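# Five classification algorithms behind one fit/score contract so the
# evaluation machinery can treat them interchangeably. Every model exposes
# a continuous class-1 score (probability where available, decision value
# otherwise -- AUC is rank-based so either works) and a default decision
# threshold for sensitivity/specificity.

#' Describe a classifier
#'
#' Defaults: RF 100 trees with `sqrt(p)` candidate features per split;
#' SVM with RBF kernel, `C = 1`, `gamma = 1/(p * var(X))`; KNN with
#' `k = 5` and Euclidean distance; Gaussian naive Bayes; LDA with
#' automatic (Ledoit-Wolf) shrinkage of the pooled covariance. All
#' overridable through `...`.
#'
#' @param algorithm one of `"RF"`, `"SVM"`, `"KNN"`, `"NB"`, `"LDA"`.
#' @param seed integer seed (consumed by the stochastic fitters, RF).
#' @param ... hyperparameter overrides: `ntree`, `mtry` (RF); `cost`,
#'   `gamma` (SVM); `k` (KNN); `var_smoothing` (NB); `shrinkage` (LDA,
#'   `"auto"` or a number in `[0, 1]`).
#' @return list with class `ClassifierSpec`.
#' @export
classifierSpec <- function(algorithm = c("RF", "SVM", "KNN", "NB", "LDA"),
                           seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  hp <- list(...)
  defaults <- switch(algorithm,
    RF = list(ntree = 100L, mtry = NULL),
    SVM = list(cost = 1, gamma = NULL),
    KNN = list(k = 5L),
    NB = list(var_smoothing = 1e-9),
    LDA = list(shrinkage = "auto"))
  bad <- setdiff(names(hp), names(defaults))
  stopifnot2(length(bad) == 0,
             sprintf("invalid hyperparameters for %s: %s", algorithm,
                     paste(bad, collapse = ", ")))
  defaults[names(hp)] <- hp
  structure(c(list(algorithm = algorithm, seed = as.integer(seed)),
              defaults),
            class = "ClassifierSpec")
}

#' Classifier algorithm names of the model grid
#' @return character vector.
#' @export
classifierAlgorithms <- function() c("RF", "SVM", "KNN", "NB", "LDA")

# Ledoit-Wolf shrinkage of a covariance estimated from centered rows Xc
# toward the scaled identity tr(S)/p * I.
.ledoitWolf <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2) / p
  if (d2 < 1e-300) return(list(Sigma = diag(max(m, 1e-12), p), gamma = 1))
  b2bar <- 0
  for (i in seq_len(n)) {
    xi <- Xc[i, ]
    b2bar <- b2bar + sum((tcrossprod(xi) - S)^2)
  }
  b2bar <- b2bar / (n^2 * p)
  b2 <- min(b2bar, d2)
  gamma <- b2 / d2
  list(Sigma = gamma * diag(m, p) + (1 - gamma) * S, gamma = gamma)
}

.fitLDA <- function(X, y, shrinkage = "auto") {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  # globally constant columns carry no discriminant information; giving
  # them weight zero keeps the fit (and the score ordering) invariant to
  # padding the design with constant features
  keep <- apply(X, 2, function(v) any(v != v[1]))
  w <- rep(0, ncol(X))
  if (!any(keep)) return(list(w = w, b = log(n1 / n0)))
  Xk <- X[, keep, drop = FALSE]
  mu0 <- colMeans(Xk[y == 0, , drop = FALSE])
  mu1 <- colMeans(Xk[y == 1, , drop = FALSE])
  Xc <- rbind(sweep(Xk[y == 0, , drop = FALSE], 2, mu0),
              sweep(Xk[y == 1, , drop = FALSE], 2, mu1))
  if (identical(shrinkage, "auto")) {
    Sigma <- .ledoitWolf(Xc)$Sigma
  } else {
    p <- ncol(Xk)
    S <- crossprod(Xc) / nrow(Xc)
    m <- sum(diag(S)) / p
    Sigma <- shrinkage * diag(max(m, 1e-12), p) + (1 - shrinkage) * S
  }
  w[keep] <- solve(Sigma, mu1 - mu0)
  b <- -sum(w[keep] * (mu0 + mu1)) / 2 + log(n1 / n0)
  list(w = w, b = b)
}

.fitNB <- function(X, y, var_smoothing = 1e-9) {
  eps <- var_smoothing * max(apply(X, 2, var), 1e-12)
  byClass <- lapply(c(0, 1), function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Xc),
         var = apply(Xc, 2, function(v) mean((v - mean(v))^2)) + eps,
         logprior = log(nrow(Xc) / nrow(X)))
  })
  names(byClass) <- c("0", "1")
  byClass
}

.nbLogLik <- function(nb, X, cl) {
  prm <- nb[[as.character(cl)]]
  ll <- rep(prm$logprior, nrow(X))
  for (j in seq_len(ncol(X))) {
    ll <- ll - 0.5 * log(2 * pi * prm$var[j]) -
      (X[, j] - prm$mu[j])^2 / (2 * prm$var[j])
  }
  ll
}

.knnScores <- function(Xtr, ytr, Xte, k) {
  kk <- min(k, nrow(Xtr))
  apply(Xte, 1, function(x) {
    dd <- sqrt(colSums((t(Xtr) - x)^2))
    nb <- order(dd, seq_along(dd))[seq_len(kk)]  # index tie-break: stable
    mean(ytr[nb])
  })
}

#' Fit a classifier under the uniform contract
#'
#' @param spec a [classifierSpec()].
#' @param X_train samples-by-features numeric matrix with column names.
#' @param y_train binary 0/1 labels; both classes must be present (guard
#'   degenerate bootstrap resamples before calling).
#' @return A `TrainedModel` list: `spec`, `features`, fitted state, and a
#'   default decision `threshold` on the score scale.
#' @export
fitClassifier <- function(spec, X_train, y_train) {
  X_train <- as.matrix(X_train)
  if (is.null(colnames(X_train)))
    colnames(X_train) <- sprintf("x%d", seq_len(ncol(X_train)))
  y <- as.integer(y_train)
  stopifnot2(length(unique(y)) == 2,
             "training labels must contain both classes")
  fit <- switch(spec$algorithm,
    RF = {
      mtry <- spec$mtry %||% max(1L, floor(sqrt(ncol(X_train))))
      withLocalSeed(spec$seed,
        randomForest::randomForest(x = X_train,
                                   y = factor(y, levels = c(0, 1)),
                                   ntree = spec$ntree, mtry = mtry))
    },
    SVM = {
      gamma <- spec$gamma %||% 1 / (ncol(X_train) *
                                      max(var(as.numeric(X_train)), 1e-12))
      e1071::svm(x = X_train, y = factor(y, levels = c(0, 1)),
                 kernel = "radial", cost = spec$cost, gamma = gamma,
                 scale = FALSE)
    },
    KNN = list(X = X_train, y = y, k = spec$k),
    NB = .fitNB(X_train, y, spec$var_smoothing),
    LDA = .fitLDA(X_train, y, spec$shrinkage))
  threshold <- if (spec$algorithm == "SVM") 0 else 0.5
  structure(list(spec = spec, features = colnames(X_train), fit = fit,
                 threshold = threshold),
            class = "TrainedModel")
}

#' Continuous class-1 scores for new samples
#'
#' Higher scores mean "more likely to regress" (class 1). Row order is
#' preserved; one finite score per row.
#'
#' @param model a `TrainedModel` from [fitClassifier()].
#' @param X_test samples-by-features matrix whose columns match training.
#' @return numeric score vector.
#' @export
predictScores <- function(model, X_test) {
  X_test <- as.matrix(X_test)
  if (is.null(colnames(X_test)))
    colnames(X_test) <- sprintf("x%d", seq_len(ncol(X_test)))
  stopifnot2(identical(colnames(X_test), model$features),
             "test columns must match training columns")
  spec <- model$spec
  sc <- switch(spec$algorithm,
    RF = as.numeric(predict(model$fit, X_test, type = "prob")[, "1"]),
    SVM = {
      dv <- attr(predict(model$fit, X_test, decision.values = TRUE),
                 "decision.values")
      v <- as.numeric(dv[, 1])
      # decision values are positive toward the level named first
      if (startsWith(colnames(dv)[1], "1")) v else -v
    },
    KNN = .knnScores(model$fit$X, model$fit$y, X_test, model$fit$k),
    NB = {
      l1 <- .nbLogLik(model$fit, X_test, 1)
      l0 <- .nbLogLik(model$fit, X_test, 0)
      1 / (1 + exp(l0 - l1))
    },
    LDA = as.numeric(
      stats::plogis(X_test %*% model$fit$w + model$fit$b)))
  stopifnot2(all(is.finite(sc)), "scores must be finite")
  unname(sc)
}
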