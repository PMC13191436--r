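# From-scratch latent-variable modelling: PCA, OPLS-DA (orthogonal signal
# correction + NIPALS PLS2), cross-validated Q2, VIP, permutation validation.

#' Wide observation-by-variable matrix from a long analyte table
#'
#' Rows are samples (group x replicate), columns are (analyte, form) peaks
#' labelled with `-M`/`-D` suffixes where a form is present.
#'
#' @param table an [analyte_table()].
#' @return list of class `data_matrix`: numeric matrix `X` (rows named
#'   `group.replicate`) and factor `groups`.
#' @export
analyte_matrix <- function(table) {
  stopifnot(inherits(table, "analyte_table"))
  lab <- paste0(table$analyte_id,
                c(none = "", monomer = "-M", dimer = "-D")[table$form])
  rowkey <- paste(table$sample_group,
                  ifelse(is.na(table$replicate), 1L, table$replicate), sep = ".")
  rows <- unique(rowkey)
  cols <- unique(lab)
  X <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  X[cbind(match(rowkey, rows), match(lab, cols))] <- table$value
  if (anyNA(X))
    stop("analyte_matrix: unbalanced table (missing cells)", call. = FALSE)
  groups <- factor(table$sample_group[match(rows, rowkey)])
  structure(list(X = X, groups = groups), class = "data_matrix")
}

.scale_fit <- function(X, scaling) {
  scaling <- match.arg(scaling, c("unit_variance", "pareto", "center", "none"))
  center <- if (scaling == "none") rep(0, ncol(X)) else colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  scl <- switch(scaling,
                unit_variance = ifelse(sdv > 0, sdv, 1),
                pareto = ifelse(sdv > 0, sqrt(sdv), 1),
                center = rep(1, ncol(X)),
                none = rep(1, ncol(X)))
  list(center = center, scale = scl, scaling = scaling)
}

.scale_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

#' Principal component analysis by exact decomposition
#'
#' Components of the centered (and optionally scaled) matrix, in decreasing
#' explained-variance order, via singular value decomposition.
#'
#' @param X numeric matrix or a `data_matrix` (rows = observations).
#' @param n_components number of components (default all).
#' @param scaling `"center"` (default), `"unit_variance"`, `"pareto"` or
#'   `"none"`.
#' @return object of class `pca_model`: `scores`, `loadings` (orthonormal
#'   columns), `explained_variance_fraction`, scaling info.
#' @export
pca <- function(X, n_components = NULL, scaling = "center") {
  if (inherits(X, "data_matrix")) X <- X$X
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_components)) n_components <- kmax
  if (n_components > kmax)
    stop("pca: n_components exceeds min(rows - 1, cols)", call. = FALSE)
  sc <- .scale_fit(X, scaling)
  Xs <- .scale_apply(X, sc)
  total <- sum(Xs^2)
  if (total < 1e-12)
    stop("pca: matrix has no variance", call. = FALSE)
  dec <- svd(Xs)
  k <- seq_len(n_components)
  structure(list(scores = dec$u[, k, drop = FALSE] %*%
                   diag(dec$d[k], n_components),
                 loadings = dec$v[, k, drop = FALSE],
                 explained_variance_fraction = dec$d[k]^2 / sum(dec$d^2),
                 scaling = sc),
            class = "pca_model")
}

# One NIPALS PLS component on (X, Y); Y may have several columns.
.nipals_pls_component <- function(X, Y, tol = 1e-12, maxit = 1000L) {
  u <- Y[, which.max(colSums(Y^2))]
  t_old <- rep(Inf, nrow(X))
  for (i in seq_len(maxit)) {
    w <- crossprod(X, u)[, 1]
    w <- w / sqrt(sum(w^2))
    tt <- X %*% w
    cc <- crossprod(Y, tt)[, 1] / sum(tt^2)
    u <- Y %*% cc / sum(cc^2)
    if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
    t_old <- tt
  }
  p <- crossprod(X, tt)[, 1] / sum(tt^2)
  list(w = w, t = tt[, 1], c = cc, u = u[, 1], p = p)
}

# Core OPLS fit on already-scaled X and centered dummy Y.
.opls_core <- function(Xs, Yc, n_orthogonal, n_predictive) {
  p_var <- ncol(Xs)
  Wo <- Po <- To <- NULL
  Xf <- Xs
  for (k in seq_len(n_orthogonal)) {
    comp <- .nipals_pls_component(Xf, Yc)
    # orthogonalize the loading against span(X'Y) so every orthogonal score
    # is exactly uncorrelated with Y
    B <- crossprod(Xf, Yc)
    Q <- qr.Q(qr(B))
    wo <- comp$p - Q %*% crossprod(Q, comp$p)
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-10) break                       # no orthogonal variation left
    wo <- wo / nrm
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    Xf <- Xf - to %*% t(po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  W <- P <- Tm <- NULL
  C <- NULL
  Xd <- Xf; Yd <- Yc
  ss0 <- sum(Yc^2)
  for (a in seq_len(n_predictive)) {
    if (sum(Yd^2) < 1e-12 * ss0 || sum(Xd^2) < 1e-12) break
    comp <- .nipals_pls_component(Xd, Yd)
    if (sum(comp$t^2) < 1e-12) break
    Xd <- Xd - comp$t %*% t(comp$p)
    Yd <- Yd - comp$t %*% t(comp$c)
    W <- cbind(W, comp$w); P <- cbind(P, comp$p)
    Tm <- cbind(Tm, comp$t); C <- cbind(C, comp$c)
  }
  if (is.null(W))
    stop("fit_oplsda: no predictive component could be extracted", call. = FALSE)
  B <- W %*% solve(crossprod(P, W)) %*% t(C)
  list(W = W, P = P, T = Tm, C = C, Wo = Wo, Po = Po, To = To,
       B = B, X_filtered = Xf, X_residual = Xd, Y_residual = Yd)
}

.remove_orthogonal <- function(Xs, core) {
  if (is.null(core$Wo)) return(Xs)
  for (k in seq_len(ncol(core$Wo))) {
    to <- Xs %*% core$Wo[, k]
    Xs <- Xs - to %*% t(core$Po[, k])
  }
  Xs
}

.dummy_y <- function(groups) {
  groups <- as.factor(groups)
  Y <- stats::model.matrix(~ groups - 1)
  colnames(Y) <- levels(groups)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  Y
}

# Deterministic stratified fold assignment: within each class the (shuffled)
# members are dealt round-robin across folds.
.stratified_folds <- function(groups, k, seed) {
  set.seed(seed)
  fold <- integer(length(groups))
  offset <- 0L
  for (g in levels(as.factor(groups))) {
    idx <- sample(which(groups == g))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  for (f in seq_len(k)) {
    train_groups <- unique(groups[fold != f])
    if (length(train_groups) < length(unique(groups)))
      stop("stratification error: fold ", f,
           " removes an entire class from training", call. = FALSE)
  }
  fold
}

#' Fit an OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis: class labels are
#' dummy-coded (one column per group), variation in X orthogonal to Y is
#' removed by iterative orthogonal signal correction, and the filtered X is
#' modelled with NIPALS PLS2 (one predictive component per Y dimension,
#' fewer if Y is exhausted). Reported statistics: `R2X` and `R2Y` on the
#' training data and `Q2 = 1 - PRESS/SS` under seeded stratified
#' cross-validation (scaling, orthogonal filtering and the regression are
#' refit inside every fold).
#'
#' @param X numeric matrix (rows = observations) or a `data_matrix`.
#' @param y group labels (ignored when `X` is a `data_matrix`, which carries
#'   its own).
#' @param n_orthogonal number of orthogonal components (default 1).
#' @param cv_folds cross-validation folds (default 7, the de-facto default
#'   of commercial OPLS software), stratified by group.
#' @param scaling `"unit_variance"` (default), `"pareto"`, `"center"` or
#'   `"none"`.
#' @param seed seed controlling fold assignment.
#' @return object of class `oplsda` with predictive scores/loadings/weights
#'   (`scores`, `loadings`, `weights`, `y_loadings`), orthogonal
#'   counterparts (`scores_ortho`, `loadings_ortho`, `weights_ortho`),
#'   `R2X`, `R2Y`, `Q2`, `vip`, and bookkeeping needed for prediction.
#' @export
fit_oplsda <- function(X, y = NULL, n_orthogonal = 1, cv_folds = 7,
                       scaling = "unit_variance", seed = 1) {
  if (inherits(X, "data_matrix")) { y <- X$groups; X <- X$X }
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("fit_oplsda: need at least two groups", call. = FALSE)
  if (length(y) != nrow(X))
    stop("fit_oplsda: length(y) != nrow(X)", call. = FALSE)
  if (cv_folds < 2 || cv_folds > nrow(X))
    stop("fit_oplsda: cv_folds must be in [2, n]", call. = FALSE)
  sc <- .scale_fit(X, scaling)
  Xs <- .scale_apply(X, sc)
  Y <- .dummy_y(y)
  ymean <- colMeans(Y)
  Yc <- sweep(Y, 2, ymean)
  core <- .opls_core(Xs, Yc, n_orthogonal, n_predictive = ncol(Yc))
  ssx <- sum(Xs^2)
  R2X <- 1 - sum(core$X_residual^2) / ssx
  R2Y <- 1 - sum(core$Y_residual^2) / sum(Yc^2)

  # cross-validated predictive ability
  fold <- .stratified_folds(y, cv_folds, seed)
  press <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    sc_f <- .scale_fit(X[tr, , drop = FALSE], scaling)
    Xtr <- .scale_apply(X[tr, , drop = FALSE], sc_f)
    Ytr <- .dummy_y(factor(y[tr], levels = levels(y)))
    ymean_f <- colMeans(Ytr)
    core_f <- .opls_core(Xtr, sweep(Ytr, 2, ymean_f), n_orthogonal,
                         n_predictive = ncol(Ytr))
    Xte <- .remove_orthogonal(.scale_apply(X[te, , drop = FALSE], sc_f), core_f)
    Yhat <- sweep(Xte %*% core_f$B, 2, ymean_f, "+")
    press <- press + sum((Y[te, , drop = FALSE] - Yhat)^2)
  }
  Q2 <- 1 - press / sum(Yc^2)

  model <- structure(list(
    scores = core$T, loadings = core$P, weights = core$W, y_loadings = core$C,
    scores_ortho = core$To, loadings_ortho = core$Po, weights_ortho = core$Wo,
    coefficients = core$B, n_orthogonal = if (is.null(core$Wo)) 0L else ncol(core$Wo),
    n_predictive = ncol(core$W),
    R2X = R2X, R2Y = R2Y, Q2 = Q2,
    scaling = sc, y_means = ymean, levels = levels(y), groups = y,
    cv_folds = cv_folds, seed = seed,
    variable_names = colnames(X)), class = "oplsda")
  model$vip <- vip(model)
  model
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("<oplsda> %d predictive + %d orthogonal components, %d groups\n",
              x$n_predictive, x$n_orthogonal, length(x$levels)))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %.3f (%d-fold stratified CV)\n",
              x$R2X, x$R2Y, x$Q2, x$cv_folds))
  invisible(x)
}

#' Predict group membership from an OPLS-DA model
#'
#' @param object an `oplsda` model.
#' @param newdata matrix with the same variables as the training data.
#' @param ... unused.
#' @return list with `y` (predicted dummy responses) and `class` (argmax
#'   group labels).
#' @export
predict.oplsda <- function(object, newdata, ...) {
  Xs <- .scale_apply(as.matrix(newdata), object$scaling)
  core <- list(Wo = object$weights_ortho, Po = object$loadings_ortho)
  Xf <- .remove_orthogonal(Xs, core)
  Yhat <- sweep(Xf %*% object$coefficients, 2, object$y_means, "+")
  colnames(Yhat) <- object$levels
  list(y = Yhat, class = object$levels[max.col(Yhat)])
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` over the
#' predictive components, with unit-norm weight vectors `w_a`, `p` the
#' number of variables and `SSY_a` the Y-variance explained by component
#' `a`. The normalization forces `mean(VIP^2) = 1`, so VIP > 1 flags
#' variables contributing more than average to the discrimination.
#'
#' @param model a fitted `oplsda` model.
#' @return named non-negative numeric vector, one score per variable.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  W <- model$weights
  ssy <- vapply(seq_len(ncol(W)), function(a)
    sum(model$scores[, a]^2) * sum(model$y_loadings[, a]^2), numeric(1))
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  v <- sqrt(nrow(W) * as.numeric(wn2 %*% ssy) / sum(ssy))
  names(v) <- model$variable_names
  v
}

#' Label-permutation validation of an OPLS-DA model
#'
#' Refits the model `n_permutations` times under randomly permuted class
#' labels and records the permuted `R2Y`/`Q2` together with the absolute
#' correlation between the permuted and original dummy responses. The
#' conventional validation-plot intercepts are the least-squares intercepts
#' of each statistic regressed on that correlation, including the
#' unpermuted model as the point at correlation 1. A sound model has an
#' original Q2 far above the permuted distribution and a negative Q2
#' intercept.
#'
#' @param X matrix or `data_matrix`.
#' @param y group labels (taken from `X` when it is a `data_matrix`).
#' @param n_permutations number of permutations (default 200; fewer than 20
#'   triggers a diagnostic warning about unstable intercepts).
#' @param seed seed for the permutations and fold assignment.
#' @param n_orthogonal,cv_folds,scaling passed to [fit_oplsda()].
#' @return object of class `permutation_result`: `R2Y_perm`, `Q2_perm`,
#'   `correlation`, originals, and `intercepts`.
#' @export
permutation_test <- function(X, y = NULL, n_permutations = 200, seed = 1,
                             n_orthogonal = 1, cv_folds = 7,
                             scaling = "unit_variance") {
  if (inherits(X, "data_matrix")) { y <- X$groups; X <- X$X }
  y <- droplevels(as.factor(y))
  if (n_permutations < 20)
    warning("permutation_test: fewer than 20 permutations gives unstable intercepts")
  original <- fit_oplsda(X, y, n_orthogonal = n_orthogonal,
                         cv_folds = cv_folds, scaling = scaling, seed = seed)
  Yc <- scale(.dummy_y(y), scale = FALSE)
  set.seed(seed)
  perms <- lapply(seq_len(n_permutations), function(i) sample(seq_along(y)))
  r2 <- q2 <- rho <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    yp <- y[perms[[i]]]
    m <- fit_oplsda(X, yp, n_orthogonal = n_orthogonal, cv_folds = cv_folds,
                    scaling = scaling, seed = seed + i)
    r2[i] <- m$R2Y; q2[i] <- m$Q2
    Yp <- scale(.dummy_y(yp), scale = FALSE)
    rho[i] <- abs(stats::cor(as.vector(Yc), as.vector(Yp)))
  }
  xx <- c(rho, 1)
  int_r2 <- unname(stats::coef(stats::lm(c(r2, original$R2Y) ~ xx))[1])
  int_q2 <- unname(stats::coef(stats::lm(c(q2, original$Q2) ~ xx))[1])
  structure(list(n_permutations = n_permutations,
                 R2Y_perm = r2, Q2_perm = q2, correlation = rho,
                 R2Y = original$R2Y, Q2 = original$Q2,
                 intercepts = c(R2Y = int_r2, Q2 = int_q2),
                 seed = seed), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations\n", x$n_permutations))
  cat(sprintf("  original R2Y = %.3f, Q2 = %.3f\n", x$R2Y, x$Q2))
  cat(sprintf("  permuted Q2: median %.3f, 95th pct %.3f; intercepts R2Y %.3f, Q2 %.3f\n",
              stats::median(x$Q2_perm), stats::quantile(x$Q2_perm, 0.95),
              x$intercepts["R2Y"], x$intercepts["Q2"]))
  invisible(x)
}
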