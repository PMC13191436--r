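# Independent oracles, deliberately implemented by different algorithms than
# the package code they check.

# PLS2 via per-component SVD of X'Y (mathematically the NIPALS fixed point,
# computed by exact decomposition instead of power iteration)
oracle_pls2 <- function(Xs, Yc, ncomp) {
  Xd <- Xs; Yd <- Yc
  Tm <- Cm <- Wm <- Pm <- NULL
  for (a in seq_len(ncomp)) {
    s <- svd(crossprod(Xd, Yd))
    w <- s$u[, 1]
    tt <- Xd %*% w
    cc <- crossprod(Yd, tt) / sum(tt^2)
    p <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(p)
    Yd <- Yd - tt %*% t(cc)
    Tm <- cbind(Tm, tt); Cm <- cbind(Cm, cc)
    Wm <- cbind(Wm, w); Pm <- cbind(Pm, p)
  }
  list(T = Tm, C = Cm, W = Wm, P = Pm, Yhat = Tm %*% t(Cm))
}

# textbook Pearson r and two-sided t-test p-value from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# NIPALS PCA by power iteration (checks the exact-decomposition route)
oracle_pca_nipals <- function(Xc, k, tol = 1e-12, maxit = 5000) {
  scores <- loadings <- NULL
  Xd <- Xc
  for (a in seq_len(k)) {
    tt <- Xd[, which.max(apply(Xd, 2, stats::var))]
    for (i in seq_len(maxit)) {
      p <- crossprod(Xd, tt) / sum(tt^2)
      p <- p / sqrt(sum(p^2))
      t_new <- Xd %*% p
      if (sqrt(sum((t_new - tt)^2)) < tol * sqrt(sum(t_new^2))) { tt <- t_new; break }
      tt <- t_new
    }
    Xd <- Xd - tt %*% t(p)
    scores <- cbind(scores, tt); loadings <- cbind(loadings, p)
  }
  list(scores = scores, loadings = loadings)
}
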