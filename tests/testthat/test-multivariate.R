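test_that("PCA recovers exact low-rank structure and completes", {
  # rank-1 data: one component carries everything
  set.seed(1)
  t1 <- outer(rnorm(10), c(1, 2, 3))
  p1 <- pca(t1, scaling = "center")
  expect_equal(p1$explained_variance_fraction[1], 1)

  # full decomposition reconstructs the centered matrix
  X <- matrix(rnorm(50), 10, 5)
  m <- pca(X, n_components = 5, scaling = "center")
  rec <- m$scores %*% t(m$loadings)
  expect_lt(max(abs(rec - scale(X, scale = FALSE))), 1e-10)
  expect_lt(max(abs(crossprod(m$loadings) - diag(5))), 1e-8)
  expect_lte(sum(m$explained_variance_fraction), 1 + 1e-12)

  expect_error(pca(matrix(1, 5, 3)), "variance")
  expect_error(pca(X, n_components = 6), "exceeds")
})

test_that("exact-decomposition PCA agrees with a NIPALS oracle", {
  set.seed(7)
  X <- matrix(rnorm(80), 16, 5)
  Xc <- scale(X, scale = FALSE)
  m <- pca(X, n_components = 3, scaling = "center")
  o <- oracle_pca_nipals(Xc, 3)
  for (a in 1:3) {
    sgn <- sign(sum(m$scores[, a] * o$scores[, a]))
    expect_lt(max(abs(m$scores[, a] - sgn * o$scores[, a])), 1e-6)
    expect_lt(max(abs(m$loadings[, a] - sgn * o$loadings[, a])), 1e-6)
  }
})

test_that("two well-separated sensor profiles load on the first two PCs", {
  pr <- expand.grid(sensor = paste0("S", 1:8), group = c("A", "B"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(21)
  pr$mean <- ifelse(pr$group == "A", runif(8, 1, 2), runif(8, 3, 6))
  pr$sd <- 0.05
  en <- simulate_enose(simulation_config(flat_means(2), seed = 13,
                                         enose_profile = pr))
  m <- pca(analyte_matrix(en), scaling = "unit_variance")
  expect_gt(sum(m$explained_variance_fraction[1:2]), 0.85)
})

test_that("OPLS-DA with no orthogonal component equals a PLS oracle", {
  dm <- sim_matrix(biomarker_means(), seed = 31)
  m <- fit_oplsda(dm, n_orthogonal = 0, cv_folds = 5, seed = 31)
  expect_equal(m$n_orthogonal, 0L)
  Xs <- scale(dm$X)
  Y <- outer(as.character(dm$groups), levels(dm$groups), "==") + 0
  Yc <- scale(Y, scale = FALSE)
  o <- oracle_pls2(Xs, Yc, ncomp = m$n_predictive)
  # identical training predictions and scores (up to component sign)
  yhat <- Xs %*% m$coefficients
  expect_lt(max(abs(yhat - o$Yhat)), 1e-8)
  for (a in seq_len(m$n_predictive)) {
    sgn <- sign(sum(m$scores[, a] * o$T[, a]))
    expect_lt(max(abs(m$scores[, a] - sgn * o$T[, a])), 1e-8)
  }
})

test_that("model invariants: orthogonality, weight norms, Q2 <= R2Y, VIP", {
  for (s in c(3, 17)) {
    dm <- sim_matrix(biomarker_means(), seed = s)
    m <- fit_oplsda(dm, n_orthogonal = 2, cv_folds = 7, seed = s)
    # unit-norm predictive weights
    expect_equal(unname(colSums(m$weights^2)),
                 rep(1, m$n_predictive), tolerance = 1e-10)
    # predictive and orthogonal scores mutually orthogonal
    expect_lt(max(abs(crossprod(m$scores, m$scores_ortho))), 1e-6)
    # orthogonal scores exactly uncorrelated with the dummy responses
    Y <- outer(as.character(dm$groups), levels(dm$groups), "==") + 0
    expect_lt(max(abs(stats::cor(m$scores_ortho, Y))), 1e-8)
    # cross-validated fit cannot beat the training fit
    expect_lte(m$Q2, m$R2Y + 1e-8)
    # VIP normalization identity
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  }

  # identical-contribution variables all score VIP = 1
  set.seed(5)
  Xeq <- outer(rnorm(12), rep(1, 4))
  yeq <- factor(rep(c("a", "b"), each = 6))
  meq <- fit_oplsda(Xeq, yeq, n_orthogonal = 0, cv_folds = 3, seed = 1)
  expect_equal(unname(meq$vip), rep(1, 4), tolerance = 1e-8)

  expect_error(fit_oplsda(matrix(rnorm(20), 5), factor(rep("a", 5))),
               "two groups")
})

test_that("fold stratification fails loudly when a class is lost", {
  dm <- sim_matrix(biomarker_means(), seed = 2, n_replicates = 2)
  expect_error(fit_oplsda(dm, cv_folds = 11, seed = 1), "cv_folds")
  m <- fit_oplsda(dm, cv_folds = 2, seed = 1)
  expect_true(is.finite(m$Q2))
  # a singleton class always leaves one training fold without it
  set.seed(8)
  X <- matrix(rnorm(15), 5, 3)
  y <- factor(c("a", "a", "b", "b", "c"))
  expect_error(fit_oplsda(X, y, cv_folds = 2, seed = 1), "stratification")
})

test_that("the fixture-based replicate world mirrors the published model quality", {
  # the study reports R2X 0.982, R2Y 0.990, Q2 0.933 on its (unpublished)
  # replicate data; the simulated stand-in around the printed means/SDs of
  # the key odorants reaches the same regime
  dm <- sim_matrix(fixture_key_means(), seed = 1)
  m <- fit_oplsda(dm, seed = 1)
  expect_gt(m$R2X, 0.85)
  expect_gt(m$R2Y, 0.95)
  expect_gt(m$Q2, 0.7)
  p <- predict(m, dm$X)
  expect_equal(p$class, as.character(dm$groups))
})

test_that("VIP recovery: the discriminating variables carry the top VIPs", {
  hits <- 0
  for (s in 1:50) {
    m <- fit_oplsda(sim_matrix(biomarker_means(), seed = s), seed = s)
    top5 <- names(sort(m$vip, decreasing = TRUE))[1:5]
    if (setequal(top5, paste0("v", 1:5)) &&
        all(m$vip[paste0("v", 1:5)] > 1)) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("permutation testing is seeded and sized correctly", {
  dm <- sim_matrix(biomarker_means(), seed = 9)
  a <- permutation_test(dm, n_permutations = 25, seed = 4)
  b <- permutation_test(dm, n_permutations = 25, seed = 4)
  expect_identical(a$Q2_perm, b$Q2_perm)
  expect_length(a$Q2_perm, 25)
  expect_length(a$correlation, 25)
  expect_warning(permutation_test(dm, n_permutations = 5, seed = 1),
                 "unstable")
})
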