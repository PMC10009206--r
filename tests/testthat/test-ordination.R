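test_that("correlation-matrix PCA has orthonormal loadings and unit variance sum", {
  set.seed(1)
  X <- matrix(rnorm(80), 20, dimnames = list(NULL, paste0("v", 1:4)))
  X[, 2] <- X[, 2] * 100 + 5  # wildly different scale; correlation PCA ignores it
  m <- pca_correlation(X)
  expect_equal(crossprod(m$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(m$variance_proportion), 1, tolerance = 1e-10)
  # score covariance is diagonal with the eigenvalues on the diagonal
  ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  S <- stats::cov(m$scores)
  expect_equal(diag(S), ev, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(S - diag(diag(S)), matrix(0, 4, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("two perfectly correlated variables load entirely on PC1", {
  x <- rnorm(15)
  m <- pca_correlation(cbind(a = x, b = 2 * x + 3))
  expect_equal(m$variance_proportion[1], 1, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCA projection is consistent and independent of fossil rows", {
  set.seed(2)
  X <- matrix(rnorm(60), 15, dimnames = list(paste0("s", 1:15), paste0("v", 1:4)))
  m <- pca_correlation(X)
  # training rows project onto their own scores
  expect_equal(project(m, X), m$scores, tolerance = 1e-10, ignore_attr = TRUE)
  # the extant centroid projects to the origin
  expect_equal(drop(project(m, matrix(m$center, 1,
                                      dimnames = list(NULL, names(m$center))))),
               rep(0, 4), tolerance = 1e-10, ignore_attr = TRUE)
  # a duplicate of an extant taxon lands on identical coordinates
  expect_equal(drop(project(m, X[3, , drop = FALSE])), m$scores[3, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # reconstruction with all components kept
  Z <- scale(X, center = m$center, scale = m$scale)
  expect_equal(m$scores %*% t(m$loadings), Z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # fossil-flagged rows must never enter the fit
  expect_error(pca_correlation(X, fossil = c(rep(FALSE, 14), TRUE)), "fossil")
  expect_error(pca_correlation(cbind(X, k = rep(1, 15))), "constant")
})

test_that("FDA separates separable classes and bounds its axis count", {
  sim <- simulate_class_data(c("a", "b"), 25, rbind(c(0, 0), c(10, 0)),
                             diag(2), seed = 3)
  m <- fda_fit(sim$X, sim$labels)
  expect_equal(ncol(m$centroids), 1L)  # classes - 1
  pred <- attr(discriminant_predict(m, sim$X), "predicted")
  expect_equal(mean(pred != sim$labels), 0)
  sim3 <- simulate_class_data(c("a", "b", "c"), 20,
                              rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0)),
                              diag(3), seed = 4)
  m3 <- fda_fit(sim3$X, sim3$labels)
  expect_lte(ncol(m3$centroids), 2L)
  expect_error(fda_fit(sim$X[1:26, ], factor(c(rep("a", 25), "b"))), "fewer than 2")
})

test_that("FDA predictions agree with the independent LDA oracle", {
  skip_if_not_installed("MASS")
  sim <- simulate_class_data(
    c("a", "b", "c", "d"), 125,
    rbind(c(0, 0, 0), c(2, 0.5, 0), c(0, 2, 1), c(1, 1, 2)),
    matrix(c(1, .3, 0, .3, 1, .2, 0, .2, 1), 3), seed = 5)
  m <- fda_fit(sim$X, sim$labels)
  pred <- attr(discriminant_predict(m, sim$X), "predicted")
  lda_pred <- predict(MASS::lda(sim$X, grouping = sim$labels), sim$X)$class
  expect_gte(mean(as.character(pred) == as.character(lda_pred)), 0.98)
})

test_that("posteriors are proper probabilities responsive to priors", {
  sim <- simulate_class_data(c("a", "b"), 30, rbind(c(0, 0), c(2, 0)),
                             diag(2), seed = 6)
  m <- fda_fit(sim$X, sim$labels)
  set.seed(7)
  Xn <- matrix(rnorm(40), 20, dimnames = list(NULL, colnames(sim$X)))
  post <- discriminant_predict(m, Xn)
  expect_true(all(post >= 0 & post <= 1))
  expect_equal(rowSums(post), rep(1, 20), tolerance = 1e-9, ignore_attr = TRUE)
  # a point at a class centroid gets that class as argmax under equal priors
  meq <- fda_fit(sim$X, sim$labels, priors = c(a = 1, b = 1))
  ctr_b <- m$centroids["b", , drop = FALSE]
  # invert the (1-axis) map at the centroid via a training point close to it
  at_b <- sim$X[which.min(rowSums((project(meq, sim$X) -
                                     ctr_b[rep(1, 60), ])^2)), , drop = FALSE]
  expect_equal(as.character(attr(discriminant_predict(meq, at_b), "predicted")), "b")
  # doubling a prior strictly increases that class's posterior everywhere
  m2 <- fda_fit(sim$X, sim$labels, priors = c(a = 1, b = 2))
  p1 <- discriminant_predict(meq, Xn)
  p2 <- discriminant_predict(m2, Xn)
  expect_true(all(p2$b > p1$b))
})

test_that("FDA posteriors are invariant to variable reordering", {
  sim <- simulate_class_data(c("a", "b", "c"), 20,
                             rbind(c(0, 0, 0), c(3, 1, 0), c(1, 3, 2)),
                             diag(3), seed = 8)
  m1 <- fda_fit(sim$X, sim$labels)
  m2 <- fda_fit(sim$X[, c(3, 1, 2)], sim$labels)
  Xn <- matrix(rnorm(30), 10, dimnames = list(NULL, colnames(sim$X)))
  p1 <- discriminant_predict(m1, Xn)
  p2 <- discriminant_predict(m2, Xn[, c(3, 1, 2)])
  expect_equal(as.matrix(p1), as.matrix(p2), tolerance = 1e-8)
})

test_that("pFDA with identity-like covariance reproduces FDA exactly", {
  tr <- random_ultrametric(30, 9)
  C <- bm_covariance(tr)
  X <- simulate_bm_traits(tr, p = 3, seed = 10)
  labs <- stats::setNames(rep(c("p", "q", "r"), each = 10), rownames(X))
  f_plain <- fda_fit(X, labs[rownames(X)])
  # lambda = 0 on an ultrametric tree
  f0 <- pfda_fit(X, labs, C, lambda = 0)
  Xn <- matrix(rnorm(12), 4, dimnames = list(paste0("f", 1:4), colnames(X)))
  expect_equal(as.matrix(discriminant_predict(f0, Xn)),
               as.matrix(discriminant_predict(f_plain, Xn)), tolerance = 1e-10)
  # C = I exactly
  fI <- pfda_fit(X, labs, diag(nrow(C)), lambda = 1)
  expect_identical(discriminant_predict(fI, Xn)$p,
                   discriminant_predict(f_plain, Xn)$p)
  expect_error(pfda_fit(X, labs, C, lambda = 1.5), "lambda")
})

test_that("optimal_lambda recovers the simulating regime", {
  tr <- random_ultrametric(32, 12)
  C <- bm_covariance(tr)
  grid <- seq(0, 1, by = 0.1)
  set.seed(13)
  star_hits <- mean(replicate(20, {
    optimal_lambda(simulate_bm_traits(tr, 3, lambda_true = 0), C, grid) == 0
  }))
  bm_hits <- mean(replicate(20, {
    optimal_lambda(simulate_bm_traits(tr, 3, lambda_true = 1), C, grid) >= 0.9
  }))
  expect_gte(star_hits, 0.8)
  expect_gte(bm_hits, 0.8)
  expect_equal(optimal_lambda(simulate_bm_traits(tr, 2, seed = 1), C, grid = 0.37), 0.37)
})

test_that("pFDA under strong phylogenetic structure selects a high lambda", {
  tr <- random_ultrametric(28, 14)
  C <- bm_covariance(tr)
  X <- simulate_bm_traits(tr, p = 3, lambda_true = 1, seed = 15)
  labs <- stats::setNames(rep(c("u", "v"), each = 14), rownames(X))
  m <- pfda_fit(X, labs, C, lambda = "optimize", grid = seq(0, 1, 0.05))
  expect_s3_class(m, "fda_model")
  expect_equal(m$method, "pfda")
  expect_gte(m$lambda, 0)
  expect_lte(m$lambda, 1)
})
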