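test_that("K equals 1 on a star phylogeny and errors on constant data", {
  star <- read_newick("(A:2,B:2,C:2,D:2,E:2,F:2);")
  C <- bm_covariance(star)
  set.seed(1)
  for (i in 1:5) {
    y <- stats::setNames(rnorm(6), rownames(C))
    expect_equal(blomberg_k(y, C), 1, tolerance = 1e-9)
  }
  expect_error(blomberg_k(stats::setNames(rep(2, 6), rownames(C)), C), "constant")
})

test_that("K matches the independent picante oracle on random trees", {
  skip_if_not_installed("picante")
  for (seed in 1:8) {
    tr <- random_tree(sample(8:24, 1), seed)
    C <- bm_covariance(tr)
    y <- simulate_bm_traits(tr, p = 1, seed = seed + 100)[, 1]
    expect_equal(blomberg_k(y, C),
                 as.numeric(picante::Kcalc(y[tr$tip.label], tr)),
                 tolerance = 1e-8)
  }
})

test_that("K_mult reduces to univariate K for one-column data", {
  for (seed in 1:5) {
    tr <- random_tree(16, seed)
    C <- bm_covariance(tr)
    Y <- simulate_bm_traits(tr, p = 1, seed = seed + 50)
    expect_equal(k_mult(Y, C, n_perm = 9, seed = 1)$statistic,
                 blomberg_k(Y[, 1], C), tolerance = 1e-10)
  }
})

test_that("K_mult is 1 on a star phylogeny for any data", {
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  C <- bm_covariance(star)
  set.seed(2)
  Y <- matrix(rnorm(15), 5, dimnames = list(rownames(C), NULL))
  expect_equal(k_mult(Y, C, n_perm = 9, seed = 1)$statistic, 1, tolerance = 1e-9)
})

test_that("K_mult permutation p-values are valid and reproducible", {
  tr <- random_ultrametric(20, 4)
  C <- bm_covariance(tr)
  Y <- simulate_bm_traits(tr, p = 2, seed = 5)
  r1 <- k_mult(Y, C, n_perm = 199, seed = 42)
  r2 <- k_mult(Y, C, n_perm = 199, seed = 42)
  expect_identical(r1$permuted_statistics, r2$permuted_statistics)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  expect_lte(r1$p_value, 1)
  expect_length(r1$permuted_statistics, 199)
  # strong Brownian signal on a deep coalescent tree should be detected
  expect_lt(r1$p_value, 0.05)
})

test_that("phylogenetic_hsd detects separation and honors the p-value floor", {
  set.seed(3)
  Y <- rbind(matrix(rnorm(24), 12), matrix(rnorm(24, mean = 10), 12))
  groups <- rep(c("a", "b"), each = 12)
  res <- phylogenetic_hsd(Y, groups, diag(24), n_perm = 1000, seed = 1)
  expect_equal(res$p_values["a", "b"], 1 / 1001)
  expect_gt(res$distances["a", "b"], 9)
  expect_equal(diag(res$p_values), c(a = 1, b = 1))
  expect_equal(diag(res$distances), c(a = 0, b = 0))
  expect_equal(res$p_values, t(res$p_values))

  # identical rows: zero distance, p = 1
  Y2 <- rbind(Y[1:12, ], Y[1:12, ])
  res2 <- phylogenetic_hsd(Y2, groups, diag(24), n_perm = 99, seed = 1)
  expect_equal(unname(res2$distances["a", "b"]), 0, tolerance = 1e-9)
  expect_equal(unname(res2$p_values["a", "b"]), 1)
})

test_that("phylogenetic_hsd with identity covariance matches a plain permutation oracle", {
  # brute-force oracle: distance between group means, residual randomization
  # of the grand-mean model, same permutation convention
  oracle <- function(Y, groups, n_perm, seed) {
    g <- factor(groups)
    means <- rowsum(Y, g) / as.vector(table(g))
    obs <- sqrt(sum((means[1, ] - means[2, ])^2))
    ctr <- colMeans(Y)
    res <- sweep(Y, 2, ctr)
    set.seed(seed)
    perm <- replicate(n_perm, {
      Ys <- sweep(res[sample(nrow(Y)), , drop = FALSE], 2, ctr, `+`)
      m <- rowsum(Ys, g) / as.vector(table(g))
      sqrt(sum((m[1, ] - m[2, ])^2))
    })
    list(d = obs, p = (1 + sum(perm >= obs)) / (1 + n_perm))
  }
  for (seed in 1:6) {
    set.seed(seed)
    n <- 16
    Y <- matrix(rnorm(n * 2, mean = rep(c(0, seed / 4), each = n / 2)), n)
    groups <- rep(c("a", "b"), each = n / 2)
    res <- phylogenetic_hsd(Y, groups, diag(n), n_perm = 499, seed = seed)
    ora <- oracle(Y, groups, 499, seed)
    expect_equal(unname(res$distances["a", "b"]), ora$d, tolerance = 1e-9)
    # same convention and seed, but independent permutation stream: p-values
    # agree within Monte-Carlo error
    expect_lt(abs(res$p_values["a", "b"] - ora$p), 0.1)
  }
})

test_that("singleton groups are dropped with a warning", {
  set.seed(9)
  Y <- matrix(rnorm(10), 5)
  expect_warning(
    res <- phylogenetic_hsd(Y, c("a", "a", "b", "b", "c"), diag(5),
                            n_perm = 19, seed = 1),
    "singleton")
  expect_setequal(res$groups, c("a", "b"))
})

test_that("tukey_hsd matches a direct studentized-range computation", {
  set.seed(11)
  y <- c(rnorm(8, 0), rnorm(10, 1.5), rnorm(7, 0.5))
  g <- rep(c("a", "b", "c"), c(8, 10, 7))
  res <- tukey_hsd(y, g)
  # oracle from first principles: group means, pooled variance, ptukey
  means <- tapply(y, g, mean)
  ni <- tapply(y, g, length)
  df <- length(y) - 3
  s2 <- sum((y - means[g])^2) / df
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    i <- pair[1]; j <- pair[2]
    se <- sqrt(s2 / 2 * (1 / ni[i] + 1 / ni[j]))
    p <- 1 - stats::ptukey(abs(means[i] - means[j]) / se, 3, df)
    expect_equal(unname(res$p_values[i, j]), unname(p), tolerance = 1e-8)
    expect_equal(unname(res$distances[i, j]), unname(abs(means[i] - means[j])),
                 tolerance = 1e-10)
  }
  # identical groups: zero distance, p = 1
  y2 <- rep(c(1, 2, 3), 2)
  res2 <- tukey_hsd(c(y2, y2), rep(c("a", "b"), each = 6))
  expect_equal(unname(res2$distances["a", "b"]), 0)
  expect_equal(unname(res2$p_values["a", "b"]), 1, tolerance = 1e-9)
})

test_that("data and covariance are aligned by taxon names", {
  tr <- random_tree(8, 13)
  C <- bm_covariance(tr)
  Y <- simulate_bm_traits(tr, p = 2, seed = 14)
  shuffled <- Y[sample(rownames(Y)), , drop = FALSE]
  expect_equal(k_mult(shuffled, C, n_perm = 9, seed = 1)$statistic,
               k_mult(Y, C, n_perm = 9, seed = 1)$statistic, tolerance = 1e-12)
  bad <- Y
  rownames(bad)[1] <- "nope"
  expect_error(k_mult(bad, C, n_perm = 9), "match")
})
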