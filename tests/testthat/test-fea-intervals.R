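test_that("mwam is the area-weighted mean, bounded by element extremes", {
  expect_equal(mwam(data.frame(area = 1, strain = 100)), 100)
  expect_equal(mwam(data.frame(area = c(1, 3), strain = c(100, 200))), 175)
  expect_equal(mwam(data.frame(area = c(5, 5), strain = c(42, 42))), 42)
  set.seed(1)
  for (i in 1:10) {
    f <- data.frame(area = runif(50, 0.1, 2), strain = runif(50, 10, 500))
    m <- mwam(f)
    expect_gte(m, min(f$strain))
    expect_lte(m, max(f$strain))
  }
  expect_error(mwam(data.frame(area = numeric(0), strain = numeric(0))), "non-empty")
  expect_error(mwam(data.frame(area = c(1, -1), strain = c(1, 2))), "positive")
})

test_that("interval compositions sum to 100 and match a per-element oracle", {
  set.seed(2)
  fields <- simulate_strain_fields(c(a = 100, b = 220, c = 350), n_elements = 80)
  spec <- interval_spec(fields, 12)
  comp <- interval_composition(fields, spec)
  expect_equal(rowSums(comp), c(a = 100, b = 100, c = 100), tolerance = 1e-9)
  expect_true(all(comp >= 0))
  # brute-force per-element binning oracle
  for (nm in names(fields)) {
    f <- fields[[nm]]
    pct <- numeric(spec$n)
    for (e in seq_len(nrow(f))) {
      k <- NA
      for (j in seq_len(spec$n)) {
        hi_ok <- if (j == spec$n) f$strain[e] <= spec$breaks[j + 1]
                 else f$strain[e] < spec$breaks[j + 1]
        if (f$strain[e] >= spec$breaks[j] && hi_ok) { k <- j; break }
      }
      pct[k] <- pct[k] + f$area[e]
    }
    expect_equal(unname(comp[nm, ]), 100 * pct / sum(f$area), tolerance = 1e-9)
  }
  # single-bin concentration
  one <- list(m = data.frame(area = c(1, 2), strain = c(100, 101)))
  sp1 <- list(lower = 0, upper = 1000, n = 10L, open_upper_tail = FALSE,
              breaks = seq(0, 1000, length.out = 11))
  c1 <- interval_composition(one, sp1)
  expect_equal(unname(c1[1, 2]), 100)
  expect_equal(sum(c1[1, -2]), 0)
})

test_that("compositions are invariant to element order and area scaling", {
  set.seed(3)
  f <- data.frame(area = runif(60, 0.5, 2), strain = runif(60, 50, 400))
  spec <- interval_spec(list(f), 8)
  base <- interval_composition(list(m = f), spec)
  shuf <- interval_composition(list(m = f[sample(60), ]), spec)
  scaled <- interval_composition(list(m = transform(f, area = area * 7)), spec)
  expect_equal(shuf, base, tolerance = 1e-12)
  expect_equal(scaled, base, tolerance = 1e-9)
})

test_that("out-of-range strains error unless the open tail is enabled", {
  f <- list(m = data.frame(area = 1, strain = 500))
  spec <- list(lower = 0, upper = 100, n = 4L, open_upper_tail = FALSE,
               breaks = seq(0, 100, length.out = 5))
  expect_error(interval_composition(f, spec), "above the interval range")
  spec$open_upper_tail <- TRUE
  comp <- interval_composition(f, spec)
  expect_equal(unname(comp[1, 4]), 100)
})

test_that("zero imputation preserves ratios and row sums", {
  comp <- rbind(a = c(50, 50, 0), b = c(20, 30, 50))
  imp <- impute_zeros(comp, delta_fraction = 0.65)
  expect_equal(rowSums(imp), c(a = 100, b = 100), tolerance = 1e-9)
  expect_true(all(imp > 0))
  expect_equal(unname(imp["a", 1] / imp["a", 2]), 1, tolerance = 1e-12)
  expect_equal(unname(imp["a", 3]), 0.65 * 50 * 1, tolerance = 1e-9 * 100)
  expect_identical(imp["b", ], comp["b", ])  # no zeros: unchanged
  expect_error(impute_zeros(rbind(c(0, 0, 0))), "all-zero")
})

test_that("clr rows sum to zero and the transform is scale-invariant", {
  set.seed(4)
  comp <- matrix(runif(30, 0.1, 50), 5)
  comp <- 100 * comp / rowSums(comp)
  z <- clr(comp)
  expect_equal(rowSums(z), rep(0, 5), tolerance = 1e-10)
  expect_equal(clr(3.7 * comp), z, tolerance = 1e-10)
  expect_equal(unname(clr(rbind(rep(25, 4)))), matrix(0, 1, 4))
  expect_error(clr(rbind(c(1, 0, 1))), "positive")
})

test_that("ilr is an isometry with an exact inverse", {
  set.seed(5)
  comp <- matrix(runif(60, 0.5, 40), 10)
  comp <- 100 * comp / rowSums(comp)
  co <- ilr(comp)
  expect_equal(ncol(co), ncol(comp) - 1L)
  expect_equal(unname(ilr(rbind(rep(100 / 6, 6)))), matrix(0, 1, 5),
               tolerance = 1e-10)
  back <- ilr_inverse(co)
  expect_equal(back, comp, tolerance = 1e-9, ignore_attr = TRUE)
  # Aitchison distance (Euclidean on clr) equals Euclidean distance on ilr
  dz <- stats::dist(clr(comp))
  di <- stats::dist(co)
  expect_equal(as.numeric(di), as.numeric(dz), tolerance = 1e-9)
})

test_that("interval convergence finds a stable interval count", {
  set.seed(6)
  fields <- simulate_strain_fields(stats::setNames(seq(80, 400, length.out = 8),
                                                   paste0("m", 1:8)),
                                   n_elements = 120)
  conv <- converge_intervals(fields, start_n = 5, step = 5, max_n = 80,
                             criterion_threshold = 0.95)
  expect_true(conv$converged)
  expect_equal((conv$n - 5) %% 5, 0)
  # duplicated identical models converge immediately (zero distances)
  dup <- list(a = fields[[1]], b = fields[[1]], c = fields[[1]])
  cdup <- converge_intervals(dup, start_n = 4, step = 2, max_n = 10)
  expect_true(cdup$converged)
  expect_equal(cdup$n, 4)
  # raising the criterion can only raise (or keep) the convergence point
  c_lo <- converge_intervals(fields, start_n = 5, step = 5, max_n = 80,
                             criterion_threshold = 0.7)
  if (conv$converged && c_lo$converged) expect_gte(conv$n, c_lo$n)
  expect_error(converge_intervals(fields[1:2]), "at least 3")
})

test_that("the impute -> ilr -> PCA pipeline runs end-to-end on synthetic fields", {
  set.seed(7)
  fields <- simulate_strain_fields(stats::setNames(runif(12, 60, 430),
                                                   paste0("m", 1:12)),
                                   n_elements = 100)
  comp <- interval_composition(fields, interval_spec(fields, 15))
  expect_equal(unname(rowSums(comp)), rep(100, 12), tolerance = 1e-9)
  imp <- impute_zeros(comp)
  expect_equal(unname(rowSums(imp)), rep(100, 12), tolerance = 1e-9)
  co <- ilr(imp)
  keep <- co[, apply(co, 2, stats::sd) > 0, drop = FALSE]
  pca <- pca_correlation(keep)
  expect_equal(nrow(pca$scores), 12L)
})
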