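# Phylogenetic-signal statistics and permutation-based comparison of group
# means. C is always the Brownian-motion covariance from bm_covariance(); all
# permutation p-values use (1 + count >= observed) / (1 + n_perm) so p is
# never 0 and never less than 1/(1 + n_perm).

# symmetric inverse square root; symmetric eigendecomposition (not Cholesky)
# so the transform is invariant to row ordering of C
sym_inv_sqrt <- function(C, tol = 1e-10) {
  eg <- eigen(C, symmetric = TRUE)
  if (any(eg$values <= tol * max(eg$values))) {
    stop("covariance matrix is singular or not positive definite", call. = FALSE)
  }
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

# phylogenetic GLS mean (row vector over columns of Y)
gls_mean <- function(Y, Cinv) {
  ones <- rep(1, nrow(Y))
  drop(crossprod(ones, Cinv %*% Y)) / sum(Cinv)
}

# core K statistic; works for a matrix Y (K_mult) or a single column (K)
k_statistic <- function(Y, C, Cinv, expected_ratio) {
  a <- gls_mean(Y, Cinv)
  E <- sweep(Y, 2L, a, `-`)
  num <- sum(E * E)
  den <- sum(E * (Cinv %*% E))
  (num / den) / expected_ratio
}

check_taxa_match <- function(Y, C) {
  if (!is.null(rownames(Y)) && !is.null(rownames(C))) {
    if (!setequal(rownames(Y), rownames(C))) {
      stop("taxa of the data do not match the covariance matrix", call. = FALSE)
    }
    Y <- Y[rownames(C), , drop = FALSE]
  } else if (nrow(Y) != nrow(C)) {
    stop("data and covariance matrix differ in size", call. = FALSE)
  }
  Y
}

#' Blomberg's K
#'
#' Phylogenetic signal of a single trait relative to the Brownian-motion
#' expectation: `K = [(y-a)'(y-a) / (y-a)' C^-1 (y-a)] / [(tr(C) - N/sum(C^-1))
#' / (N-1)]` with `a` the phylogenetic GLS mean. K = 1 is the Brownian
#' expectation (and holds exactly on a star phylogeny); K < 1 means relatives
#' resemble each other less than Brownian motion predicts, K > 1 more.
#'
#' For a permutation p-value call [k_mult()] with a one-column matrix; the two
#' statistics coincide for one-dimensional data.
#'
#' @param y Named numeric vector (one value per taxon), non-constant.
#' @param C Brownian covariance from [bm_covariance()].
#' @return The K statistic (numeric scalar).
#' @export
blomberg_k <- function(y, C) {
  Y <- as.matrix(y)
  if (stats::sd(Y) == 0) stop("trait is constant; K is undefined", call. = FALSE)
  Y <- check_taxa_match(Y, C)
  N <- nrow(C)
  Cinv <- solve(C)
  expected <- (sum(diag(C)) - N / sum(Cinv)) / (N - 1)
  k_statistic(Y, C, Cinv, expected)
}

#' Multivariate phylogenetic signal (K_mult)
#'
#' Generalization of Blomberg's K to a trait matrix: squared deviations from
#' the phylogenetic GLS mean are summed across traits in both the numerator
#' and the `C^-1`-weighted denominator, then scaled by the same
#' tree-expectation ratio as the univariate K. For a single column the
#' statistic equals [blomberg_k()] exactly. Significance is assessed by
#' permuting rows of the data across the tips of the tree.
#'
#' @param Y Numeric matrix or data frame, taxa in rows (named).
#' @param C Brownian covariance from [bm_covariance()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed for reproducible permutations.
#' @return An object of class `"phylo_signal"`: list with `statistic`,
#'   `p_value`, `n_permutations`, `permuted_statistics`.
#' @examples
#' tr <- ape::rtree(16)
#' C <- bm_covariance(tr)
#' Y <- simulate_bm_traits(tr, p = 2, seed = 1)
#' k_mult(Y, C, n_perm = 99, seed = 1)
#' @export
k_mult <- function(Y, C, n_perm = 1000, seed = NULL) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (all(apply(Y, 2L, stats::sd) == 0)) stop("data are constant; K_mult is undefined", call. = FALSE)
  Y <- check_taxa_match(Y, C)
  N <- nrow(C)
  Cinv <- solve(C)
  expected <- (sum(diag(C)) - N / sum(Cinv)) / (N - 1)
  obs <- k_statistic(Y, C, Cinv, expected)
  if (!is.null(seed)) set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) {
    k_statistic(Y[sample.int(N), , drop = FALSE], C, Cinv, expected)
  }, numeric(1))
  p <- (1 + sum(perms >= obs)) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 permuted_statistics = perms),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Phylogenetic signal (K_mult)\n")
  cat(sprintf("  statistic: %.4f\n  p-value:   %.4g  (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Permutation-based pairwise comparison of group means under a phylogeny
#'
#' "Phylogenetic HSD": the data and the group design matrix are transformed by
#' the symmetric inverse square root of the Brownian covariance (phylogenetic
#' GLS), group least-squares means are estimated, and the Euclidean distance
#' between each pair of group means is compared against a null distribution
#' obtained by residual randomization of the intercept-only (reduced) model.
#' With `C` an identity matrix this reduces to an ordinary (non-phylogenetic)
#' permutation test of pairwise mean differences. Groups with a single member
#' are dropped with a warning.
#'
#' @param Y Numeric matrix or data frame (taxa x traits, rownames = taxa).
#' @param groups Factor or character vector of group labels, one per row of `Y`.
#' @param C Brownian covariance (use `diag(nrow(Y))` for a plain test).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return Object of class `"pairwise_perm"`: list with `distances` (pairwise
#'   distance between group means), `p_values`, `groups`, `n_permutations`,
#'   `method = "phylo_hsd"`.
#' @export
phylogenetic_hsd <- function(Y, groups, C, n_perm = 1000, seed = NULL) {
  Y <- as.matrix(Y)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(Y))
  tab <- table(groups)
  singletons <- names(tab)[tab < 2L]
  if (length(singletons) > 0L) {
    warning("dropping singleton group(s): ", paste(singletons, collapse = ", "))
    keep <- !(groups %in% singletons)
    Y <- Y[keep, , drop = FALSE]
    groups <- groups[keep]
    if (!is.null(rownames(Y))) C <- C[rownames(Y), rownames(Y)]
    else C <- C[keep, keep]
  }
  if (length(unique(groups)) < 2L) stop("need at least 2 groups with 2+ members", call. = FALSE)
  if (!is.null(rownames(Y)) && !is.null(rownames(C))) {
    if (!setequal(rownames(Y), rownames(C))) {
      stop("taxa of the data do not match the covariance matrix", call. = FALSE)
    }
    ord <- match(rownames(C), rownames(Y))
    Y <- Y[ord, , drop = FALSE]
    groups <- groups[ord]
  } else if (nrow(Y) != nrow(C)) {
    stop("data and covariance matrix differ in size", call. = FALSE)
  }
  n <- nrow(Y)
  g <- factor(groups)
  Tm <- sym_inv_sqrt(C)
  Yt <- Tm %*% Y
  X <- stats::model.matrix(~g)
  Xt <- Tm %*% X
  X0t <- Tm %*% matrix(1, n, 1)
  qr_full <- qr(Xt)
  qr_red <- qr(X0t)
  fit0 <- X0t %*% qr.coef(qr_red, Yt)
  res0 <- Yt - fit0
  levs <- levels(g)
  L <- stats::model.matrix(~f, data = data.frame(f = factor(levs, levels = levs)))
  pair_dist <- function(Ystar) {
    beta <- qr.coef(qr_full, Ystar)
    as.matrix(stats::dist(L %*% beta))
  }
  obs <- pair_dist(Yt)
  if (!is.null(seed)) set.seed(seed)
  count <- matrix(0, length(levs), length(levs))
  for (i in seq_len(n_perm)) {
    d <- pair_dist(fit0 + res0[sample.int(n), , drop = FALSE])
    count <- count + (d >= obs)
  }
  p <- (1 + count) / (1 + n_perm)
  diag(p) <- 1
  dimnames(obs) <- dimnames(p) <- list(levs, levs)
  structure(list(distances = obs, p_values = p, groups = levs,
                 n_permutations = n_perm, method = "phylo_hsd"),
            class = "pairwise_perm")
}

#' @export
print.pairwise_perm <- function(x, ...) {
  cat(sprintf("Pairwise comparison of group means (%s, %d permutations)\n",
              x$method, x$n_permutations))
  cat("Distances between means:\n")
  print(round(x$distances, 4))
  cat("P-values:\n")
  print(round(x$p_values, 4))
  invisible(x)
}

#' Tukey's HSD on a one-way layout
#'
#' Classical studentized-range pairwise comparison of group means (wrapping
#' [stats::aov()] + [stats::TukeyHSD()]), returned in the same shape as
#' [phylogenetic_hsd()] for side-by-side reporting.
#'
#' @param y Numeric response vector.
#' @param groups Group labels (2+ groups; at least 2 total residual df).
#' @return Object of class `"pairwise_perm"` with `method = "tukey"`;
#'   `distances` holds absolute differences of group means and `p_values` the
#'   Tukey-adjusted p-values. `n_permutations` is `NA` (exact distribution).
#' @export
tukey_hsd <- function(y, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(y) - nlevels(g) < 2L) stop("need at least 2 residual degrees of freedom", call. = FALSE)
  fit <- stats::aov(y ~ g, data = data.frame(y = y, g = g))
  tk <- stats::TukeyHSD(fit)$g
  levs <- levels(g)
  k <- length(levs)
  dmat <- matrix(0, k, k, dimnames = list(levs, levs))
  pmat <- matrix(1, k, k, dimnames = list(levs, levs))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    dmat[a, b] <- dmat[b, a] <- abs(tk[i, "diff"])
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  structure(list(distances = dmat, p_values = pmat, groups = levs,
                 n_permutations = NA_integer_, method = "tukey"),
            class = "pairwise_perm")
}
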