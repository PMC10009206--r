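# Ordination and discriminant analysis. All fitting functions operate on
# extant rows only; fossil rows are projected afterwards through the fitted
# transform and never influence the rotation. Passing rows flagged as fossil
# to a fitting function is an error, enforced by assert_extant().

assert_extant <- function(fossil) {
  if (!is.null(fossil) && any(fossil)) {
    stop("fossil-flagged rows must be excluded from fitting; project them instead",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Correlation-matrix principal component analysis
#'
#' PCA on z-scored variables (i.e. on the correlation matrix, which brings
#' variables measured in different units onto the same scale). The extant
#' means and standard deviations are stored so that new (fossil) rows can be
#' projected with [project()] using only the extant-fitted transform.
#'
#' @param X Numeric matrix or data frame (rows = taxa, columns = variables),
#'   no constant columns, at least 2 rows.
#' @param fossil Optional logical vector; any `TRUE` raises an error (fossils
#'   are projected, never fitted).
#' @return Object of class `"pca_cor"`: `center`, `scale`, `loadings`
#'   (variables x components, orthonormal), `scores` (training scores),
#'   `variance_proportion`.
#' @export
pca_correlation <- function(X, fossil = NULL) {
  assert_extant(fossil)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  structure(list(center = pc$center, scale = pc$scale, loadings = pc$rotation,
                 scores = pc$x,
                 variance_proportion = pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_cor")
}

#' @export
print.pca_cor <- function(x, ...) {
  cat("Correlation-matrix PCA:", ncol(x$loadings), "components,",
      nrow(x$scores), "training rows\n")
  cat("Variance proportions:", paste(round(x$variance_proportion, 3), collapse = " "), "\n")
  invisible(x)
}

#' Project new rows through a fitted ordination
#'
#' Projection uses only the transform fitted on extant rows: fossil rows can
#' be added or removed without changing the model. Methods exist for
#' [pca_correlation()] and [fda_fit()]/[pfda_fit()] models.
#'
#' @param model A fitted `"pca_cor"` or `"fda_model"` object.
#' @param X_new Matrix or data frame containing the model's variables.
#' @return Score matrix (rows of `X_new` x model axes).
#' @export
project <- function(model, X_new) UseMethod("project")

check_vars <- function(model_vars, X_new) {
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new)) && !is.null(model_vars)) {
    missing <- setdiff(model_vars, colnames(X_new))
    if (length(missing) > 0L) {
      stop("missing variable(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    X_new <- X_new[, model_vars, drop = FALSE]
  } else if (ncol(X_new) != length(model_vars)) {
    stop("wrong number of variables for this model", call. = FALSE)
  }
  X_new
}

#' @export
project.pca_cor <- function(model, X_new) {
  X_new <- check_vars(names(model$center), X_new)
  scale(X_new, center = model$center, scale = model$scale) %*% model$loadings
}

#' Flexible discriminant analysis (optimal scoring, linear backend)
#'
#' FDA by optimal scoring: class indicators are regressed on the predictors,
#' the score directions are the non-trivial eigenvectors of the resulting
#' class-space problem, and the discriminant variates are whitened against the
#' pooled within-class covariance so that Gaussian posteriors in discriminant
#' space coincide with the classical linear discriminant rule when its
#' assumptions hold. At most `nlevels(labels) - 1` axes are returned, ordered
#' by decreasing discrimination.
#'
#' @param X Numeric matrix or data frame of extant predictors.
#' @param labels Class labels (factor or character), each class with >= 2
#'   members.
#' @param priors Optional named numeric vector of class prior probabilities
#'   (default: training class proportions). Must be positive; normalized to
#'   sum to 1.
#' @param fossil Optional logical vector; any `TRUE` raises an error.
#' @return Object of class `"fda_model"`: `axes` (affine map: list with
#'   `center` and `weights`), `centroids` (class x axes), `priors`, `labels`,
#'   `scores` (training variates), `method = "fda"`.
#' @export
fda_fit <- function(X, labels, priors = NULL, fossil = NULL) {
  assert_extant(fossil)
  X <- as.matrix(X)
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("class(es) with fewer than 2 members: ",
         paste(names(which(table(g) < 2L)), collapse = ", "), call. = FALSE)
  }
  n <- nrow(X)
  J <- nlevels(g)
  Yind <- stats::model.matrix(~ g - 1)
  colnames(Yind) <- levels(g)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, `-`)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xc), Yind)
  Yhat <- fit$fitted.values
  props <- colMeans(Yind)
  M <- crossprod(Yind, Yhat) / n                      # J x J, symmetric
  u <- sqrt(props)
  A <- M / outer(u, u)                                # Dp^{-1/2} M Dp^{-1/2}
  A <- A - outer(u, u)  # deflate the trivial constant-score direction exactly
  eg <- eigen(A, symmetric = TRUE)
  keep <- which(eg$values > 1e-9)
  keep <- keep[seq_len(min(length(keep), J - 1L, ncol(X)))]
  if (length(keep) == 0L) stop("no discriminating directions found", call. = FALSE)
  theta <- sweep(eg$vectors[, keep, drop = FALSE], 1L, u, `/`)
  V <- Yhat %*% theta                                 # raw discriminant variates
  # whiten variates against pooled within-class covariance
  Vcent <- V - rowsum(V, g)[g, , drop = FALSE] / as.vector(table(g))[g]
  Wv <- crossprod(Vcent) / (n - J)
  Tw <- sym_inv_sqrt(Wv)
  Z <- V %*% Tw
  weights <- (fit$coefficients[-1L, , drop = FALSE] %*% theta) %*% Tw
  offset <- drop(crossprod(fit$coefficients[1L, ], theta) %*% Tw)
  centroids <- rowsum(Z, g) / as.vector(table(g))
  if (is.null(priors)) {
    priors <- props
  } else {
    if (is.null(names(priors))) names(priors) <- levels(g)
    priors <- priors[levels(g)]
    if (any(is.na(priors) | priors <= 0)) stop("priors must be positive for every class", call. = FALSE)
    priors <- priors / sum(priors)
  }
  rownames(centroids) <- levels(g)
  structure(list(method = "fda", center = center, weights = weights,
                 offset = offset, centroids = centroids, priors = priors,
                 labels = g, scores = Z, eigenvalues = eg$values[keep]),
            class = "fda_model")
}

#' @export
print.fda_model <- function(x, ...) {
  cat(sprintf("%s model: %d classes, %d discriminant axes, %d training rows\n",
              toupper(x$method), nrow(x$centroids), ncol(x$centroids),
              nrow(x$scores)))
  if (!is.null(x$lambda)) cat("  lambda:", x$lambda, "\n")
  invisible(x)
}

#' @export
project.fda_model <- function(model, X_new) {
  # pFDA note: fossil rows carry no entry in the extant phylogenetic
  # covariance, so they pass through with unit self-variance (no whitening);
  # the extant-fitted centering and axis weights still apply
  X_new <- check_vars(names(model$center), X_new)
  Xc <- sweep(X_new, 2L, model$center, `-`)
  sweep(Xc %*% model$weights, 2L, model$offset, `+`)
}

#' Posterior class probabilities from a discriminant model
#'
#' Gaussian class-conditional posteriors in the whitened discriminant space:
#' `P(class g | x) ~ prior_g * exp(-0.5 * ||z(x) - centroid_g||^2)`,
#' normalized to sum to 1 per row. The predicted class is the argmax (ties
#' broken toward the first class in sorted label order).
#'
#' @param model A fitted `"fda_model"`.
#' @param X_new Rows to classify (model variables required).
#' @return Object of class `"posterior_table"`: data frame of class posterior
#'   probabilities with a `predicted` attribute (factor of argmax classes).
#' @export
discriminant_predict <- function(model, X_new) {
  Z <- project(model, X_new)
  d2 <- outer(rowSums(Z^2), rowSums(model$centroids^2), `+`) -
    2 * Z %*% t(model$centroids)
  logpost <- sweep(-0.5 * d2, 2L, log(model$priors), `+`)
  logpost <- logpost - apply(logpost, 1L, max)
  post <- exp(logpost)
  post <- post / rowSums(post)
  colnames(post) <- rownames(model$centroids)
  rownames(post) <- rownames(X_new)
  predicted <- factor(colnames(post)[apply(post, 1L, which.max)],
                      levels = colnames(post))
  structure(as.data.frame(post), predicted = predicted, class = c("posterior_table", "data.frame"))
}

#' Phylogenetic flexible discriminant analysis
#'
#' FDA after phylogenetic generalized-least-squares whitening of the
#' predictors. The Brownian covariance has its off-diagonal entries scaled by
#' Pagel's lambda, is normalized to unit mean self-variance, and its symmetric
#' inverse square root is applied to the extant predictor rows before fitting
#' FDA. With `lambda = 0` on an ultrametric tree (or `C` proportional to the
#' identity) the whitener is the identity and pFDA reproduces [fda_fit()]
#' exactly. Fossil rows, which have no entry in `C`, are projected with unit
#' self-variance (no whitening), an approximation stated in the vignette.
#'
#' @param X Extant predictor matrix (rownames must appear in `C`).
#' @param labels Class labels for the extant rows.
#' @param C Brownian covariance from [bm_covariance()] (extant taxa).
#' @param lambda Pagel's lambda in `[0, 1]`, or `"optimize"` to choose it by
#'   [optimal_lambda()].
#' @param priors,fossil Passed to [fda_fit()].
#' @param grid Grid used when `lambda = "optimize"`.
#' @return An `"fda_model"` with `method = "pfda"`, the `lambda` used, and the
#'   whitening transform stored.
#' @export
pfda_fit <- function(X, labels, C, lambda = "optimize", priors = NULL,
                     fossil = NULL, grid = seq(0, 1, by = 0.01)) {
  assert_extant(fossil)
  X <- as.matrix(X)
  X <- check_taxa_match(X, C)
  if (identical(lambda, "optimize")) {
    lambda <- optimal_lambda(X, C, grid = grid)
  }
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must be in [0, 1]", call. = FALSE)
  }
  Cl <- lambda_transform(C, lambda)
  Cl <- Cl / mean(diag(Cl))  # unit mean self-variance, so lambda = 0 on an
                             # ultrametric tree gives an identity whitener
  W <- sym_inv_sqrt(Cl)
  labels <- if (!is.null(names(labels))) labels[rownames(X)] else labels
  Xw <- W %*% X
  dimnames(Xw) <- dimnames(X)
  fit <- fda_fit(Xw, labels, priors = priors)
  fit$method <- "pfda"
  fit$lambda <- lambda
  fit$whitener <- W
  fit$fossil_whitener <- 1  # unit self-variance for projected fossils
  fit
}

# scale off-diagonal entries of C by lambda
lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Profile Pagel's lambda by per-variable GLS likelihood
#'
#' For each grid value, the off-diagonal entries of `C` are scaled by lambda
#' and the Brownian GLS log-likelihood of each column of `X` (mean and rate
#' profiled out analytically) is summed across columns; the grid value
#' maximizing the summed log-likelihood is returned (ties toward the smaller
#' value).
#'
#' @param X Trait matrix (taxa x variables, rownames matching `C`).
#' @param C Brownian covariance.
#' @param grid Candidate lambda values in `[0, 1]` (default 0 to 1 by 0.01).
#' @return The selected lambda (scalar from `grid`).
#' @export
optimal_lambda <- function(X, C, grid = seq(0, 1, by = 0.01)) {
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  X <- as.matrix(X)
  X <- check_taxa_match(X, C)
  N <- nrow(X)
  ll <- vapply(grid, function(lam) {
    Cl <- lambda_transform(C, lam)
    ch <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Cinv <- chol2inv(ch)
    a <- gls_mean(X, Cinv)
    E <- sweep(X, 2L, a, `-`)
    sig2 <- colSums(E * (Cinv %*% E)) / N
    sum(-N / 2 * (log(2 * pi * sig2) + 1) - logdet / 2)
  }, numeric(1))
  grid[which.max(ll)]  # which.max takes the first (smallest) on ties
}
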