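# Post-processing of finite-element strain fields: mesh-weighted mean strain,
# the intervals method (percent model area per equal-width strain interval),
# convergence testing over the number of intervals, and compositional-data
# machinery (multiplicative zero replacement, clr and ilr transforms).
#
# A strain field is a data frame (or list) with columns `area` (> 0, any
# consistent units) and `strain` (max in-plane principal strain, microstrain,
# >= 0). Absolute strain values are meaningful only for comparison among
# models built under the same assumptions.

check_field <- function(field) {
  area <- field$area; strain <- field$strain
  if (is.null(area) || is.null(strain) || length(area) == 0L) {
    stop("a strain field needs non-empty 'area' and 'strain' columns", call. = FALSE)
  }
  if (any(area <= 0)) stop("element areas must be positive", call. = FALSE)
  if (any(strain < 0)) stop("strains must be non-negative", call. = FALSE)
  list(area = as.numeric(area), strain = as.numeric(strain))
}

#' Mesh-weighted arithmetic mean (MWAM) strain
#'
#' Area-weighted mean of element strains,
#' `sum(strain_i * area_i) / sum(area_i)`: a scalar summary of a solved
#' finite-element model's overall strain state, bounded by the minimum and
#' maximum element strain.
#'
#' @param field Strain field (data frame with `area`, `strain`).
#' @return MWAM strain in the strain units of the field (microstrain).
#' @examples
#' mwam(data.frame(area = c(1, 3), strain = c(100, 200)))  # 175
#' @export
mwam <- function(field) {
  f <- check_field(field)
  sum(f$strain * f$area) / sum(f$area)
}

#' Shared interval specification for a set of strain fields
#'
#' Equal-width strain intervals spanning the pooled `[min, max]` strain of all
#' models; shared bins are required for the models' compositions to be
#' comparable.
#'
#' @param fields List of strain fields.
#' @param n_intervals Number of intervals (>= 2).
#' @param open_upper_tail If `TRUE`, strains at or above the upper bound fall
#'   in the last interval (the last bin is closed at the top either way for
#'   strains equal to the pooled maximum).
#' @return List with `lower`, `upper`, `n`, `open_upper_tail`, `breaks`.
#' @export
interval_spec <- function(fields, n_intervals, open_upper_tail = FALSE) {
  if (n_intervals < 2L) stop("need at least 2 intervals", call. = FALSE)
  strains <- unlist(lapply(fields, function(f) check_field(f)$strain))
  lower <- min(strains); upper <- max(strains)
  if (lower >= upper) upper <- lower + 1e-9  # all models uniform in strain
  list(lower = lower, upper = upper, n = as.integer(n_intervals),
       open_upper_tail = open_upper_tail,
       breaks = seq(lower, upper, length.out = n_intervals + 1L))
}

#' Percent model area per strain interval
#'
#' The intervals method: for each model the fraction of total mesh area whose
#' element strain falls in each interval, times 100. Rows (models) sum to 100.
#'
#' @param fields Named list of strain fields.
#' @param spec Interval specification from [interval_spec()]; alternatively an
#'   integer, in which case a shared spec is built from `fields`.
#' @return Matrix (models x intervals) of percentages, class
#'   `"interval_composition"` with the spec attached as attribute `"spec"`.
#' @export
interval_composition <- function(fields, spec) {
  if (is.numeric(spec) && length(spec) == 1L) spec <- interval_spec(fields, spec)
  breaks <- spec$breaks
  comp <- t(vapply(fields, function(field) {
    f <- check_field(field)
    idx <- findInterval(f$strain, breaks, rightmost.closed = TRUE)
    if (any(idx == 0L)) stop("strain below the interval range", call. = FALSE)
    if (any(idx > spec$n)) {
      if (spec$open_upper_tail) idx[idx > spec$n] <- spec$n
      else stop("strain above the interval range (enable open_upper_tail?)", call. = FALSE)
    }
    pct <- numeric(spec$n)
    agg <- rowsum(f$area, idx)
    pct[as.integer(rownames(agg))] <- agg[, 1L]
    100 * pct / sum(f$area)
  }, numeric(spec$n)))
  if (!is.null(names(fields))) rownames(comp) <- names(fields)
  colnames(comp) <- paste0("int", seq_len(spec$n))
  structure(comp, spec = spec, class = c("interval_composition", class(comp)))
}

#' Convergence testing for the number of strain intervals
#'
#' Increases the interval count from `start_n` in steps of `step`; at each
#' count the compositions are imputed, ilr-transformed and ordinated
#' (correlation-matrix PCA, or FDA when `groups` are given), and the pairwise
#' distance matrix between models in ordination space is computed. The search
#' stops when the Pearson correlation between consecutive distance matrices
#' reaches `criterion_threshold`, returning the smaller interval count of the
#' converged pair. Zero-variance distance matrices are defined as converged.
#'
#' @param fields Named list of strain fields (>= 3 models).
#' @param start_n,step,max_n Interval-count search grid.
#' @param criterion_threshold Correlation required for convergence (default
#'   0.99).
#' @param downstream `"pca"` or `"fda"`.
#' @param groups Class labels (required for `downstream = "fda"`).
#' @param delta_fraction Passed to [impute_zeros()].
#' @return List of class `"interval_convergence"`: `n` (first converged
#'   count, `NA` if not reached by `max_n`), `converged`, `history` (data
#'   frame of counts and correlations).
#' @export
converge_intervals <- function(fields, start_n = 10, step = 5, max_n = 200,
                               criterion_threshold = 0.99,
                               downstream = c("pca", "fda"), groups = NULL,
                               delta_fraction = 0.65) {
  downstream <- match.arg(downstream)
  if (length(fields) < 3L) stop("need at least 3 models", call. = FALSE)
  if (downstream == "fda" && is.null(groups)) stop("downstream = 'fda' needs groups", call. = FALSE)
  dist_at <- function(n) {
    comp <- interval_composition(fields, interval_spec(fields, n))
    coords <- ilr(impute_zeros(comp, delta_fraction = delta_fraction))
    # degenerate coordinate sets (identical models) yield constant columns;
    # distances are then all zero and handled by the correlation rule below
    sds <- apply(coords, 2L, stats::sd)
    if (all(sds == 0)) return(stats::dist(coords))
    keep <- coords[, sds > 0, drop = FALSE]
    if (downstream == "pca") {
      stats::dist(pca_correlation(keep)$scores)
    } else {
      stats::dist(fda_fit(keep, groups)$scores)
    }
  }
  grid <- seq(start_n, max_n, by = step)
  hist_n <- integer(0); hist_cor <- numeric(0)
  d_prev <- dist_at(grid[1L])
  for (i in seq_along(grid)[-1L]) {
    d_cur <- dist_at(grid[i])
    r <- if (stats::sd(d_prev) == 0 || stats::sd(d_cur) == 0) 1 else stats::cor(d_prev, d_cur)
    hist_n <- c(hist_n, grid[i - 1L]); hist_cor <- c(hist_cor, r)
    if (r >= criterion_threshold) {
      return(structure(list(n = grid[i - 1L], converged = TRUE,
                            history = data.frame(n = hist_n, cor_with_next = hist_cor)),
                       class = "interval_convergence"))
    }
    d_prev <- d_cur
  }
  warning("interval counts did not converge by max_n = ", max_n)
  structure(list(n = NA_integer_, converged = FALSE,
                 history = data.frame(n = hist_n, cor_with_next = hist_cor)),
            class = "interval_convergence")
}

#' @export
print.interval_convergence <- function(x, ...) {
  if (x$converged) cat("Intervals converged at n =", x$n, "\n")
  else cat("Intervals did not converge within the searched range\n")
  invisible(x)
}

#' Multiplicative zero replacement for compositions
#'
#' Replaces zeros in each row by `delta = delta_fraction x (row's smallest
#' positive value)` and multiplicatively rescales the non-zero parts so the
#' row again sums to 100; ratios between non-zero parts are preserved. When a
#' row has many zeros and a large minimum part the nominal replacement could
#' exceed the row total, so `delta` is capped such that imputed parts never
#' take more than half of the row's mass.
#'
#' @param comp Composition matrix (rows sum to 100); at least one positive
#'   entry per row.
#' @param delta_fraction Fraction of the row-minimum positive value used as
#'   the replacement (default 0.65).
#' @return Strictly positive composition matrix, rows summing to 100.
#' @export
impute_zeros <- function(comp, delta_fraction = 0.65) {
  comp <- as.matrix(comp)
  if (any(comp < 0)) stop("compositions must be non-negative", call. = FALSE)
  out <- t(apply(comp, 1L, function(x) {
    z <- x == 0
    if (all(z)) stop("all-zero composition row", call. = FALSE)
    if (!any(z)) return(x)
    delta <- delta_fraction * min(x[!z])
    delta <- min(delta, 50 / sum(z))  # imputed mass capped at half the total
    total_delta <- delta * sum(z)
    x[!z] <- x[!z] * (100 - total_delta) / sum(x[!z])
    x[z] <- delta
    x
  }))
  dimnames(out) <- dimnames(comp)
  out
}

#' Centered log-ratio transform
#'
#' `clr(x) = log(x / geometric_mean(x))` per row; rows sum to 0 and the
#' transform is invariant to rescaling a row by a positive constant.
#'
#' @param comp Strictly positive composition matrix (impute zeros first).
#' @return Matrix of clr coordinates (same dimensions).
#' @export
clr <- function(comp) {
  comp <- as.matrix(comp)
  if (any(comp <= 0)) stop("clr requires strictly positive entries", call. = FALSE)
  lx <- log(comp)
  sweep(lx, 1L, rowMeans(lx), `-`)
}

# fixed Helmert-type orthonormal basis (D x (D-1)), parts in bin order;
# column k contrasts the first k parts against part k+1
ilr_basis <- function(D) {
  V <- matrix(0, D, D - 1L)
  for (k in seq_len(D - 1L)) {
    V[seq_len(k), k] <- sqrt(1 / (k * (k + 1)))
    V[k + 1L, k] <- -sqrt(k / (k + 1))
  }
  V
}

#' Isometric log-ratio transform
#'
#' ilr coordinates under a fixed Helmert-type orthonormal basis (parts in bin
#' order), mapping D parts to D-1 coordinates. The map is an isometry:
#' Euclidean distance between ilr coordinate rows equals the Aitchison
#' distance between the compositions.
#'
#' @param comp Strictly positive composition matrix.
#' @return Matrix of ilr coordinates (rows x (D-1)).
#' @export
ilr <- function(comp) {
  z <- clr(comp)
  out <- z %*% ilr_basis(ncol(z))
  colnames(out) <- paste0("ilr", seq_len(ncol(out)))
  rownames(out) <- rownames(comp)
  out
}

#' Inverse isometric log-ratio transform
#'
#' Maps D-1 ilr coordinates (under the same fixed basis as [ilr()]) back to a
#' D-part composition closed to 100. `ilr_inverse(ilr(x))` recovers `x` after
#' closure.
#'
#' @param coords Matrix of ilr coordinates.
#' @return Composition matrix with rows summing to 100.
#' @export
ilr_inverse <- function(coords) {
  coords <- as.matrix(coords)
  z <- coords %*% t(ilr_basis(ncol(coords) + 1L))
  x <- exp(z)
  out <- 100 * x / rowSums(x)
  rownames(out) <- rownames(coords)
  out
}
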