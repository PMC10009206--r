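# Seeded synthetic-data generators. Each generator emulates the statistical
# structure one pipeline stage assumes - Brownian traits on a time-scaled
# tree, class-structured Gaussian morphometrics, diet-stratified log-normal
# body masses, log-normal-area strain fields with exact target MWAM - so the
# whole pipeline is testable without any external data. Every generator is
# bit-reproducible given a seed.

# multivariate normal draws via the Cholesky factor of Sigma
rmvn <- function(n, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("covariance is not positive definite", call. = FALSE))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% ch
}

#' Simulate Brownian-motion traits on a tree
#'
#' Independent traits drawn from a multivariate normal with covariance
#' `sigma2 * C(lambda_true)`, where `C` is the Brownian covariance of the
#' tree and `lambda_true` scales its off-diagonal entries (Pagel's lambda;
#' 0 = star-like independence, 1 = full Brownian structure).
#'
#' @param tree A `"phylo"` tree.
#' @param p Number of traits.
#' @param sigma2 Brownian rate (trait variance per Ma). Default 1.
#' @param lambda_true Pagel's lambda in `[0, 1]`. Default 1.
#' @param seed Optional integer seed.
#' @return Numeric matrix (tips x traits) with tip labels as rownames.
#' @export
simulate_bm_traits <- function(tree, p, sigma2 = 1, lambda_true = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), p >= 1, sigma2 > 0,
            lambda_true >= 0, lambda_true <= 1)
  if (!is.null(seed)) set.seed(seed)
  C <- lambda_transform(bm_covariance(tree), lambda_true)
  Y <- t(rmvn(p, sigma2 * C))
  rownames(Y) <- tree$tip.label
  colnames(Y) <- paste0("trait", seq_len(p))
  Y
}

#' Simulate labeled Gaussian class data
#'
#' Samples with class-specific means and a shared covariance, exercising the
#' discriminant-analysis stages.
#'
#' @param classes Character vector of class names.
#' @param n_per_class Samples per class (scalar or per-class vector).
#' @param means Matrix of class means (classes x variables).
#' @param shared_covariance Common within-class covariance (variables x
#'   variables); must be positive definite.
#' @param seed Optional integer seed.
#' @return List with `X` (matrix) and `labels` (factor).
#' @export
simulate_class_data <- function(classes, n_per_class, means, shared_covariance, seed = NULL) {
  means <- as.matrix(means)
  stopifnot(length(classes) == nrow(means),
            ncol(means) == nrow(shared_covariance))
  n_per_class <- rep_len(n_per_class, length(classes))
  if (!is.null(seed)) set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(classes), function(j) {
    sweep(rmvn(n_per_class[j], shared_covariance), 2L, means[j, ], `+`)
  }))
  labels <- factor(rep(classes, n_per_class), levels = classes)
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  rownames(X) <- paste0(rep(classes, n_per_class), "_",
                        unlist(lapply(n_per_class, seq_len)))
  list(X = X, labels = labels)
}

#' Simulate diet-stratified log10 body masses
#'
#' Species masses drawn log10-normally within diet categories. The defaults
#' mirror a broadly sampled extant bird dataset: sample sizes per diet follow
#' the study design (141 species across ten diet categories) and group means
#' reflect typical adult masses - small invertivores, granivores and
#' nectarivores; heavier vertebrate-eaters, folivores and frugivores.
#'
#' @param n_per_diet Named integer vector of species per diet.
#' @param mean_log10 Named numeric vector of mean log10 mass (g) per diet.
#' @param sd_log10 Within-diet standard deviation of log10 mass (scalar or
#'   named vector). Default 0.5.
#' @param seed Optional integer seed.
#' @return Data frame: `species`, `diet`, `log10_mass`.
#' @export
simulate_mass_data <- function(
    n_per_diet = c(Folivore = 9, Frugivore = 17, Generalist = 17,
                   `Husking Granivore` = 8, `Swallowing Granivore` = 8,
                   Invertivore = 43, Nectarivore = 7, Piscivore = 15,
                   Scavenger = 8, `Tetrapod Hunter` = 9),
    mean_log10 = c(Folivore = 2.9, Frugivore = 2.6, Generalist = 2.3,
                   `Husking Granivore` = 1.8, `Swallowing Granivore` = 1.7,
                   Invertivore = 1.9, Nectarivore = 1.3, Piscivore = 3.0,
                   Scavenger = 3.3, `Tetrapod Hunter` = 2.9),
    sd_log10 = 0.5, seed = NULL) {
  diets <- names(n_per_diet)
  stopifnot(!is.null(diets), all(diets %in% names(mean_log10)))
  sd_log10 <- if (is.null(names(sd_log10))) stats::setNames(rep_len(sd_log10, length(diets)), diets) else sd_log10
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(diets, function(d) {
    data.frame(species = paste0(gsub("[^A-Za-z]", "", d), "_sp", seq_len(n_per_diet[[d]])),
               diet = d,
               log10_mass = stats::rnorm(n_per_diet[[d]], mean_log10[[d]], sd_log10[[d]]))
  })
  do.call(rbind, rows)
}

#' Simulate finite-element strain fields
#'
#' Element areas are log-normal; element strains are drawn log-normally with
#' the given dispersion and then rescaled multiplicatively so that the
#' realized mesh-weighted mean strain equals `target_mwam` exactly, giving
#' sharp oracles for [mwam()] and [interval_composition()].
#'
#' @param target_mwam Named numeric vector of target MWAM strains
#'   (microstrain, > 0), one per model.
#' @param n_elements Elements per mesh (scalar or per-model). Default 200.
#' @param dispersion Log-scale SD of element strain (scalar or per-model).
#'   Default 0.5.
#' @param seed Optional integer seed.
#' @return Named list of strain fields (data frames with `area`, `strain`).
#' @export
simulate_strain_fields <- function(target_mwam, n_elements = 200,
                                   dispersion = 0.5, seed = NULL) {
  stopifnot(all(target_mwam > 0))
  m <- length(target_mwam)
  n_elements <- rep_len(n_elements, m)
  dispersion <- rep_len(dispersion, m)
  if (!is.null(seed)) set.seed(seed)
  fields <- lapply(seq_len(m), function(i) {
    area <- stats::rlnorm(n_elements[i], meanlog = 0, sdlog = 0.4)
    strain <- stats::rlnorm(n_elements[i], meanlog = log(target_mwam[i]),
                            sdlog = dispersion[i])
    strain <- strain * target_mwam[i] / (sum(strain * area) / sum(area))
    data.frame(area = area, strain = strain)
  })
  names(fields) <- if (!is.null(names(target_mwam))) names(target_mwam)
                   else paste0("model", seq_len(m))
  fields
}

#' Construct claw-arc landmarks from curvature and radius
#'
#' Inverse construction for the claw geometry: three points on a circle of
#' the given radius spanning the given arc, with the middle landmark at the
#' arc midpoint. `arc_curvature()` recovers the curvature and `arc_length()`
#' returns `radius * curvature` (radians).
#'
#' @param curvature_deg Arc angle in degrees, strictly between 0 and 360.
#' @param radius Circle radius (> 0).
#' @return 3 x 2 landmark matrix (base, midpoint, tip).
#' @examples
#' arc_curvature(claw_from_parameters(180, 1))  # 180
#' @export
claw_from_parameters <- function(curvature_deg, radius = 1) {
  if (curvature_deg <= 0 || curvature_deg >= 360) {
    stop("curvature must be strictly between 0 and 360 degrees", call. = FALSE)
  }
  stopifnot(radius > 0)
  half <- curvature_deg * pi / 360
  ang <- pi / 2 + c(half, 0, -half)
  radius * cbind(cos(ang), sin(ang))
}

#' Pathological datasets exercising downstream error paths
#'
#' Small degenerate inputs used to test error handling: an interval
#' composition with an all-zero row, group labels with a singleton group, and
#' a claw record missing a digit.
#'
#' @return Named list of degenerate inputs.
#' @export
pathological_presets <- function() {
  list(
    all_zero_composition = rbind(a = c(50, 50, 0), b = c(0, 0, 0)),
    singleton_groups = data.frame(
      taxon = paste0("t", 1:5),
      group = c("A", "A", "B", "B", "C")
    ),
    incomplete_claw = list(II = claw_from_parameters(90, 1))
  )
}
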