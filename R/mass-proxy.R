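#' Estimate log10 body mass from skeletal measurements
#'
#' Applies the published enantiornithine mass regression to the log10-scale
#' forelimb and hindlimb measurements:
#' `-2.626 + 1.528*HL + 0.34*bcL + 0.828*dHW - 1.451*UL + 0.811*dUW + 0.378*TL`
#' where HL = humerus length, bcL = bicipital crest length, dHW = distal
#' humerus width, UL = ulna length, dUW = distal ulna width, TL = tibiotarsus
#' length (log10 mm), returning log10 mass (log10 g).
#'
#' @param HL,bcL,dHW,UL,dUW,TL log10 linear measurements; each may be a
#'   vector (recycled to a common length). Alternatively pass a single data
#'   frame / named list as `HL` containing all six columns.
#' @return log10 body mass estimate(s).
#' @examples
#' estimate_log_mass(0, 0, 0, 0, 0, 0)  # the regression intercept, -2.626
#' @export
estimate_log_mass <- function(HL, bcL, dHW, UL, dUW, TL) {
  if (is.list(HL) || is.data.frame(HL)) {
    m <- HL
    need <- c("HL", "bcL", "dHW", "UL", "dUW", "TL")
    missing <- setdiff(need, names(m))
    if (length(missing) > 0L) {
      stop("missing measurement field(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    HL <- m$HL; bcL <- m$bcL; dHW <- m$dHW; UL <- m$UL; dUW <- m$dUW; TL <- m$TL
  }
  vals <- cbind(HL, bcL, dHW, UL, dUW, TL)
  if (any(!is.finite(vals))) stop("all six measurements must be finite", call. = FALSE)
  -2.626 + 1.528 * HL + 0.34 * bcL + 0.828 * dHW - 1.451 * UL + 0.811 * dUW + 0.378 * TL
}

#' Youden-index optimal cut-point between two groups
#'
#' Scans the midpoints of adjacent sorted pooled values exhaustively and
#' returns the threshold maximizing Youden's J = sensitivity + specificity -
#' 1, where the group with the larger mean is treated as "positive" (above
#' threshold). Ties in J are broken toward the smaller threshold.
#'
#' @param group_a,group_b Numeric vectors (non-empty). Typically log10 body
#'   masses of two lumped diet groups.
#' @param positive Which group counts as positive ("auto" = larger mean,
#'   or `"a"` / `"b"`).
#' @return List of class `"youden_cutpoint"`: `threshold`, `youden_J`,
#'   `sensitivity`, `specificity`, `direction` (name of the positive group).
#' @examples
#' youden_cutpoint(c(1, 2, 3), c(10, 11, 12))  # J = 1 at threshold 6.5
#' @export
youden_cutpoint <- function(group_a, group_b, positive = c("auto", "a", "b")) {
  positive <- match.arg(positive)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (positive == "auto") positive <- if (mean(group_a) >= mean(group_b)) "a" else "b"
  pos <- if (positive == "a") group_a else group_b
  neg <- if (positive == "a") group_b else group_a
  pooled <- sort(unique(c(pos, neg)))
  cand <- if (length(pooled) > 1L) (pooled[-1L] + pooled[-length(pooled)]) / 2 else pooled
  sens <- vapply(cand, function(t) mean(pos > t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg <= t), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)[1L]  # candidates sorted: ties -> smaller
  structure(list(threshold = cand[best], youden_J = J[best],
                 sensitivity = sens[best], specificity = spec[best],
                 direction = positive),
            class = "youden_cutpoint")
}

#' @export
print.youden_cutpoint <- function(x, ...) {
  cat(sprintf("Youden cut-point: %.4g (J = %.3f, sens = %.3f, spec = %.3f; positive = group %s)\n",
              x$threshold, x$youden_J, x$sensitivity, x$specificity, x$direction))
  invisible(x)
}

#' Classify a mass interval against diet-group cut-points
#'
#' For each contrast (a named threshold, e.g. invertivore-vs-vertivore and
#' FolFrug-vs-GranNect), reports which side of the cut-point a fossil's mass
#' interval `[low, high]` is consistent with: `"above"`, `"below"`, or
#' `"inconclusive"` when the interval straddles the threshold. Masses and
#' thresholds must be on the same (log10) scale.
#'
#' @param log_mass_interval Numeric length-2 vector `c(low, high)` (a point
#'   estimate may be given as `c(x, x)` or a single value).
#' @param cutpoints Named numeric vector of thresholds, one per contrast.
#' @return Named character vector over contrasts with values
#'   `"above"` / `"below"` / `"inconclusive"`.
#' @export
classify_by_mass <- function(log_mass_interval, cutpoints) {
  if (length(log_mass_interval) == 1L) log_mass_interval <- rep(log_mass_interval, 2L)
  low <- log_mass_interval[1L]; high <- log_mass_interval[2L]
  if (low > high) stop("interval must satisfy low <= high", call. = FALSE)
  out <- vapply(cutpoints, function(t) {
    if (low > t) "above" else if (high < t) "below" else "inconclusive"
  }, character(1))
  names(out) <- names(cutpoints)
  out
}

#' Diet-lumping maps for the two body-mass contrasts
#'
#' Carnivores split into invertivores versus vertivores (piscivores,
#' scavengers, tetrapod hunters); herbivores split into folivores + frugivores
#' versus granivores + nectarivores. Used to pool species-level diet labels
#' before [youden_cutpoint()].
#'
#' @return Named list of two contrasts, each a list with `a` and `b` label
#'   sets (`a` is the side expected to be heavier).
#' @export
mass_contrasts <- function() {
  list(
    carnivore = list(a = c("Piscivore", "Scavenger", "Tetrapod Hunter"),
                     b = "Invertivore"),
    herbivore = list(a = c("Folivore", "Frugivore"),
                     b = c("Granivore", "Husking Granivore",
                           "Swallowing Granivore", "Nectarivore"))
  )
}

#' Youden cut-points for the standard mass contrasts
#'
#' Pools log10 species masses by the [mass_contrasts()] lumping and runs
#' [youden_cutpoint()] for each contrast.
#'
#' @param log_mass Numeric vector of log10 species masses (g).
#' @param diet Diet label per species.
#' @param contrasts Contrast list in the format of [mass_contrasts()].
#' @return Data frame with one row per contrast: `threshold_log10`,
#'   `threshold_g` (back-transformed to grams), `youden_J`, `sensitivity`,
#'   `specificity`.
#' @export
mass_cutpoints <- function(log_mass, diet, contrasts = mass_contrasts()) {
  rows <- lapply(names(contrasts), function(nm) {
    ct <- contrasts[[nm]]
    a <- log_mass[diet %in% ct$a]
    b <- log_mass[diet %in% ct$b]
    if (length(a) == 0L || length(b) == 0L) {
      stop("contrast '", nm, "' has an empty side", call. = FALSE)
    }
    cp <- youden_cutpoint(a, b)
    data.frame(contrast = nm, threshold_log10 = cp$threshold,
               threshold_g = 10^cp$threshold, youden_J = cp$youden_J,
               sensitivity = cp$sensitivity, specificity = cp$specificity)
  })
  do.call(rbind, rows)
}
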