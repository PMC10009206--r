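# Diet-category assignment from EltonTraits-style percentage columns, rater
# agreement (Fleiss' kappa), and synthesis of per-proxy posterior predictions
# into likely / unlikely / agreed diet sets.

elton_columns <- c("Diet-PlantO", "Diet-Fruit", "Diet-Seed", "Diet-Nect",
                   "Diet-Inv", "Diet-Fish", "Diet-Scav", "Diet-Ect", "Diet-End")

# cut-off rules: category, percentage column(s) summed, threshold
diet_rules <- list(
  Folivore          = list(cols = "Diet-PlantO", min = 60),
  Frugivore         = list(cols = "Diet-Fruit",  min = 60),
  Granivore         = list(cols = "Diet-Seed",   min = 70),
  Invertivore       = list(cols = "Diet-Inv",    min = 60),
  Nectarivore       = list(cols = "Diet-Nect",   min = 60),
  Piscivore         = list(cols = "Diet-Fish",   min = 50),
  Scavenger         = list(cols = "Diet-Scav",   min = 50),
  `Tetrapod Hunter` = list(cols = c("Diet-Ect", "Diet-End"), min = 60)
)

#' Assign a diet category from EltonTraits-style percentages
#'
#' Applies the percentage cut-offs: Folivore 60+% plant, Frugivore 60+% fruit,
#' Granivore 70+% seed, Invertivore 60+% invertebrates, Nectarivore 60+%
#' nectar, Piscivore 50+% fish, Scavenger 50+% scavenge, Tetrapod Hunter 60+%
#' tetrapods (ectotherm + endotherm percentages summed), and Generalist when
#' no category exceeds 40%. If two rules fire (possible only at a 50/50
#' fish/scavenge split) the higher percentage wins and an exact tie is
#' `"unclassified"`; rows meeting no rule are `"unclassified"`.
#'
#' @param row Named numeric vector / one-row data frame with the columns
#'   `Diet-PlantO`, `Diet-Fruit`, `Diet-Seed`, `Diet-Nect`, `Diet-Inv`,
#'   `Diet-Fish`, `Diet-Scav`, `Diet-Ect`, `Diet-End`; entries non-negative
#'   and summing to 100.
#' @return Character scalar: a diet category, `"Generalist"`, or
#'   `"unclassified"`.
#' @export
assign_diet <- function(row) {
  if (is.data.frame(row)) row <- unlist(row[1L, , drop = TRUE])
  missing <- setdiff(elton_columns, names(row))
  if (length(missing) > 0L) {
    stop("missing diet column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- as.numeric(row[elton_columns])
  names(vals) <- elton_columns
  if (any(vals < 0)) stop("diet percentages must be non-negative", call. = FALSE)
  if (abs(sum(vals) - 100) > 1e-6) stop("diet percentages must sum to 100", call. = FALSE)
  pct <- vapply(diet_rules, function(r) sum(vals[r$cols]), numeric(1))
  fired <- pct >= vapply(diet_rules, `[[`, numeric(1), "min")
  if (!any(fired)) {
    return(if (all(pct <= 40)) "Generalist" else "unclassified")
  }
  hits <- pct[fired]
  if (length(hits) > 1L) {
    top <- hits[hits == max(hits)]
    if (length(top) > 1L) return("unclassified")  # exact tie (e.g. 50/50)
    return(names(top))
  }
  names(hits)
}

#' Fleiss' kappa for inter-rater agreement
#'
#' Chance-corrected agreement `kappa = (P_bar - P_bar_e) / (1 - P_bar_e)`
#' over a subjects x raters table of categorical assignments, using the
#' standard category-proportion definitions. With the classifier's predicted
#' diets as one "rater" and the true diets as another this scores how well a
#' proxy recovers known diets.
#'
#' @param ratings Matrix or data frame, one row per subject, one column per
#'   rater, entries categorical labels (>= 2 subjects, >= 2 raters).
#' @return List of class `"agreement_result"`: `kappa`, `n_subjects`,
#'   `n_raters`, `categories`, and `flagged` (`TRUE` with `kappa = NA` when
#'   only one category occurs, where kappa is undefined).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); r <- ncol(ratings)
  if (n < 2L || r < 2L) stop("need at least 2 subjects and 2 raters", call. = FALSE)
  cats <- sort(unique(as.character(ratings)))
  if (length(cats) < 2L) {
    return(structure(list(kappa = NA_real_, n_subjects = n, n_raters = r,
                          categories = cats, flagged = TRUE),
                     class = "agreement_result"))
  }
  counts <- t(apply(ratings, 1L, function(x) table(factor(x, levels = cats))))
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(counts) / (n * r)
  P_e <- sum(p_j^2)
  kappa <- if (P_e == 1) 1 else (P_bar - P_e) / (1 - P_e)
  structure(list(kappa = kappa, n_subjects = n, n_raters = r,
                 categories = cats, flagged = FALSE),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (x$flagged) cat("Fleiss' kappa undefined (single category)\n")
  else cat(sprintf("Fleiss' kappa = %.3f (%d subjects, %d raters, %d categories)\n",
                   x$kappa, x$n_subjects, x$n_raters, length(x$categories)))
  invisible(x)
}

#' Combine per-proxy posterior predictions for one fossil
#'
#' For each proxy's posterior table, diets with posterior probability at or
#' above `likely_threshold` are "likely". The "agreed" set holds diets that
#' are likely in every proxy whose category set contains them (category-aware
#' intersection); "unlikely" holds diets below threshold in every proxy that
#' covers them.
#'
#' @param posteriors Named list of per-proxy posteriors for a single fossil:
#'   each element a named numeric vector (or one-row data frame /
#'   `"posterior_table"`) of class probabilities.
#' @param likely_threshold Posterior probability counting as "likely"
#'   (default 0.10).
#' @return List with character vectors `likely` (per proxy), `agreed`,
#'   `unlikely`.
#' @export
evidence_summary <- function(posteriors, likely_threshold = 0.10) {
  if (length(posteriors) == 0L) stop("need at least one proxy posterior table", call. = FALSE)
  as_vec <- function(p) {
    if (is.data.frame(p)) p <- unlist(p[1L, , drop = TRUE])
    if (is.null(names(p)) || length(p) == 0L) stop("posteriors must be named and non-empty", call. = FALSE)
    p
  }
  posts <- lapply(posteriors, as_vec)
  likely <- lapply(posts, function(p) names(p)[p >= likely_threshold])
  all_cats <- unique(unlist(lapply(posts, names)))
  covered_by <- function(cat) names(posts)[vapply(posts, function(p) cat %in% names(p), logical(1))]
  agreed <- Filter(function(cat) {
    prox <- covered_by(cat)
    length(prox) > 0L && all(vapply(prox, function(pr) cat %in% likely[[pr]], logical(1)))
  }, all_cats)
  unlikely <- Filter(function(cat) {
    prox <- covered_by(cat)
    length(prox) > 0L && !any(vapply(prox, function(pr) cat %in% likely[[pr]], logical(1)))
  }, all_cats)
  list(likely = likely, agreed = as.character(agreed), unlikely = as.character(unlikely))
}
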