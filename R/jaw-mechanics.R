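# Jaw lever mechanics and size-free shape indices. All quantities are ratios
# of linear measurements, so absolute scale is never required and every index
# is invariant under uniform scaling and rigid motion of the input geometry.

#' Mechanical advantage of a lever system
#'
#' @param in_lever,out_lever Lever arm lengths (same units); `out_lever > 0`.
#' @return `in_lever / out_lever`.
#' @examples
#' mechanical_advantage(1, 4)  # 0.25
#' @export
mechanical_advantage <- function(in_lever, out_lever) {
  if (any(out_lever <= 0)) stop("out-lever must be positive", call. = FALSE)
  in_lever / out_lever
}

#' Jaw mechanical-advantage and functional indices
#'
#' Computes, per jaw (upper and lower), the anterior and posterior
#' jaw-closing mechanical advantage (AMA, PMA) and the jaw-opening mechanical
#' advantage (OMA), plus the size-free shape indices: relative articular
#' offset AO (lower jaw), relative average cranium height ACH, and relative
#' maximum / average mandibular height (MMH, AMH). Any index whose inputs are
#' missing (`NA` or absent) is returned as `NA`; the others are still
#' computed.
#'
#' @param m Named list or one-row data frame of measurements (all in the same
#'   linear units): `upper_closing_inlever`, `upper_opening_inlever`,
#'   `upper_anterior_outlever`, `upper_posterior_outlever`, and the `lower_*`
#'   equivalents; `lower_jaw_length`, `articular_offset`,
#'   `cranium_avg_height`, `cranium_length` (the explicit ACH denominator),
#'   `mandible_max_height`, `mandible_avg_height`.
#' @return One-row data frame with `AMA_upper`, `PMA_upper`, `OMA_upper`,
#'   `AMA_lower`, `PMA_lower`, `OMA_lower`, `AO`, `ACH`, `MMH`, `AMH`.
#' @export
jaw_indices <- function(m) {
  get <- function(nm) {
    v <- m[[nm]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
  }
  ratio <- function(num, den) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den <= 0) stop("denominator measurement must be positive", call. = FALSE)
    num / den
  }
  data.frame(
    AMA_upper = ratio(get("upper_closing_inlever"), get("upper_anterior_outlever")),
    PMA_upper = ratio(get("upper_closing_inlever"), get("upper_posterior_outlever")),
    OMA_upper = ratio(get("upper_opening_inlever"), get("upper_anterior_outlever")),
    AMA_lower = ratio(get("lower_closing_inlever"), get("lower_anterior_outlever")),
    PMA_lower = ratio(get("lower_closing_inlever"), get("lower_posterior_outlever")),
    OMA_lower = ratio(get("lower_opening_inlever"), get("lower_anterior_outlever")),
    AO  = ratio(get("articular_offset"), get("lower_jaw_length")),
    ACH = ratio(get("cranium_avg_height"), get("cranium_length")),
    MMH = ratio(get("mandible_max_height"), get("lower_jaw_length")),
    AMH = ratio(get("mandible_avg_height"), get("lower_jaw_length"))
  )
}

#' Quadrate-position sensitivity of jaw levers
#'
#' Recomputes lever-based indices with the jaw articulation (quadrate contact)
#' moved to alternative positions, as in sensitivity analyses that slide the
#' articulation to the extreme anterior and posterior ends of the articular
#' surface. Lever endpoints (muscle insertions and bite points) stay fixed;
#' all in- and out-levers are re-measured as distances from each candidate
#' articulation.
#'
#' @param geometry Named list of 2D points (each `c(x, y)`; a single number is
#'   taken as `c(x, 0)`): `articulation` (baseline), `closing_insertion`,
#'   `opening_insertion` (optional), `anterior_bite`, `posterior_bite`
#'   (optional).
#' @param articulation_positions List of alternative articulation points (same
#'   format). The baseline is always returned first under the name
#'   `"baseline"`.
#' @return Data frame, one row per scenario: lever lengths plus `AMA`, `PMA`,
#'   `OMA` where computable.
#' @examples
#' g <- list(articulation = 0, closing_insertion = 1, anterior_bite = 10)
#' quadrate_sensitivity(g, list(shifted = -1))  # AMA 0.1 -> 2/11
#' @export
quadrate_sensitivity <- function(geometry, articulation_positions = list()) {
  as_pt <- function(p) if (length(p) == 1L) c(p, 0) else as.numeric(p[1:2])
  dist2d <- function(a, b) sqrt(sum((a - b)^2))
  fixed <- lapply(geometry[setdiff(names(geometry), "articulation")], as_pt)
  scenarios <- c(list(baseline = as_pt(geometry$articulation)),
                 lapply(articulation_positions, as_pt))
  rows <- lapply(names(scenarios), function(nm) {
    art <- scenarios[[nm]]
    lever <- function(pt_name) {
      if (is.null(fixed[[pt_name]])) return(NA_real_)
      l <- dist2d(art, fixed[[pt_name]])
      if (l == 0) stop("articulation coincides with lever endpoint '", pt_name, "'", call. = FALSE)
      l
    }
    ci <- lever("closing_insertion"); oi <- lever("opening_insertion")
    ab <- lever("anterior_bite"); pb <- lever("posterior_bite")
    data.frame(scenario = nm, closing_inlever = ci, opening_inlever = oi,
               anterior_outlever = ab, posterior_outlever = pb,
               AMA = if (!is.na(ci) && !is.na(ab)) ci / ab else NA_real_,
               PMA = if (!is.na(ci) && !is.na(pb)) ci / pb else NA_real_,
               OMA = if (!is.na(oi) && !is.na(ab)) oi / ab else NA_real_)
  })
  do.call(rbind, rows)
}
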