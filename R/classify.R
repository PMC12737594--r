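#' The triangular suitability region
#'
#' A suitable dog's scores are expected to show positive valence with
#' arousal fluctuating between moderate positive and negative values,
#' increasing in amplitude as valence grows. On the valence-arousal plane
#' this is the closed triangle with vertices at the origin, (+5, +3), and
#' (+5, -3): the set \{(x, y): 0 <= x <= 5, |y| <= 0.6 x\}. Vertices and
#' edges belong to the region.
#'
#' @param max_valence Valence coordinate of the far vertices (default 5).
#' @param max_arousal Absolute arousal at `max_valence` (default 3).
#' @return An object of class `suitability_region`.
#' @export
#' @examples
#' r <- suitability_region()
#' in_region(c(0, 5, 2.5, -1), c(0, 3, 2, 0), r)
suitability_region <- function(max_valence = 5, max_arousal = 3) {
  stopifnot(max_valence > 0, max_arousal > 0)
  structure(list(max_valence = max_valence, max_arousal = max_arousal,
                 slope = max_arousal / max_valence),
            class = "suitability_region")
}

#' Test membership in the suitability region
#'
#' @param valence,arousal Numeric vectors (validated against \[-5, 5\]).
#' @param region A [suitability_region()].
#' @return A logical vector: `TRUE` where the point lies inside the closed
#'   triangle.
#' @export
in_region <- function(valence, arousal, region = suitability_region()) {
  validate_score(valence, arousal)
  valence >= 0 & valence <= region$max_valence &
    abs(arousal) <= region$slope * valence
}

#' Configuration of the suitability decision rule
#'
#' Tunable parameters of the deterministic S/P/U rule. The defaults encode
#' the published decision logic: a majority (strictly more than
#' `majority_threshold` of the *scored* sub-phases) inside the triangular
#' region is required for suitability; high-arousal episodes (arousal above
#' the region at positive valence, e.g. jumping on a stranger) demote S to
#' pending; the food-motivation sub-phase is exempted when everything else
#' is inside and overall valence is positive; poor performance in the most
#' relevant ("critical") sub-phases vetoes suitability; any aggressive
#' episode is immediately unsuitable.
#'
#' @param majority_threshold Fraction of scored sub-phases that must be
#'   strictly exceeded inside the region (default 0.5).
#' @param high_arousal_cutoff Arousal above which a positive-valence score
#'   counts as a high-arousal episode even inside the vertical band
#'   (default +3, the region's arousal cap).
#' @param episode_k Number of high-arousal episodes needed to demote S to P
#'   (default 1).
#' @param food_exempt Sub-phase code exempted by the food-motivation rule
#'   (default `"b"`).
#' @param critical Codes of the critical sub-phases (default
#'   `c("d","e","f","m","q","u")`: unusual objects, sounds, handling by
#'   strangers/groups).
#' @param borderline Class assigned when the majority of scores is outside
#'   the region but median valence is non-negative: `"unsuitable"` (default)
#'   or `"pending"`.
#' @param region A [suitability_region()].
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(majority_threshold = 0.5,
                                  high_arousal_cutoff = 3,
                                  episode_k = 1L,
                                  food_exempt = "b",
                                  critical = c("d", "e", "f", "m", "q", "u"),
                                  borderline = c("unsuitable", "pending"),
                                  region = suitability_region()) {
  borderline <- match.arg(borderline)
  stopifnot(majority_threshold >= 0, majority_threshold <= 1,
            high_arousal_cutoff <= 5, episode_k >= 1,
            all(critical %in% subphase_codes()),
            all(food_exempt %in% subphase_codes()))
  structure(list(majority_threshold = majority_threshold,
                 high_arousal_cutoff = high_arousal_cutoff,
                 episode_k = as.integer(episode_k),
                 food_exempt = food_exempt, critical = critical,
                 borderline = borderline, region = region),
            class = "classification_config")
}

#' Classify one dyad's consensus sheet as S, P, or U
#'
#' Applies the decision rules in fixed priority order and records which
#' rule fired:
#' \enumerate{
#'   \item any aggression flag -> U;
#'   \item valence of -5 in a critical sub-phase -> U;
#'   \item food exemption: every scored sub-phase except the
#'     food-motivation one inside the region, and median valence positive
#'     -> S;
#'   \item inside fraction above the majority threshold, no high-arousal
#'     episode, no critical sub-phase with negative valence -> S;
#'   \item inside fraction above the threshold but at least `episode_k`
#'     high-arousal episodes (arousal above the cutoff or above the region's
#'     upper edge, at positive valence) or a critical sub-phase with
#'     negative valence -> P;
#'   \item majority outside and median valence negative -> U;
#'   \item majority outside, median valence non-negative -> the configured
#'     borderline class (default U).
#' }
#'
#' @param sheet A `consensus_sheet` (or data frame with `subphase`,
#'   `valence`, `arousal`, `aggression`, `refusal`) with at least one score.
#' @param config A [classification_config()].
#' @return An object of class `suitability_classification`: a list with the
#'   assigned `class` (`"S"`, `"P"`, `"U"`), the `inside_fraction`, median
#'   valence and arousal, the ordered `rules` that triggered, and the
#'   per-sub-phase `membership` table.
#' @export
classify_dyad <- function(sheet, config = classification_config()) {
  if (is.null(sheet) || nrow(sheet) == 0L) {
    stop("cannot classify an empty score sheet", call. = FALSE)
  }
  dyad_id <- attr(sheet, "dyad_id") %||% NA_character_
  sheet <- as.data.frame(sheet)
  sheet <- sheet[order(sheet$subphase), , drop = FALSE]
  inside <- in_region(sheet$valence, sheet$arousal, config$region)
  n <- nrow(sheet)
  frac <- mean(inside)
  med_v <- stats::median(sheet$valence)
  med_a <- stats::median(sheet$arousal)
  above_region <- sheet$valence > 0 &
    sheet$arousal > config$region$slope * sheet$valence
  episode <- sheet$valence > 0 &
    (sheet$arousal > config$high_arousal_cutoff | above_region)
  crit <- sheet$subphase %in% config$critical
  crit_floor <- any(crit & sheet$valence <= -5)
  crit_neg <- any(crit & sheet$valence < 0)
  non_food_inside <- all(inside[!sheet$subphase %in% config$food_exempt])
  rules <- character()
  if (any(sheet$aggression)) {
    cls <- "U"; rules <- "R1_aggression"
  } else if (crit_floor) {
    cls <- "U"; rules <- "R2_critical_valence_floor"
  } else if (non_food_inside && !all(inside) && med_v > 0) {
    cls <- "S"; rules <- "R3_food_exemption"
  } else if (frac > config$majority_threshold &&
             sum(episode) < config$episode_k && !crit_neg) {
    cls <- "S"; rules <- "R4_majority_inside"
  } else if (frac > config$majority_threshold) {
    cls <- "P"
    rules <- c(if (sum(episode) >= config$episode_k) "R5_high_arousal_episodes",
               if (crit_neg) "R5_critical_negative_valence")
  } else if (med_v < 0) {
    cls <- "U"; rules <- "R6_majority_outside_negative_valence"
  } else {
    cls <- if (config$borderline == "unsuitable") "U" else "P"
    rules <- "R7_borderline_policy"
  }
  structure(list(
    dyad_id = dyad_id,
    class = cls,
    inside_fraction = frac,
    n_scored = n,
    median_valence = med_v,
    median_arousal = med_a,
    n_episodes = sum(episode),
    rules = rules,
    membership = data.frame(subphase = sheet$subphase,
                            valence = sheet$valence,
                            arousal = sheet$arousal,
                            inside = inside,
                            episode = episode,
                            stringsAsFactors = FALSE),
    config = config
  ), class = "suitability_classification")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.suitability_classification <- function(x, ...) {
  cat(sprintf("Suitability classification for dyad %s: %s\n", x$dyad_id, x$class))
  cat(sprintf("  scored sub-phases: %d | inside region: %.1f%% | episodes: %d\n",
              x$n_scored, 100 * x$inside_fraction, x$n_episodes))
  cat(sprintf("  median valence: %.2f | median arousal: %.2f\n",
              x$median_valence, x$median_arousal))
  cat("  triggered rule(s): ", paste(x$rules, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot a classified sheet on the valence-arousal grid
#'
#' Draws the Cartesian scoring grid with the triangular suitability region
#' shaded and the dyad's sub-phase scores overlaid (filled points inside the
#' region, open points outside).
#'
#' @param x A `suitability_classification`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.suitability_classification <- function(x, ...) {
  r <- x$config$region
  graphics::plot(NA, xlim = c(-5, 5), ylim = c(-5, 5),
                 xlab = "Valence", ylab = "Arousal",
                 main = sprintf("Dyad %s: %s", x$dyad_id, x$class), ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::polygon(c(0, r$max_valence, r$max_valence),
                    c(0, r$max_arousal, -r$max_arousal),
                    col = grDevices::adjustcolor("darkgreen", 0.2),
                    border = "darkgreen")
  m <- x$membership
  graphics::points(m$valence, m$arousal, pch = ifelse(m$inside, 19, 1),
                   col = ifelse(m$inside, "darkgreen", "firebrick"))
  invisible(x)
}

#' Classify every dyad in a set of consensus sheets
#'
#' @param sheets A named list of consensus sheets (names or `dyad_id`
#'   attributes identify the dyads).
#' @param config A [classification_config()].
#' @return A data frame with one row per dyad: `dyad_id`, `class`,
#'   `inside_fraction`, `n_scored`, `median_valence`, `median_arousal`,
#'   `n_episodes`, `rules` (collapsed).
#' @export
classify_cohort <- function(sheets, config = classification_config()) {
  res <- lapply(sheets, classify_dyad, config = config)
  out <- do.call(rbind, lapply(res, function(r) {
    data.frame(dyad_id = r$dyad_id, class = r$class,
               inside_fraction = r$inside_fraction, n_scored = r$n_scored,
               median_valence = r$median_valence,
               median_arousal = r$median_arousal,
               n_episodes = r$n_episodes,
               rules = paste(r$rules, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
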