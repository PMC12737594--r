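#' The caregiver questionnaire sections
#'
#' Seven sections, each answered on a bounded ordinal scale and tagged as a
#' frequency or intensity measure (C-BARQ convention).
#'
#' @return A data frame with columns `section` and `type`.
#' @export
questionnaire_sections <- function() {
  data.frame(
    section = c("trainability_obedience", "separation", "aggression",
                "fear_anxiety", "excitability", "attachment", "other"),
    type = c("frequency", "frequency", "intensity", "intensity",
             "intensity", "frequency", "frequency"),
    stringsAsFactors = FALSE
  )
}

#' Score one questionnaire section
#'
#' Aggregates the answered items of a section into a section score. The
#' default policy is the arithmetic mean of the answered items (missing
#' items are excluded from the denominator); a sum policy is available for
#' sections conventionally reported as totals.
#'
#' @param items Numeric vector of ordinal item scores (NAs = unanswered).
#' @param aggregation `"mean"` (default) or `"sum"`.
#' @param scale Length-2 numeric giving the permissible item range
#'   (default `c(0, 4)`).
#' @return The section score (a single number).
#' @export
#' @examples
#' score_section(c(0, 1, 0, 1))        # 0.5
#' score_section(c(2, NA, 4), "sum")   # 6
score_section <- function(items, aggregation = c("mean", "sum"),
                          scale = c(0, 4)) {
  aggregation <- match.arg(aggregation)
  items <- items[!is.na(items)]
  if (!length(items)) stop("all items of the section are missing", call. = FALSE)
  if (any(items < scale[1L] | items > scale[2L])) {
    stop(sprintf("item score outside the [%g, %g] scale", scale[1L], scale[2L]),
         call. = FALSE)
  }
  switch(aggregation, mean = mean(items), sum = sum(items))
}

OPEN_ENDED_LEVELS <- c("Yes", "Yes after a training programme", "Maybe", "No")

#' Map the caregiver's open-ended verdict to an expected class
#'
#' The open-ended suitability question ("would your dog be suitable for
#' AAI?") is pre-simplified upstream into four categories, which map
#' deterministically onto the three-level test outcome: "Yes" to S, "No" to
#' U, and both "Maybe" and "Yes after a training programme" to P.
#'
#' @param category Character vector of categories (case-insensitive;
#'   `"Yes after training"` and `"Yes after a training program"` are
#'   accepted spellings of the training-programme category).
#' @return A character vector over `{"S", "P", "U"}`.
#' @export
#' @examples
#' map_open_ended(c("Yes", "Maybe", "No"))
map_open_ended <- function(category) {
  key <- tolower(trimws(as.character(category)))
  key[key %in% c("yes after training", "yes after a training program",
                 "yes after a training programme")] <- "yes after a training programme"
  lut <- c("yes" = "S", "yes after a training programme" = "P",
           "maybe" = "P", "no" = "U")
  bad <- !key %in% names(lut)
  if (any(bad)) {
    stop("unknown open-ended category: ",
         paste(unique(category[bad]), collapse = ", "),
         ". Accepted: ", paste(OPEN_ENDED_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  unname(lut[key])
}

#' Score a full questionnaire table
#'
#' Accepts a wide per-dyad table whose item columns are section-prefixed
#' (e.g. `separation_1`, `separation_2`, ...). Columns named exactly after a
#' section are taken as pre-aggregated section scores. A `verdict` column,
#' when present, is carried through with its mapped expected class.
#'
#' @param df Data frame with a `dyad_id` column, item or section columns,
#'   and optionally `verdict`.
#' @param aggregation Named character vector of per-section policies
#'   (`"mean"`/`"sum"`); unnamed single value recycles to all sections.
#' @param scale Item scale passed to [score_section()].
#' @return A data frame with `dyad_id`, one column per scored section, and
#'   (when a verdict is present) `verdict` and `expected_class`.
#' @export
score_questionnaire <- function(df, aggregation = "mean", scale = c(0, 4)) {
  stopifnot("dyad_id" %in% names(df))
  sections <- questionnaire_sections()$section
  if (is.null(names(aggregation))) {
    aggregation <- stats::setNames(rep(aggregation[1L], length(sections)), sections)
  } else {
    full <- stats::setNames(rep("mean", length(sections)), sections)
    full[names(aggregation)] <- aggregation
    aggregation <- full
  }
  out <- data.frame(dyad_id = as.character(df$dyad_id), stringsAsFactors = FALSE)
  for (sec in sections) {
    if (sec %in% names(df)) {
      out[[sec]] <- as.numeric(df[[sec]])
    } else {
      cols <- grep(paste0("^", sec, "_"), names(df), value = TRUE)
      if (!length(cols)) next
      out[[sec]] <- apply(df[cols], 1L, function(items) {
        score_section(as.numeric(items), aggregation[[sec]], scale = scale)
      })
    }
  }
  if ("verdict" %in% names(df)) {
    out$verdict <- as.character(df$verdict)
    out$expected_class <- map_open_ended(out$verdict)
  }
  out
}

#' Caregiver verdicts and test classifications for the 38-dyad cohort
#'
#' The published screening cohort's caregiver verdict categories (simplified
#' open-ended answers) paired with the behavioural-test classification, one
#' row per dyad. Used to reproduce the caregiver-versus-test agreement
#' analysis (3x3 contingency, Cohen's kappa, concordance).
#'
#' @return A data frame with columns `dyad_id`, `category`, `test_class`.
#' @export
#' @examples
#' v <- caregiver_verdicts()
#' table(map_open_ended(v$category), v$test_class)
caregiver_verdicts <- function() {
  path <- system.file("extdata", "caregiver_verdicts.csv", package = "aaiscreen")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
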