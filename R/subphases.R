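#' Registry of scored test sub-phases
#'
#' The behavioural aptitude test comprises 26 sub-phases coded `a`--`z`, of
#' which the first 24 (`a`--`x`) are scored on the valence--arousal grid.
#' Sub-phases `a`--`f` expose the dog to environmental stimuli (exploration,
#' food, toys, unusual objects, sounds); `g`--`x` are social stimuli
#' (separation, handling, strangers, groups, unusual social appearances).
#' Sub-phases `y` and `z` use a different grid and are rejected by the scored
#' sheet schema.
#'
#' @return A data frame with columns `code` (letters a--x), `label`
#'   (descriptive name), and `phase` (`"environmental"` or `"social"`).
#' @export
#' @examples
#' subphase_table()
subphase_table <- function() {
  data.frame(
    code = letters[1:24],
    label = c(
      "room exploration", "food motivation", "toy motivation",
      "unusual static objects", "sounds", "unusual moving objects",
      "separation", "social attraction (caregiver)", "handling (caregiver)",
      "brush (caregiver)", "play invitation (caregiver)",
      "social attraction (female stranger)", "handling (female stranger)",
      "brush (female stranger)", "play invitation (female stranger)",
      "social attraction (male stranger)", "handling (male stranger)",
      "brush (male stranger)", "play invitation (male stranger)",
      "social attraction (group)", "handling (group)",
      "white coat and surgical face mask", "crutches and sunglasses",
      "baby doll"
    ),
    phase = c(rep("environmental", 6), rep("social", 18)),
    stringsAsFactors = FALSE
  )
}

#' @rdname subphase_table
#' @export
subphase_codes <- function() letters[1:24]

#' Validate valence-arousal score pairs
#'
#' Both axes of the circumplex grid are bounded to \[-5, +5\]: valence (x)
#' spans withdrawal/aggression (-5) to approach/tolerance (+5); arousal (y)
#' spans passive (-5) to highly activated (+5). Vectors are validated
#' element-wise.
#'
#' @param valence,arousal Numeric vectors of equal length.
#' @return Invisibly, a data frame with the validated `valence` and `arousal`.
#'   Errors name the offending axis and value.
#' @export
#' @examples
#' validate_score(2.5, 1.5)
validate_score <- function(valence, arousal) {
  if (!is.numeric(valence) || !is.numeric(arousal)) {
    stop("valence and arousal must be numeric", call. = FALSE)
  }
  if (length(valence) != length(arousal)) {
    stop("valence and arousal must have the same length", call. = FALSE)
  }
  check_axis <- function(x, axis) {
    bad <- which(!is.na(x) & (x < -5 | x > 5))
    if (length(bad)) {
      stop(sprintf(
        "%s out of range [-5, 5]: %s",
        axis, paste(format(x[bad[seq_len(min(5, length(bad)))]]), collapse = ", ")
      ), call. = FALSE)
    }
  }
  check_axis(valence, "valence")
  check_axis(arousal, "arousal")
  invisible(data.frame(valence = valence, arousal = arousal))
}

#' Apply behaviour-flag overrides to raw scores
#'
#' Two overrides take precedence over the evaluator's coordinate: an
#' aggressive episode is scored (-5, +5) regardless of the raw coordinate,
#' and refusal to participate in a sub-phase forces valence to -5 while the
#' observed arousal is retained. The operation is idempotent and preserves
#' the flags.
#'
#' @param scores A data frame with numeric columns `valence` and `arousal`
#'   and logical columns `aggression` and `refusal`.
#' @return The data frame with overrides applied.
#' @export
#' @examples
#' apply_overrides(data.frame(valence = 3, arousal = 1,
#'                            aggression = TRUE, refusal = FALSE))
apply_overrides <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("valence", "arousal", "aggression", "refusal") %in% names(scores)))
  validate_score(scores$valence, scores$arousal)
  agg <- scores$aggression %in% TRUE
  ref <- scores$refusal %in% TRUE
  scores$valence[agg] <- -5
  scores$arousal[agg] <- 5
  scores$valence[ref & !agg] <- -5
  scores
}

empty_score_frame <- function() {
  data.frame(subphase = character(), valence = numeric(), arousal = numeric(),
             aggression = logical(), refusal = logical(), note = character(),
             stringsAsFactors = FALSE)
}

normalise_score_frame <- function(scores, allow_missing = TRUE) {
  needed <- c("subphase", "valence", "arousal")
  miss <- setdiff(needed, names(scores))
  if (length(miss)) stop("score sheet lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"aggression" %in% names(scores)) scores$aggression <- FALSE
  if (!"refusal" %in% names(scores)) scores$refusal <- FALSE
  if (!"note" %in% names(scores)) scores$note <- ""
  scores$subphase <- as.character(scores$subphase)
  bad <- !scores$subphase %in% subphase_codes()
  if (any(bad)) {
    stop("unknown sub-phase code(s): ",
         paste(unique(scores$subphase[bad]), collapse = ", "),
         " (scored sub-phases are a-x)", call. = FALSE)
  }
  if (anyDuplicated(scores$subphase)) {
    stop("duplicate sub-phase scores: ",
         paste(unique(scores$subphase[duplicated(scores$subphase)]), collapse = ", "),
         call. = FALSE)
  }
  validate_score(scores$valence, scores$arousal)
  scores$aggression <- scores$aggression %in% TRUE
  scores$refusal <- scores$refusal %in% TRUE
  scores[order(scores$subphase),
         c("subphase", "valence", "arousal", "aggression", "refusal", "note"),
         drop = FALSE]
}

#' Construct a single rater's score sheet
#'
#' One evaluator's sheet for one dog-caregiver dyad: at most one
#' (valence, arousal) judgment per scored sub-phase, plus aggression and
#' refusal flags. Missing sub-phases are tolerated and simply absent;
#' completeness is reported, not assumed.
#'
#' @param dyad_id Identifier of the dog-caregiver dyad.
#' @param rater_id Identifier of the evaluator.
#' @param scores Data frame with columns `subphase`, `valence`, `arousal`,
#'   and optionally `aggression`, `refusal`, `note`.
#' @return An object of class `rater_sheet` (a validated data frame with
#'   `dyad_id` and `rater_id` attributes).
#' @export
rater_sheet <- function(dyad_id, rater_id, scores) {
  out <- normalise_score_frame(scores)
  structure(out, dyad_id = as.character(dyad_id),
            rater_id = as.character(rater_id),
            class = c("rater_sheet", "data.frame"))
}

#' Aggregate rater sheets into a consensus sheet
#'
#' Combines independent evaluators' sheets for the same dyad into a single
#' consensus sheet. Per sub-phase, valence and arousal are aggregated over
#' the raters who scored it (arithmetic mean by default), behaviour flags
#' are OR'd, and the flag overrides are re-applied after aggregation so a
#' flagged sub-phase can never average away. Sub-phases scored by no rater
#' are absent from the consensus.
#'
#' @param sheets A list of [rater_sheet()] objects for the same dyad (a
#'   single sheet may be passed directly).
#' @param method Aggregation policy for the coordinates: `"mean"` (default),
#'   `"median"`, or `"first"` (first contributing rater's value).
#' @return An object of class `consensus_sheet` with attributes `dyad_id`,
#'   `raters`, and `method`.
#' @export
aggregate_raters <- function(sheets, method = c("mean", "median", "first")) {
  method <- match.arg(method)
  if (inherits(sheets, "rater_sheet")) sheets <- list(sheets)
  if (!length(sheets)) stop("no rater sheets supplied", call. = FALSE)
  dyads <- unique(vapply(sheets, attr, "", "dyad_id"))
  if (length(dyads) != 1L) {
    stop("rater sheets belong to different dyads: ",
         paste(dyads, collapse = ", "), call. = FALSE)
  }
  raters <- vapply(sheets, attr, "", "rater_id")
  all_rows <- do.call(rbind, lapply(sheets, function(s) as.data.frame(s)))
  agg_fun <- switch(method, mean = mean, median = stats::median,
                    first = function(x) x[1L])
  by_sub <- split(all_rows, all_rows$subphase)
  out <- do.call(rbind, lapply(by_sub, function(d) {
    data.frame(
      subphase = d$subphase[1L],
      valence = agg_fun(d$valence),
      arousal = agg_fun(d$arousal),
      aggression = any(d$aggression),
      refusal = any(d$refusal),
      note = paste(d$note[nzchar(d$note)], collapse = "; "),
      stringsAsFactors = FALSE
    )
  }))
  out <- apply_overrides(out)
  rownames(out) <- NULL
  structure(out[order(out$subphase), , drop = FALSE],
            dyad_id = dyads, raters = raters, method = method,
            class = c("consensus_sheet", "data.frame"))
}

#' Descriptive summary of a score sheet
#'
#' Per-dyad descriptives in the style of the study's score table: mean,
#' median, quartiles (linear interpolation), minimum, maximum of valence and
#' arousal, and the number of scored sub-phases.
#'
#' @param sheet A `consensus_sheet`, `rater_sheet`, or plain data frame with
#'   `valence` and `arousal` columns.
#' @return A data frame with one row per dimension (`valence`, `arousal`).
#' @export
summarize_sheet <- function(sheet) {
  stopifnot(nrow(sheet) >= 1L)
  one <- function(x, dim) {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(dimension = dim, n = length(x), mean = mean(x),
               median = stats::median(x), q1 = q[1L], q3 = q[2L],
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }
  rbind(one(sheet$valence, "valence"), one(sheet$arousal, "arousal"))
}
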