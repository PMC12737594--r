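#' Snap scores to the half-point grid
#'
#' Evaluators score on a 0.5-step grid; generated values are rounded to the
#' nearest half point and clipped to \[-5, 5\].
#'
#' @param x Numeric vector.
#' @return Snapped vector.
#' @export
snap_to_grid <- function(x) pmin(5, pmax(-5, round(x * 2) / 2))

default_questionnaire_params <- function() {
  # Significant sections use the published S+P vs U group moments; the
  # non-significant sections (trainability, excitability, other) are
  # class-independent with plausible 0-4-scale values.
  list(
    trainability_obedience = list(sp = c(2.4, 0.7), u = c(2.4, 0.7)),
    separation = list(sp = c(0.205, 0.223), u = c(0.677, 0.613)),
    aggression = list(sp = c(8.857, 6.815), u = c(16.750, 11.674)),
    fear_anxiety = list(sp = c(0.493, 0.379), u = c(0.903, 0.520)),
    excitability = list(sp = c(1.6, 0.7), u = c(1.6, 0.7)),
    attachment = list(sp = c(1.857, 0.727), u = c(2.424, 0.815)),
    other = list(sp = c(0.9, 0.6), u = c(0.9, 0.6))
  )
}

default_verdict_matrix <- function() {
  # P(caregiver verdict class | latent test class), columns = latent class.
  # Renormalised from the observed 38-dyad contingency structure.
  matrix(c(1, 0, 0,            # latent S: Yes always
           3 / 5, 1 / 5, 1 / 5, # latent P
           10 / 24, 4 / 24, 10 / 24), # latent U
         nrow = 3, dimnames = list(verdict = c("S", "P", "U"),
                                   latent = c("S", "P", "U")))
}

#' Configuration of the synthetic-cohort generator
#'
#' Defines the study conditions the generator emulates: a 38-dyad cohort
#' with latent class proportions 9:5:24 (S:P:U), per-class truncated-normal
#' valence/arousal score distributions moment-matched to the published
#' score table, two raters with independent scoring error, questionnaire
#' section scores with the published group moments, caregiver verdicts
#' drawn conditionally on the latent class, and log-normal cortisol pairs
#' with no class effect on the delta.
#'
#' @param n_dyads Number of dyads (default 38).
#' @param class_probs Latent class probabilities, named S/P/U (default
#'   9/38, 5/38, 24/38).
#' @param valence_mean,valence_sd,arousal_mean,arousal_sd Per-class score
#'   moments in S, P, U order (defaults: valence 2.5/2.1/0.4 with SD
#'   1.0/1.2/2.2; arousal 1.0/1.2/1.5 with SD 1.3/1.7/1.8).
#' @param rater_error_sd SD of each evaluator's independent scoring error
#'   (default 1.35, calibrated so the pooled two-rater ICC is about 0.65,
#'   with valence near 0.70 and arousal near 0.61).
#' @param equicorrelation Within-dog correlation of sub-phase scores
#'   (share of the class score variance attributed to a dog-level random
#'   effect; default 0 = independence given class).
#' @param aggression_prob Per-sub-phase probability of an aggressive
#'   episode by class (default 0, 0, 0.01).
#' @param refusal_prob Per-sub-phase probability of refusal by class
#'   (default 0).
#' @param missing_prob Probability that any single rater-by-sub-phase score
#'   is missing (default 1/912).
#' @param questionnaire Named list of per-section generation parameters,
#'   each `list(sp = c(mean, sd), u = c(mean, sd))` (see
#'   `aaiscreen:::default_questionnaire_params`). Section scores are drawn
#'   from gamma distributions matching the given mean and SD exactly
#'   (non-negative, right-skewed when SD approaches the mean).
#' @param cortisol List with `meanlog`, `sdlog` (log-normal marginal fit to
#'   the published overall moments, mean 1.58 and SD 1.40 ng/mL) and
#'   `dyad_share` (share of log-variance at the dog level, inducing T0-T1
#'   correlation; delta is centred at zero with no class effect).
#' @param verdict_matrix 3x3 matrix of P(verdict class | latent class),
#'   verdict in rows, latent class in columns.
#' @param pending_split Probabilities of "Maybe" vs "Yes after a training
#'   programme" within a pending-type verdict.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_dyads = 38,
                             class_probs = c(S = 9, P = 5, U = 24) / 38,
                             valence_mean = c(S = 2.5, P = 2.1, U = 0.4),
                             valence_sd = c(S = 1.0, P = 1.2, U = 2.2),
                             arousal_mean = c(S = 1.0, P = 1.2, U = 1.5),
                             arousal_sd = c(S = 1.3, P = 1.7, U = 1.8),
                             rater_error_sd = 1.35,
                             equicorrelation = 0,
                             aggression_prob = c(S = 0, P = 0, U = 0.01),
                             refusal_prob = c(S = 0, P = 0, U = 0),
                             missing_prob = 1 / 912,
                             questionnaire = default_questionnaire_params(),
                             cortisol = list(meanlog = 0.169, sdlog = 0.760,
                                             dyad_share = 0.5),
                             verdict_matrix = default_verdict_matrix(),
                             pending_split = c(maybe = 0.6, after_training = 0.4)) {
  if (abs(sum(class_probs) - 1) > 1e-8 || any(class_probs < 0)) {
    stop("class_probs must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(all(valence_sd > 0), all(arousal_sd > 0), rater_error_sd >= 0,
            equicorrelation >= 0, equicorrelation < 1,
            missing_prob >= 0, missing_prob < 1,
            all(abs(colSums(verdict_matrix) - 1) < 1e-8))
  structure(list(n_dyads = as.integer(n_dyads), class_probs = class_probs,
                 valence_mean = valence_mean, valence_sd = valence_sd,
                 arousal_mean = arousal_mean, arousal_sd = arousal_sd,
                 rater_error_sd = rater_error_sd,
                 equicorrelation = equicorrelation,
                 aggression_prob = aggression_prob,
                 refusal_prob = refusal_prob,
                 missing_prob = missing_prob,
                 questionnaire = questionnaire, cortisol = cortisol,
                 verdict_matrix = verdict_matrix,
                 pending_split = pending_split),
            class = "generator_config")
}

# Non-negative draws matching a target mean and SD exactly: gamma with
# shape (m/s)^2 and scale s^2/m (section scores are bounded below by 0 and
# right-skewed when the SD approaches the mean).
rgamma_ms <- function(n, mean, sd) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- numeric(n)
  pos <- mean > 0
  out[pos] <- stats::rgamma(sum(pos), shape = (mean[pos] / sd[pos])^2,
                            scale = sd[pos]^2 / mean[pos])
  out
}

#' Generate a complete synthetic cohort
#'
#' Draws a seeded synthetic cohort with the full observable data structure
#' of the screening study (two rater score sheets per dyad over the 24
#' scored sub-phases, questionnaire section scores with a caregiver
#' verdict, and a T0/T1 salivary cortisol pair) plus the latent class
#' labels, which are returned separately from the observables so recovery
#' can be tested.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (required for reproducibility).
#' @return An object of class `aai_cohort`: a list with `truth` (dyad_id,
#'   class), `true_scores`, `scores` (long rater rows), `questionnaire`,
#'   `cortisol`, and the `config` and `seed` used.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(), seed = 1)
#' table(cohort$truth$class)
generate_cohort <- function(config = generator_config(), seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!missing(seed) && !is.null(seed)) set.seed(seed) else seed <- NA_integer_
  n <- config$n_dyads
  subs <- subphase_codes()
  ns <- length(subs)
  classes <- sample(c("S", "P", "U"), n, replace = TRUE,
                    prob = config$class_probs)
  dyads <- sprintf("d%02d", seq_len(n))
  truth <- data.frame(dyad_id = dyads, class = classes, stringsAsFactors = FALSE)
  rho <- config$equicorrelation
  idx <- match(classes, c("S", "P", "U"))

  true_scores <- do.call(rbind, lapply(seq_len(n), function(i) {
    ci <- idx[i]
    b_v <- stats::rnorm(1); b_a <- stats::rnorm(1)
    v <- config$valence_mean[ci] + config$valence_sd[ci] *
      (sqrt(rho) * b_v + sqrt(1 - rho) * stats::rnorm(ns))
    a <- config$arousal_mean[ci] + config$arousal_sd[ci] *
      (sqrt(rho) * b_a + sqrt(1 - rho) * stats::rnorm(ns))
    data.frame(dyad_id = dyads[i], subphase = subs,
               valence = snap_to_grid(v), arousal = snap_to_grid(a),
               aggression = stats::runif(ns) < config$aggression_prob[ci],
               refusal = stats::runif(ns) < config$refusal_prob[ci],
               stringsAsFactors = FALSE)
  }))

  scores <- do.call(rbind, lapply(c("R1", "R2"), function(r) {
    s <- true_scores
    s$rater_id <- r
    s$valence <- snap_to_grid(s$valence +
                              stats::rnorm(nrow(s), 0, config$rater_error_sd))
    s$arousal <- snap_to_grid(s$arousal +
                              stats::rnorm(nrow(s), 0, config$rater_error_sd))
    s
  }))
  scores <- apply_overrides(scores)
  scores$note <- ""
  keep <- stats::runif(nrow(scores)) >= config$missing_prob
  scores <- scores[keep, c("dyad_id", "rater_id", "subphase", "valence",
                           "arousal", "aggression", "refusal", "note")]
  rownames(scores) <- NULL

  qp <- config$questionnaire
  questionnaire <- data.frame(dyad_id = dyads, stringsAsFactors = FALSE)
  grp <- ifelse(classes == "U", "u", "sp")
  for (sec in names(qp)) {
    mu <- vapply(grp, function(g) qp[[sec]][[g]][1L], 0)
    sd <- vapply(grp, function(g) qp[[sec]][[g]][2L], 0)
    questionnaire[[sec]] <- rgamma_ms(n, mu, sd)
  }
  vm <- config$verdict_matrix
  verdict_class <- vapply(classes, function(cl) {
    sample(rownames(vm), 1L, prob = vm[, cl])
  }, "")
  pending_label <- sample(c("Maybe", "Yes after a training programme"), n,
                          replace = TRUE, prob = config$pending_split)
  questionnaire$verdict <- ifelse(
    verdict_class == "S", "Yes",
    ifelse(verdict_class == "U", "No", pending_label))

  co <- config$cortisol
  s_b <- co$sdlog * sqrt(co$dyad_share)
  s_e <- co$sdlog * sqrt(1 - co$dyad_share)
  b <- stats::rnorm(n, 0, s_b)
  cortisol <- data.frame(
    dyad_id = dyads,
    t0 = exp(co$meanlog + b + stats::rnorm(n, 0, s_e)),
    t1 = exp(co$meanlog + b + stats::rnorm(n, 0, s_e)),
    stringsAsFactors = FALSE
  )

  structure(list(truth = truth, true_scores = true_scores, scores = scores,
                 questionnaire = questionnaire, cortisol = cortisol,
                 config = config, seed = seed),
            class = "aai_cohort")
}

#' @export
print.aai_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d dyads (seed %s)\n", nrow(x$truth), x$seed))
  print(table(latent = x$truth$class))
  cat(sprintf("%d rater score rows, %d questionnaire rows, %d cortisol pairs\n",
              nrow(x$scores), nrow(x$questionnaire), nrow(x$cortisol)))
  invisible(x)
}

#' Split a long score table into rater sheets
#'
#' @param scores Long data frame with `dyad_id`, `rater_id`, `subphase`,
#'   `valence`, `arousal`, `aggression`, `refusal` columns.
#' @return A list of [rater_sheet()] objects, one per (dyad, rater).
#' @export
sheets_from_scores <- function(scores) {
  key <- interaction(scores$dyad_id, scores$rater_id, drop = TRUE)
  lapply(split(scores, key), function(d) {
    rater_sheet(d$dyad_id[1L], d$rater_id[1L],
                d[c("subphase", "valence", "arousal", "aggression",
                    "refusal", "note")])
  })
}

#' Consensus sheets per dyad from a long score table
#'
#' @inheritParams sheets_from_scores
#' @param method Aggregation policy passed to [aggregate_raters()].
#' @return A named list of consensus sheets, one per dyad.
#' @export
consensus_from_scores <- function(scores, method = "mean") {
  sheets <- sheets_from_scores(scores)
  dyads <- vapply(sheets, attr, "", "dyad_id")
  lapply(split(sheets, dyads), aggregate_raters, method = method)
}

#' Write a cohort to plain-text files
#'
#' Writes `scores.csv`, `true_scores.csv`, `questionnaire.csv`,
#' `cortisol.csv`, and `truth.json` (latent classes plus the generator
#' parameters) into a directory. The files round-trip losslessly through
#' [read_cohort()].
#'
#' @param cohort An `aai_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
cohort_to_files <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aai_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("scores.csv", "true_scores.csv",
                            "questionnaire.csv", "cortisol.csv", "truth.json"))
  utils::write.csv(cohort$scores, paths[1L], row.names = FALSE)
  utils::write.csv(cohort$true_scores, paths[2L], row.names = FALSE)
  utils::write.csv(cohort$questionnaire, paths[3L], row.names = FALSE)
  utils::write.csv(cohort$cortisol, paths[4L], row.names = FALSE)
  cfg <- cohort$config
  cfg$verdict_matrix <- as.data.frame(cfg$verdict_matrix)
  jsonlite::write_json(
    list(truth = cohort$truth, seed = cohort$seed, config = unclass(cfg)),
    paths[5L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort back from files written by [cohort_to_files()]
#'
#' @param dir Directory containing the cohort files.
#' @return An `aai_cohort` (the generator config is restored as a plain
#'   list).
#' @export
read_cohort <- function(dir) {
  truth_js <- jsonlite::read_json(file.path(dir, "truth.json"),
                                  simplifyVector = TRUE)
  structure(list(
    truth = truth_js$truth,
    true_scores = utils::read.csv(file.path(dir, "true_scores.csv"),
                                  stringsAsFactors = FALSE),
    scores = read_scores_frame(file.path(dir, "scores.csv")),
    questionnaire = utils::read.csv(file.path(dir, "questionnaire.csv"),
                                    stringsAsFactors = FALSE),
    cortisol = utils::read.csv(file.path(dir, "cortisol.csv"),
                               stringsAsFactors = FALSE),
    config = truth_js$config, seed = truth_js$seed
  ), class = "aai_cohort")
}
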