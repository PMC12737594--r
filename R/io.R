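# Read and validate the long-format score CSV as a data frame, reporting
# offending rows by line number (header = line 1).
read_scores_frame <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("dyad_id", "rater_id", "subphase", "valence", "arousal")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("score file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"aggression" %in% names(df)) df$aggression <- FALSE
  if (!"refusal" %in% names(df)) df$refusal <- FALSE
  if (!"note" %in% names(df)) df$note <- ""
  df$note[is.na(df$note)] <- ""
  if (!nrow(df)) {
    warning("score file ", path, " contains no score rows", call. = FALSE)
    return(df)
  }
  line <- seq_len(nrow(df)) + 1L
  bad_sub <- !df$subphase %in% subphase_codes()
  if (any(bad_sub)) {
    stop("unknown sub-phase code(s) (scored sub-phases are a-x) at line(s) ",
         paste(utils::head(line[bad_sub], 10), collapse = ", "),
         ": ", paste(utils::head(unique(df$subphase[bad_sub]), 10), collapse = ", "),
         call. = FALSE)
  }
  bad_rng <- is.na(df$valence) | is.na(df$arousal) |
    abs(df$valence) > 5 | abs(df$arousal) > 5
  if (any(bad_rng)) {
    stop("valence/arousal missing or outside [-5, 5] at line(s) ",
         paste(utils::head(line[bad_rng], 10), collapse = ", "), call. = FALSE)
  }
  df$aggression <- df$aggression %in% c(TRUE, "TRUE", "true", 1)
  df$refusal <- df$refusal %in% c(TRUE, "TRUE", "true", 1)
  df
}

#' Read a long-format score sheet CSV
#'
#' One row per (dyad, rater, sub-phase) with columns `dyad_id`, `rater_id`,
#' `subphase` (a-x), `valence`, `arousal`, and optionally `aggression`,
#' `refusal`, `note`. Malformed rows are rejected with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A list of [rater_sheet()] objects (empty list, with a warning,
#'   for a header-only file).
#' @export
read_scores <- function(path) {
  df <- read_scores_frame(path)
  if (!nrow(df)) return(list())
  sheets_from_scores(df)
}

#' Write a long-format score sheet CSV
#'
#' @param scores Long score data frame (as in an `aai_cohort`).
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' Read a questionnaire CSV
#'
#' One row per dyad with a `dyad_id` column, section or section-prefixed
#' item columns, and optionally a `verdict` column holding one of the four
#' open-ended categories.
#'
#' @param path Path to the CSV file.
#' @return A data frame.
#' @export
read_questionnaire <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"dyad_id" %in% names(df)) {
    stop("questionnaire file lacks a dyad_id column", call. = FALSE)
  }
  df
}

#' Read a cortisol CSV
#'
#' One row per dyad with columns `dyad_id`, `t0`, `t1` (ng/mL).
#'
#' @param path Path to the CSV file.
#' @return A data frame.
#' @export
read_cortisol <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("dyad_id", "t0", "t1"), names(df))
  if (length(miss)) {
    stop("cortisol file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$t0 < 0 | df$t1 < 0, na.rm = TRUE)) {
    stop("cortisol concentrations must be non-negative", call. = FALSE)
  }
  df
}

merge_sp <- function(class) ifelse(class == "U", "U", "S+P")

#' Run the full analysis pipeline
#'
#' Executes the analysis stages in the study's order: descriptives,
#' two-rater reliability (ICC, when two raters are present), rater
#' aggregation and classification (or externally supplied classes),
#' caregiver-versus-test agreement, the nonparametric group battery on
#' per-dyad medians and questionnaire sections, and the paired cortisol
#' analysis.
#'
#' @param scores Long score data frame, or path to a score CSV.
#' @param questionnaire Questionnaire data frame or CSV path (optional).
#' @param cortisol Cortisol data frame or CSV path (optional).
#' @param override_classes Optional data frame `dyad_id`, `class` supplying
#'   externally determined S/P/U labels (e.g. the human evaluators'
#'   published classifications); when given, the classifier is bypassed for
#'   the agreement and grouping stages.
#' @param config A [classification_config()].
#' @param aggregation Rater aggregation policy (see [aggregate_raters()]).
#' @param alpha Significance level for the battery (default 0.05,
#'   two-sided).
#' @param out_dir Optional directory; when supplied, the report JSON, tidy
#'   stats CSV, and plot-data CSV are written there.
#' @return An object of class `aai_report` (a list of stage outputs).
#' @export
run_pipeline <- function(scores, questionnaire = NULL, cortisol = NULL,
                         override_classes = NULL,
                         config = classification_config(),
                         aggregation = "mean", alpha = 0.05,
                         out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.character(scores)) scores <- read_scores_frame(scores)
  if (is.character(questionnaire)) questionnaire <- read_questionnaire(questionnaire)
  if (is.character(cortisol)) cortisol <- read_cortisol(cortisol)

  # Stage 1: descriptives on consensus scores
  consensus <- consensus_from_scores(scores, method = aggregation)
  pooled <- do.call(rbind, lapply(consensus, as.data.frame))
  descriptives <- summarize_sheet(pooled)

  # Stage 2: inter-rater reliability, per dimension, pooling all
  # (dyad, sub-phase) score pairs
  raters <- unique(scores$rater_id)
  icc <- NULL
  if (length(raters) >= 2) {
    icc <- lapply(c(valence = "valence", arousal = "arousal"), function(dim) {
      wide <- stats::reshape(
        scores[c("dyad_id", "subphase", "rater_id", dim)],
        idvar = c("dyad_id", "subphase"), timevar = "rater_id",
        direction = "wide")
      icc_two_rater(as.matrix(wide[, -(1:2), drop = FALSE]))
    })
  }

  # Stage 3: classification (or external override labels)
  classifications <- classify_cohort(consensus, config = config)
  classes <- classifications$class
  names(classes) <- classifications$dyad_id
  if (!is.null(override_classes)) {
    stopifnot(all(c("dyad_id", "class") %in% names(override_classes)))
    classes <- stats::setNames(as.character(override_classes$class),
                               as.character(override_classes$dyad_id))
  }

  # Stage 4: caregiver-vs-test agreement
  agreement <- NULL
  if (!is.null(questionnaire) && "verdict" %in% names(questionnaire)) {
    qd <- as.character(questionnaire$dyad_id)
    keep <- qd %in% names(classes)
    expected <- map_open_ended(questionnaire$verdict[keep])
    observed <- unname(classes[qd[keep]])
    tab <- build_contingency(expected, observed)
    agreement <- list(table = tab, kappa = cohens_kappa(tab),
                      concordance = concordance(tab))
  }

  # Stage 5: group battery on per-dyad medians
  med <- do.call(rbind, lapply(names(consensus), function(d) {
    s <- consensus[[d]]
    data.frame(dyad_id = d, median_valence = stats::median(s$valence),
               median_arousal = stats::median(s$arousal),
               stringsAsFactors = FALSE)
  }))
  med$class <- unname(classes[med$dyad_id])
  med <- med[!is.na(med$class), , drop = FALSE]
  stats_out <- list()
  if (length(unique(med$class)) >= 2) {
    for (dim in c("median_valence", "median_arousal")) {
      x <- med[[dim]]
      stats_out[[paste0("kw_", dim)]] <- kruskal_wallis(x, med$class)
      if (length(unique(med$class)) >= 3) {
        stats_out[[paste0("dunn_", dim)]] <- dunn_holm(x, med$class)
      }
      merged <- merge_sp(med$class)
      if (length(unique(merged)) == 2) {
        stats_out[[paste0("mw_", dim)]] <- mann_whitney(
          x[merged == "S+P"], x[merged == "U"],
          comparison = paste0(dim, ": S+P vs U"))
      }
    }
  }

  # Stage 6: questionnaire sections
  q_scores <- NULL
  if (!is.null(questionnaire)) {
    q_scores <- score_questionnaire(questionnaire)
    q_scores$class <- unname(classes[as.character(q_scores$dyad_id)])
    secs <- intersect(questionnaire_sections()$section, names(q_scores))
    for (sec in secs) {
      ok <- !is.na(q_scores$class)
      if (length(unique(q_scores$class[ok])) >= 2) {
        stats_out[[paste0("kw_q_", sec)]] <-
          kruskal_wallis(q_scores[[sec]][ok], q_scores$class[ok])
        merged <- merge_sp(q_scores$class[ok])
        if (length(unique(merged)) == 2) {
          stats_out[[paste0("mw_q_", sec)]] <- mann_whitney(
            q_scores[[sec]][ok][merged == "S+P"],
            q_scores[[sec]][ok][merged == "U"],
            comparison = paste0(sec, ": S+P vs U"))
        }
      }
    }
  }

  # Stage 7: cortisol
  cortisol_out <- NULL
  if (!is.null(cortisol)) {
    dc <- delta_cortisol(cortisol)
    dc$class <- unname(classes[as.character(dc$dyad_id)])
    gate <- list(t0 = shapiro_gate(dc$t0, alpha), t1 = shapiro_gate(dc$t1, alpha))
    paired <- wilcoxon_paired(dc$t0, dc$t1, "T1 vs T0 (all dyads)")
    kw_delta <- NULL
    ok <- !is.na(dc$class)
    if (length(unique(dc$class[ok])) >= 2) {
      kw_delta <- kruskal_wallis(dc$delta[ok], dc$class[ok])
    }
    cortisol_out <- list(deltas = dc, shapiro = gate, paired = paired,
                         kw_delta = kw_delta)
  }

  plot_data <- do.call(rbind, lapply(names(consensus), function(d) {
    s <- consensus[[d]]
    data.frame(dyad_id = d, subphase = s$subphase, valence = s$valence,
               arousal = s$arousal,
               inside = in_region(s$valence, s$arousal, config$region),
               stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    descriptives = descriptives, icc = icc, plot_data = plot_data,
    classifications = classifications, classes = classes,
    agreement = agreement, stats = stats_out,
    questionnaire_scores = q_scores, cortisol = cortisol_out,
    provenance = list(alpha = alpha, aggregation = aggregation,
                      n_dyads = length(consensus),
                      package_version = as.character(utils::packageVersion("aaiscreen")))
  ), class = "aai_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.aai_report <- function(x, ...) {
  cat("Suitability screening report\n")
  cat(sprintf("  dyads: %d | classes: %s\n", x$provenance$n_dyads,
              paste(sprintf("%s=%d", names(table(x$classes)), table(x$classes)),
                    collapse = " ")))
  if (!is.null(x$icc)) {
    for (d in names(x$icc)) {
      cat(sprintf("  ICC (%s): %.3f [%.3f, %.3f]\n", d, x$icc[[d]]$icc,
                  x$icc[[d]]$lower, x$icc[[d]]$upper))
    }
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("  caregiver-vs-test kappa: %.3f (%s), overall concordance %.1f%%\n",
                x$agreement$kappa$kappa, x$agreement$kappa$label,
                x$agreement$concordance$overall))
  }
  cat(sprintf("  %d battery results\n", length(x$stats)))
  invisible(x)
}

stats_to_frame <- function(stats_out) {
  rows <- lapply(names(stats_out), function(nm) {
    s <- stats_out[[nm]]
    if (inherits(s, "group_test")) {
      cbind(id = nm, as.data.frame(s))
    } else if (is.data.frame(s)) {
      data.frame(id = nm, test = "Dunn-Holm", comparison = s$comparison,
                 statistic = s$z, df = NA_real_, p = s$p,
                 p_adjusted = s$p_adjusted, effect = NA_real_,
                 effect_name = NA_character_, magnitude = NA_character_,
                 code = s$code, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (full report), `stats.csv` (tidy one-row-per-
#' comparison battery), `classifications.csv`, and `plot_data.csv`
#' (per-dyad, per-sub-phase valence/arousal/region membership for
#' rendering the Cartesian grids).
#'
#' @param report An `aai_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$classifications,
                   file.path(dir, "classifications.csv"), row.names = FALSE)
  if (!is.null(report$plot_data)) {
    utils::write.csv(report$plot_data, file.path(dir, "plot_data.csv"),
                     row.names = FALSE)
  }
  st <- stats_to_frame(report$stats)
  if (!is.null(st)) {
    utils::write.csv(st, file.path(dir, "stats.csv"), row.names = FALSE)
  }
  js <- list(
    descriptives = report$descriptives,
    icc = lapply(report$icc, function(i) i[c("icc", "lower", "upper", "model", "p")]),
    classes = as.list(report$classes),
    agreement = if (!is.null(report$agreement)) list(
      table = as.data.frame(report$agreement$table),
      kappa = report$agreement$kappa[c("kappa", "p_o", "p_e", "n", "label")],
      concordance = report$agreement$concordance),
    stats = if (!is.null(st)) st,
    provenance = report$provenance
  )
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
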