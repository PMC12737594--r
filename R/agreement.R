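SPU_LEVELS <- c("S", "P", "U")

#' Build the 3x3 caregiver-versus-test contingency table
#'
#' Tallies aligned pairs of expected classes (from the caregiver's mapped
#' verdict; rows) against observed test classes (columns) over the S/P/U
#' labels.
#'
#' @param caregiver Character vector of expected classes (rows).
#' @param test Character vector of observed test classes (columns), same
#'   length.
#' @return A 3x3 contingency `table` (class `contingency_spu`) with S/P/U
#'   rows and columns.
#' @export
build_contingency <- function(caregiver, test) {
  if (length(caregiver) != length(test)) {
    stop("caregiver and test class vectors differ in length", call. = FALSE)
  }
  if (!length(caregiver)) stop("no class pairs supplied", call. = FALSE)
  bad <- unique(c(caregiver[!caregiver %in% SPU_LEVELS],
                  test[!test %in% SPU_LEVELS]))
  if (length(bad)) {
    stop("classes must be S, P, or U; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(caregiver = factor(caregiver, SPU_LEVELS),
               test = factor(test, SPU_LEVELS))
  class(tab) <- c("contingency_spu", class(tab))
  tab
}

#' Cohen's kappa for a square contingency table
#'
#' Unweighted chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e)
#' with observed agreement p_o = trace/N and expected agreement
#' p_e = sum_i (row_i * col_i) / N^2. A Landis-Koch qualitative band is
#' attached informationally.
#'
#' @param table A square contingency table (e.g. from
#'   [build_contingency()]).
#' @return An object of class `agreement_result`: list with `kappa`, `p_o`,
#'   `p_e`, `n`, `label`, and the `table`.
#' @export
#' @examples
#' tab <- build_contingency(c("S","S","U"), c("S","U","U"))
#' cohens_kappa(tab)
cohens_kappa <- function(table) {
  m <- unclass(as.matrix(table))
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  n <- sum(m)
  if (n == 0) stop("empty contingency table", call. = FALSE)
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (p_e >= 1) stop("degenerate table: expected agreement is 1", call. = FALSE)
  kappa <- (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n = n,
                 label = landis_koch(kappa), table = table),
            class = "agreement_result")
}

landis_koch <- function(kappa) {
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (%s agreement)\n", x$kappa, x$label))
  cat(sprintf("  observed agreement %.3f, expected %.3f, N = %d\n",
              x$p_o, x$p_e, x$n))
  invisible(x)
}

#' Per-row and overall concordance of a contingency table
#'
#' Row concordance is the diagonal count as a percentage of the row total
#' (rows with no observations are reported as `NA`); overall concordance is
#' 100 * trace / N.
#'
#' @param table A square contingency table.
#' @return A list with `per_row` (named numeric, percent) and `overall`
#'   (percent).
#' @export
concordance <- function(table) {
  m <- unclass(as.matrix(table))
  stopifnot(nrow(m) == ncol(m))
  n <- sum(m)
  if (n == 0) stop("empty contingency table", call. = FALSE)
  rs <- rowSums(m)
  per_row <- ifelse(rs > 0, 100 * diag(m) / rs, NA_real_)
  names(per_row) <- rownames(m)
  list(per_row = per_row, overall = 100 * sum(diag(m)) / n)
}

#' Two-rater intraclass correlation (ICC)
#'
#' Single-rater ICC from a two-way items-by-raters layout, computed from the
#' ANOVA mean squares (Shrout-Fleiss). The default `"consistency"` model
#' (ICC(3,1)-style) is (MSR - MSE) / (MSR + (k-1) MSE); the `"agreement"`
#' model (ICC(2,1)) additionally penalises rater mean differences. For
#' pooled score sheets the items are all (dyad, sub-phase) pairs of one
#' dimension, so valence and arousal reliability are assessed separately.
#' The confidence interval and p-value come from the F distribution of
#' MSR/MSE; the p-value tests ICC = 0.
#'
#' @param scores Numeric matrix, items in rows, raters in columns. Rows
#'   containing missing values are dropped (listwise).
#' @param model `"consistency"` (default) or `"agreement"`.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `lower`, `upper`,
#'   `model`, `p`, `n_items`, `k_raters`, and the mean squares.
#' @export
icc_two_rater <- function(scores, model = c("consistency", "agreement"),
                          conf = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(scores)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("at least two raters are required", call. = FALSE)
  if (n < 5) stop("at least 5 complete items are required", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst == 0 || msr == 0) {
    stop("no between-item variance: ICC undefined for constant data",
         call. = FALSE)
  }
  icc <- switch(model,
    consistency = (msr - mse) / (msr + (k - 1) * mse),
    agreement = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
  # CI and p from F = MSR/MSE (exact for the consistency model)
  fv <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  alpha <- 1 - conf
  fl <- fv / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fv * stats::qf(1 - alpha / 2, df2, df1)
  lower <- (fl - 1) / (fl + k - 1)
  upper <- (fu - 1) / (fu + k - 1)
  p <- stats::pf(fv, df1, df2, lower.tail = FALSE)
  structure(list(icc = icc, lower = lower, upper = upper, conf = conf,
                 model = sprintf("two-way, single rater, %s", model),
                 p = p, n_items = n, k_raters = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f, %d%% CI [%.3f, %.3f] (%s)\n",
              x$icc, round(100 * x$conf), x$lower, x$upper, x$model))
  cat(sprintf("  %d items x %d raters, p = %.3g\n", x$n_items, x$k_raters, x$p))
  invisible(x)
}
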