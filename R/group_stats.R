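# Effect-size magnitude bands: eta^2 at 0.06/0.14, r at 0.1/0.3/0.5.
magnitude_eta2 <- function(e) {
  if (e < 0.06) "small" else if (e < 0.14) "moderate" else "large"
}
magnitude_r <- function(r) {
  r <- abs(r)
  if (r < 0.1) "negligible" else if (r < 0.3) "small" else if (r < 0.5) "moderate" else "large"
}

#' Significance codes in the style of the study's tables
#'
#' @param p Numeric vector of p-values.
#' @return `"***"` (< 0.001), `"**"` (< 0.01), `"*"` (< 0.05), `"."`
#'   (< 0.1, a significant tendency), `"ns"` otherwise.
#' @export
signif_code <- function(p) {
  cut(p, c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", ".", "ns"), right = FALSE) |> as.character()
}

group_test <- function(test, comparison, statistic, df = NA_real_, p,
                       effect = NA_real_, effect_name = NA_character_,
                       magnitude = NA_character_, p_adjusted = NA_real_) {
  structure(list(test = test, comparison = comparison, statistic = statistic,
                 df = df, p = p, p_adjusted = p_adjusted, effect = effect,
                 effect_name = effect_name, magnitude = magnitude,
                 code = signif_code(if (is.na(p_adjusted)) p else p_adjusted)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g", x$test, x$comparison, x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", p = %.4g", x$p))
  if (!is.na(x$p_adjusted)) cat(sprintf(", p.adj = %.4g", x$p_adjusted))
  if (!is.na(x$effect)) {
    cat(sprintf(", %s = %.3f (%s)", x$effect_name, x$effect, x$magnitude))
  }
  cat(" ", x$code, "\n")
  invisible(x)
}

#' @export
as.data.frame.group_test <- function(x, ...) {
  data.frame(test = x$test, comparison = x$comparison,
             statistic = unname(x$statistic), df = unname(x$df), p = x$p,
             p_adjusted = x$p_adjusted, effect = x$effect,
             effect_name = x$effect_name, magnitude = x$magnitude,
             code = x$code, stringsAsFactors = FALSE)
}

#' Eta-squared effect size for the Kruskal-Wallis H statistic
#'
#' eta^2 = (H - k + 1) / (n - k), which can be slightly negative when H is
#' below its null expectation.
#'
#' @param h Kruskal-Wallis statistic.
#' @param k Number of groups.
#' @param n Total sample size.
#' @return The eta-squared value.
#' @export
#' @examples
#' eta_squared_h(8.06, 3, 38)  # 0.173
eta_squared_h <- function(h, k, n) (h - k + 1) / (n - k)

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Rank-based k-group comparison (tie-corrected H via
#' [stats::kruskal.test()]) augmented with the eta-squared effect size and
#' its magnitude band.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length.
#' @return A `group_test` with statistic H, df = k - 1, the p-value, and
#'   eta-squared.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (any(tabulate(groups) == 0)) stop("empty group", call. = FALSE)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  kt <- stats::kruskal.test(values, groups)
  k <- nlevels(groups); n <- length(values)
  e2 <- eta_squared_h(unname(kt$statistic), k, n)
  group_test("Kruskal-Wallis", paste(levels(groups), collapse = " vs "),
             unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value,
             effect = e2, effect_name = "eta2", magnitude = magnitude_eta2(e2))
}

# Tie-corrected variance term for pooled-rank z statistics:
# sum over tie groups of (t^3 - t).
tie_term <- function(x) {
  t <- table(x)
  sum(t^3 - t)
}

#' Dunn's post hoc test with Holm correction
#'
#' All pairwise comparisons on the pooled ranks of a k-group sample. Each
#' pairwise z uses the tie-corrected pooled-rank variance
#' (N(N+1)/12 - sum(t^3 - t)/(12(N-1))); raw two-sided p-values are
#' adjusted by Holm's step-down procedure ([stats::p.adjust()]).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (k >= 2; conventionally used with k >= 3 after
#'   a significant Kruskal-Wallis test).
#' @return A data frame with one row per pair: `comparison`, `z`, `p`,
#'   `p_adjusted`, `code`.
#' @export
dunn_holm <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (any(tabulate(groups) == 0)) stop("empty group", call. = FALSE)
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  s2 <- n * (n + 1) / 12 - tie_term(values) / (12 * (n - 1))
  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    z <- (mean_r[[i]] - mean_r[[j]]) /
      sqrt(s2 * (1 / n_g[[i]] + 1 / n_g[[j]]))
    data.frame(comparison = paste(i, "vs", j), z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = "holm")
  out$code <- signif_code(out$p_adjusted)
  rownames(out) <- NULL
  out
}

# Tie-corrected normal-approximation z for the Mann-Whitney U statistic
# (no continuity correction; used for the rank-biserial effect size).
mw_z <- function(u, x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term(pooled) / (n * (n - 1)))
  (u - n1 * n2 / 2) / sqrt(sigma2)
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-group rank comparison. The U statistic and p-value come from
#' [stats::wilcox.test()] (normal approximation with tie correction by
#' default; exact for small tie-free samples when `exact = TRUE`). The
#' effect size is r = |z| / sqrt(n1 + n2) with the tie-corrected z.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param comparison Label for the comparison.
#' @param exact Use the exact distribution when possible (default FALSE).
#' @return A `group_test` with statistic U and effect size r.
#' @export
mann_whitney <- function(x, y, comparison = "group1 vs group2", exact = FALSE) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  u <- unname(wt$statistic)
  z <- mw_z(u, x, y)
  r <- abs(z) / sqrt(length(x) + length(y))
  group_test("Mann-Whitney U", comparison, u, p = wt$p.value,
             effect = r, effect_name = "r", magnitude = magnitude_r(r))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values (e.g. cortisol at T0 and
#' T1). Zero differences are dropped; V is the sum of the ranks of the
#' positive differences `after - before`.
#'
#' @param before,after Paired numeric vectors.
#' @param comparison Label for the comparison.
#' @return A `group_test` with statistic V.
#' @export
wilcoxon_paired <- function(before, after, comparison = "T1 vs T0") {
  stopifnot(length(before) == length(after))
  d <- after - before
  d <- d[!is.na(d)]
  if (!length(d) || all(d == 0)) {
    stop("all paired differences are zero", call. = FALSE)
  }
  if (sum(d != 0) < 5) {
    stop("fewer than 5 non-zero paired differences", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE))
  group_test("Wilcoxon signed-rank", comparison, unname(wt$statistic),
             p = wt$p.value)
}

#' Shapiro-Wilk normality gate
#'
#' Reports W and p, and a gate flag `normal = (p >= alpha)`. The gate is
#' used only to justify the nonparametric analysis path; it never switches
#' methods silently.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha Gate level (default 0.05).
#' @return A list with `W`, `p`, `normal`.
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got n = ", n, call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    stop("constant input: normality test undefined", call. = FALSE)
  }
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value, normal = st$p.value >= alpha)
}

#' Per-dyad cortisol deltas
#'
#' Computes delta = T1 - T0 (ng/mL) per dyad; dyads with a missing member
#' of the pair are excluded with a message (mirroring swabs with
#' insufficient saliva).
#'
#' @param pairs Data frame with columns `dyad_id`, `t0`, `t1`, and
#'   optionally `class`.
#' @return A data frame with `dyad_id`, `t0`, `t1`, `delta` (and `class`
#'   when supplied), one row per complete pair.
#' @export
delta_cortisol <- function(pairs) {
  stopifnot(all(c("dyad_id", "t0", "t1") %in% names(pairs)))
  if (any(pairs$t0 < 0 | pairs$t1 < 0, na.rm = TRUE)) {
    stop("cortisol concentrations must be non-negative", call. = FALSE)
  }
  complete <- !is.na(pairs$t0) & !is.na(pairs$t1)
  if (any(!complete)) {
    message(sum(!complete), " dyad(s) excluded: incomplete cortisol pair")
  }
  out <- pairs[complete, , drop = FALSE]
  out$delta <- out$t1 - out$t0
  rownames(out) <- NULL
  out
}
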