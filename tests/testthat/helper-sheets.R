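# Build a score frame for all 24 sub-phases at a constant coordinate,
# optionally overriding individual sub-phases.
uniform_scores <- function(valence, arousal, overrides = NULL) {
  df <- data.frame(subphase = subphase_codes(), valence = valence,
                   arousal = arousal, aggression = FALSE, refusal = FALSE,
                   note = "", stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    for (code in names(overrides)) {
      i <- match(code, df$subphase)
      df$valence[i] <- overrides[[code]][1L]
      df$arousal[i] <- overrides[[code]][2L]
    }
  }
  df
}

make_consensus <- function(scores, dyad = "d1") {
  aggregate_raters(rater_sheet(dyad, "R1", scores))
}

# Independent barycentric-coordinate point-in-triangle oracle for the
# region with vertices (0,0), (5,3), (5,-3); closed boundary.
barycentric_in_triangle <- function(x, y, eps = 1e-9) {
  a <- c(0, 0); b <- c(5, 3); c_ <- c(5, -3)
  m <- cbind(b - a, c_ - a)
  lam <- solve(m, c(x - a[1L], y - a[2L]))
  all(lam >= -eps) && sum(lam) <= 1 + eps
}
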