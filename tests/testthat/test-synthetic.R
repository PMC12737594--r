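test_that("cohort generation is seeded, complete, and on the score grid", {
  co <- generate_cohort(generator_config(), seed = 21)
  expect_equal(nrow(co$truth), 38)
  expect_equal(nrow(co$true_scores), 38 * 24)
  # two rater sheets minus missing rows
  expect_lte(nrow(co$scores), 38 * 24 * 2)
  expect_gt(nrow(co$scores), 38 * 24 * 2 - 20)
  expect_true(all(co$scores$valence %in% seq(-5, 5, 0.5)))
  expect_true(all(co$scores$arousal %in% seq(-5, 5, 0.5)))
  expect_equal(nrow(co$questionnaire), 38)
  expect_true(all(co$questionnaire$verdict %in%
                    c("Yes", "No", "Maybe", "Yes after a training programme")))
  expect_true(all(co$cortisol$t0 > 0 & co$cortisol$t1 > 0))
  # determinism: same seed, same config -> identical cohort
  co2 <- generate_cohort(generator_config(), seed = 21)
  expect_identical(co, co2)
})

test_that("degenerate class probabilities and invalid configs are handled", {
  co <- generate_cohort(generator_config(class_probs = c(S = 1, P = 0, U = 0)),
                        seed = 3)
  expect_true(all(co$truth$class == "S"))
  expect_error(generator_config(class_probs = c(S = 0.5, P = 0.2, U = 0.2)),
               "sum to 1")
  expect_error(generator_config(missing_prob = 1.2), "missing_prob")
})

test_that("generated verdicts track the latent class via the conditional matrix", {
  # latent S dogs always get a "Yes"; expected kappa against latent classes
  # is the table-derived 0.285 on average
  kappas <- numeric(60)
  for (i in seq_along(kappas)) {
    co <- generate_cohort(generator_config(), seed = 7000 + i)
    expected <- map_open_ended(co$questionnaire$verdict)
    expect_true(all(expected[co$truth$class == "S"] == "S"))
    kappas[i] <- tryCatch(
      cohens_kappa(build_contingency(expected, co$truth$class))$kappa,
      error = function(e) NA_real_)
  }
  expect_equal(mean(kappas, na.rm = TRUE), 0.285, tolerance = 0.1 / 0.285)
})

test_that("questionnaire group moments match the generating parameters", {
  # pool several seeds so group means are estimated from n >> 38
  sep_sp <- sep_u <- c()
  for (i in 1:20) {
    co <- generate_cohort(generator_config(), seed = 400 + i)
    u <- co$truth$class == "U"
    sep_sp <- c(sep_sp, co$questionnaire$separation[!u])
    sep_u <- c(sep_u, co$questionnaire$separation[u])
  }
  expect_equal(mean(sep_sp), 0.205, tolerance = 0.15)
  expect_equal(mean(sep_u), 0.677, tolerance = 0.15)
})

test_that("separation scores separate S+P from U in most seeded cohorts", {
  reject <- logical(30)
  for (i in seq_along(reject)) {
    co <- generate_cohort(generator_config(), seed = 600 + i)
    u <- co$truth$class == "U"
    reject[i] <- mann_whitney(co$questionnaire$separation[!u],
                              co$questionnaire$separation[u])$p < 0.05
  }
  expect_gt(mean(reject), 0.5)
})

test_that("suitable-class pooled valence stays near its calibration mean", {
  co <- generate_cohort(generator_config(), seed = 17)
  s_dyads <- co$truth$dyad_id[co$truth$class == "S"]
  v <- co$true_scores$valence[co$true_scores$dyad_id %in% s_dyads]
  expect_gt(length(v), 100)
  expect_equal(mean(v), 2.5, tolerance = 0.25 / 2.5)
})

test_that("cohorts round-trip losslessly through files", {
  co <- generate_cohort(generator_config(), seed = 31)
  dir <- withr::local_tempdir()
  cohort_to_files(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$truth, co$truth)
  expect_equal(back$scores, co$scores, tolerance = 1e-12)
  expect_equal(back$true_scores, co$true_scores, tolerance = 1e-12)
  expect_equal(back$questionnaire, co$questionnaire, tolerance = 1e-12)
  expect_equal(back$cortisol, co$cortisol, tolerance = 1e-12)
  expect_equal(sum(table(back$truth$class)), 38)
  # byte-identical files under the same seed
  dir2 <- withr::local_tempdir()
  cohort_to_files(generate_cohort(generator_config(), seed = 31), dir2)
  for (f in c("scores.csv", "questionnaire.csv", "cortisol.csv", "truth.json")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})

test_that("ICC on generated sheets tracks the generative variance ratio", {
  diffs <- numeric(20)
  for (i in seq_along(diffs)) {
    cfg <- generator_config()
    co <- generate_cohort(cfg, seed = 800 + i)
    w <- stats::reshape(co$scores[c("dyad_id", "subphase", "rater_id", "valence")],
                        idvar = c("dyad_id", "subphase"), timevar = "rater_id",
                        direction = "wide")
    obs <- icc_two_rater(as.matrix(w[, -(1:2)]))$icc
    vb <- stats::var(co$true_scores$valence)
    diffs[i] <- obs - vb / (vb + cfg$rater_error_sd^2)
  }
  expect_lt(abs(mean(diffs)), 0.1)
})
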